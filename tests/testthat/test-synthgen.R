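# Synthetic-data generators: construction targets, determinism, geometry.

test_that("mini simulation matches its Poisson and amplitude construction", {
  p <- mini_sim_params(rate = 2, duration = 60, seed = 11)
  s <- simulate_minis(p)
  # Poisson(120) count within 3 sd
  expect_lt(abs(nrow(s$truth) - 120), 3 * sqrt(120))
  expect_true(all(diff(s$truth$time_s) >= 0))

  # noiseless, dispersion-free events reproduce their unit amplitude
  p0 <- mini_sim_params(rate = 0.5, duration = 20, amp_cv = 0, amp_mean = 1,
                        noise_sd = 0, seed = 4)
  s0 <- simulate_minis(p0)
  expect_true(all(s0$truth$amplitude == 1))
  iso <- s0$truth$time_s
  iso <- iso[c(diff(iso) > 0.1, TRUE) & c(TRUE, diff(iso) > 0.1)]
  for (t0 in iso[iso < p0$duration - 0.05]) {
    win <- s0$trace$samples[floor(t0 / p0$dt) + seq_len(500)]
    expect_equal(max(win), 1, tolerance = 1e-9)
  }
})

test_that("mini simulation is bitwise reproducible under a fixed seed", {
  p <- mini_sim_params(rate = 3, duration = 5, seed = 99)
  expect_identical(simulate_minis(p), simulate_minis(p))
})

test_that("depletion-only trains are exactly geometric and telescoping", {
  p <- quantal_model_params(N0 = 500, pr = 0.5, q = 1, k_replenish = 0,
                            trial_noise_cv = 0, n_trains = 1)
  tr <- simulate_trains(p)$trains
  a <- tr$amplitude
  expect_equal(a[1], 250)
  expect_equal(a, 250 * 0.5^(seq_len(60) - 1), tolerance = 1e-12)
  expect_lt(abs(sum(a) - 500 * (1 - 0.5^60)) / 500, 1e-12)
  # vesicle conservation: total released quanta never exceed the pool
  expect_lte(sum(a) / p$q, p$N0)
})

test_that("replenishing trains converge to the recurrence fixed point", {
  p <- quantal_model_params(N0 = 400, pr = 0.4, q = 2, k_replenish = 30,
                            trial_noise_cv = 0, n_trains = 1)
  tr <- simulate_trains(p)$trains
  oracle <- oracle_recurrence(400, 0.4, 2, 30, 60, 60)
  expect_equal(tr$amplitude, oracle, tolerance = 1e-12)
  # fixed point of N -> s + k dt (N0 - s), s = N(1-pr)
  kdt <- 30 / 60
  Nstar <- kdt * 400 / (1 - (1 - 0.4) * (1 - kdt))
  expect_equal(tail(tr$amplitude, 1), 2 * 0.4 * Nstar, tolerance = 1e-6)
})

test_that("screen tables hit their construction targets", {
  # all PHP-competent: EPSC conserved, mEPSP scaled by 0.6
  s <- simulate_screen(screen_sim_params(n_lines = 60, seed = 21))
  tab <- s$table
  lines <- tab[tab$genotype_class == "line", ]
  expect_equal(mean(lines$value[lines$modality == "EPSC"]), 70,
               tolerance = 0.03)
  expect_equal(mean(lines$value[lines$modality == "mEPSP"]), 0.6 * 0.8,
               tolerance = 0.03)
  # all PHP-deficient: EPSC falls to 0.6x
  sd_ <- simulate_screen(screen_sim_params(n_lines = 60,
                                           frac_php_deficient = 1, seed = 22))
  ld <- sd_$table[sd_$table$genotype_class == "line", ]
  expect_equal(mean(ld$value[ld$modality == "EPSC"]), 0.6 * 70,
               tolerance = 0.03)
  # WT references present under both conditions
  expect_setequal(unique(tab$condition[tab$line_id == "WT"]),
                  c("control", "PhTX"))
})

test_that("NMJ counts per line have mean ~4 on the range 3..12", {
  counts <- unlist(lapply(1:20, function(sd)
    simulate_screen(screen_sim_params(n_lines = 180, seed = sd))$truth$n_nmjs))
  expect_gte(min(counts), 3)
  expect_lte(max(counts), 12)
  expect_equal(mean(counts), 4, tolerance = 0.05)
})

test_that("screen group means obey the law of large numbers", {
  tab <- simulate_php_experiment(TRUE, n_per_arm = 1e4, seed = 5)
  m <- with(tab, tapply(value, interaction(condition, modality), mean))
  se <- 0.15 / sqrt(1e4)
  expect_lt(abs(m[["control.mEPSP"]] - 0.8), 4 * se * 0.8)
  expect_lt(abs(m[["PhTX.mEPSP"]] - 0.48), 4 * se * 0.48)
  expect_lt(abs(m[["control.EPSC"]] - 70), 4 * se * 70)
  expect_lt(abs(m[["PhTX.EPSC"]] - 70), 4 * se * 70)
})

test_that("fully coupled boutons with zero jitter coincide with references", {
  b <- simulate_boutons(bouton_sim_params(coupling_fraction = 1,
                                          coupling_sigma = 0, seed = 3))
  d <- nnd_set(b$geometry$target, b$geometry$reference)
  expect_true(all(d == 0))
  expect_true(all(b$truth$coupled))
})

test_that("all simulated points lie inside their polygon", {
  for (sd in 1:10) {
    b <- simulate_boutons(bouton_sim_params(coupling_fraction = 0.5,
                                            coupling_sigma = 80, seed = sd))
    g <- b$geometry
    expect_true(all(synhomeo:::points_in_polygon(g$reference, g$polygon)))
    expect_true(all(synhomeo:::points_in_polygon(g$target, g$polygon)))
  }
  expect_identical(simulate_boutons(bouton_sim_params(seed = 8)),
                   simulate_boutons(bouton_sim_params(seed = 8)))
})

test_that("CSR target-to-reference NND matches the Poisson-process mean", {
  # mean NND to a density-lambda point set is 1/(2 sqrt(lambda));
  # Monte-Carlo over many boutons in a square where edge effects are small
  poly <- square_polygon(2000)
  lambda <- 150 / (2000 * 2000)
  expected <- 1 / (2 * sqrt(lambda))
  set.seed(42)
  d <- replicate(300, {
    g <- simulate_boutons(bouton_sim_params(polygon = poly, n_ref = 150,
                                            n_target = 20,
                                            coupling_fraction = 0))$geometry
    mean(nnd_set(g$target, g$reference))
  })
  expect_equal(mean(d), expected, tolerance = 0.05)
})

test_that("rendered images respect their construction", {
  empty <- make_geometry(square_polygon(400),
                         matrix(numeric(0), ncol = 2),
                         matrix(numeric(0), ncol = 2))
  img0 <- render_puncta_image(empty, noise_sd = 0)
  expect_true(all(img0$reference == 0) && all(img0$target == 0))
  expect_equal(img0$pixel_size, 20)

  one <- make_geometry(square_polygon(400), matrix(c(200, 200), ncol = 2),
                       matrix(numeric(0), ncol = 2))
  img1 <- render_puncta_image(one, noise_sd = 0)
  peak <- which(img1$reference == max(img1$reference), arr.ind = TRUE)
  px <- img1$origin[1] + (peak[1, "col"] - 0.5) * img1$pixel_size
  py <- img1$origin[2] + (peak[1, "row"] - 0.5) * img1$pixel_size
  expect_lt(max(abs(c(px, py) - 200)), img1$pixel_size)
})
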