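# Quantal metrics: group means, quantal content, PHP normalization, RRP.

test_that("group mean of per-NMJ means weighs every NMJ equally", {
  expect_equal(group_mean_mepsc(c(0.8, 1.0, 1.2)), 1.0)
  expect_equal(group_mean_mepsc(0.9), 0.9)
  # two NMJs with very different event counts still contribute equally:
  # the group mean is the mean of the two NMJ means, not the pooled mean
  nmj_a <- rep(1.0, 100); nmj_b <- rep(2.0, 10)
  per_nmj <- c(mean(nmj_a), mean(nmj_b))
  expect_equal(group_mean_mepsc(per_nmj), 1.5)
  expect_false(isTRUE(all.equal(group_mean_mepsc(per_nmj),
                                mean(c(nmj_a, nmj_b)))))
  expect_error(group_mean_mepsc(numeric(0)))
})

test_that("quantal content divides evoked means by the group mini mean", {
  expect_equal(quantal_content(60, 1.0), 60)
  expect_equal(quantal_content(0, 1.0), 0)
  expect_error(quantal_content(60, 0))
  # Monte-Carlo recovery of a constructed QC of 50 at q = 0.01
  set.seed(31)
  mepsc <- 0.01 * (1 + rnorm(20, 0, 0.15))
  epsc <- 0.5 * (1 + rnorm(20, 0, 0.15))
  qc <- quantal_content(epsc, group_mean_mepsc(mepsc))
  expect_equal(mean(qc), 50, tolerance = 0.05)
})

test_that("PHP normalization discriminates competent from deficient", {
  expect_equal(php_ratio(c(2, 2), c(2, 2))$mean_ratio, 1)
  qc_of <- function(tab, cond) {
    sub <- tab[tab$condition == cond, ]
    quantal_content(sub$value[sub$modality == "EPSC"],
                    group_mean_mepsc(sub$value[sub$modality == "mEPSP"]))
  }
  comp <- simulate_php_experiment(TRUE, n_per_arm = 20, seed = 41)
  r <- php_ratio(qc_of(comp, "PhTX"), qc_of(comp, "control"))
  expect_equal(r$mean_ratio, 1 / 0.6, tolerance = 0.1)
  defi <- simulate_php_experiment(FALSE, n_per_arm = 20, seed = 42)
  r2 <- php_ratio(qc_of(defi, "PhTX"), qc_of(defi, "control"))
  expect_equal(r2$mean_ratio, 1, tolerance = 0.1)
})

test_that("cumulative profiles average trains and accumulate", {
  p <- quantal_model_params(N0 = 300, pr = 0.3, q = 1, trial_noise_cv = 0,
                            n_trains = 5)
  tr <- simulate_trains(p)$trains
  prof <- cumulative_profile(tr)
  one <- tr$amplitude[tr$train_id == 1]
  expect_equal(prof$mean_amplitude, one)          # identical trains
  expect_true(all(diff(prof$cumulative) >= 0))
  expect_equal(prof$t_s, (seq_len(60) - 1) / 60)

  flat <- data.frame(cell_id = "c", train_id = 1, stimulus_index = 1:10,
                     amplitude = 10)
  pf <- cumulative_profile(flat, freq = 60)
  expect_equal(pf$cumulative, 10 * (1:10))

  ragged <- rbind(flat, data.frame(cell_id = "c", train_id = 2,
                                   stimulus_index = 1:5, amplitude = 1))
  expect_error(cumulative_profile(ragged), "ragged")
})

test_that("constant-amplitude trains give the degenerate linear profile", {
  flat <- data.frame(cell_id = "c", train_id = 1, stimulus_index = 1:60,
                     amplitude = 10)
  prof <- cumulative_profile(flat, freq = 60)
  est <- rrp_from_cumulative(prof, group_mepsc = 2)
  # C_i = 10 i = 10 (1 + 60 t): intercept 10, slope 600
  expect_equal(est$intercept, 10, tolerance = 1e-9)
  expect_equal(est$slope, 600, tolerance = 1e-9)
  expect_equal(est$rrp_quanta, 5, tolerance = 1e-9)
})

test_that("geometric depletion recovers pool, pr and PPR exactly", {
  p <- quantal_model_params(N0 = 500, pr = 0.5, q = 1, k_replenish = 0,
                            trial_noise_cv = 0)
  prof <- cumulative_profile(simulate_trains(p)$trains)
  est <- rrp_from_cumulative(prof, group_mepsc = 1)
  expect_lt(abs(est$intercept - 500), 1e-6)
  expect_equal(est$rrp_quanta, est$intercept)
  pp <- pr_and_ppr(prof, est)
  expect_equal(pp$p_r, 0.5, tolerance = 1e-6)
  expect_equal(pp$ppr, 0.5, tolerance = 1e-12)   # 1 - pr for geometric decay
  # facilitating profile gives PPR > 1
  fac <- cumulative_profile(data.frame(cell_id = "c", train_id = 1,
                                       stimulus_index = 1:20,
                                       amplitude = seq(10, 48, by = 2)),
                            freq = 60)
  fest <- suppressWarnings(rrp_from_cumulative(fac, 1, last_k = 5))
  expect_equal(suppressWarnings(pr_and_ppr(fac, fest))$ppr, 1.2)
})

test_that("parameter recovery holds across the depletion grid", {
  for (pr in c(0.3, 0.5, 0.7)) for (N0 in c(200, 500)) {
    p <- quantal_model_params(N0 = N0, pr = pr, q = 1, k_replenish = 0,
                              trial_noise_cv = 0)
    prof <- cumulative_profile(simulate_trains(p)$trains)
    est <- rrp_from_cumulative(prof, 1)
    expect_lt(abs(est$rrp_quanta - N0) / N0, 1e-4)
    expect_lt(abs(pr_and_ppr(prof, est)$p_r - pr), 1e-4)
  }
})

test_that("the estimator reproduces the replenishment bias of the method", {
  # with replenishment the intercept overestimates q N0; the estimate must
  # agree with an independent recurrence + closed-form OLS oracle
  for (k in c(10, 60, 240)) {
    p <- quantal_model_params(N0 = 300, pr = 0.4, q = 0.8, k_replenish = k,
                              trial_noise_cv = 0)
    prof <- cumulative_profile(simulate_trains(p)$trains)
    est <- rrp_from_cumulative(prof, group_mepsc = 0.8)
    a_or <- oracle_recurrence(300, 0.4, 0.8, k, 60, 60)
    cum_or <- cumsum(a_or)
    t_or <- (0:59) / 60
    ols <- oracle_ols(t_or[46:60], cum_or[46:60])
    expect_lt(abs(est$intercept - ols["intercept"]), 1e-9)
    # first-order replenishment shallows depletion, so the intercept
    # underestimates q N0; the bias is reproduced, never corrected
    expect_gt(est$intercept, 0)
    expect_lt(est$intercept, 0.8 * 300)
  }
})

test_that("RRP estimation is scale-equivariant", {
  p <- quantal_model_params(N0 = 300, pr = 0.4, q = 1, k_replenish = 20,
                            trial_noise_cv = 0.05, seed = 9)
  tr <- simulate_trains(p)$trains
  prof <- cumulative_profile(tr)
  est <- rrp_from_cumulative(prof, 1)
  tr2 <- tr; tr2$amplitude <- 3 * tr2$amplitude
  prof2 <- cumulative_profile(tr2)
  est2 <- rrp_from_cumulative(prof2, 1)
  expect_equal(est2$intercept, 3 * est$intercept, tolerance = 1e-9)
  pp <- pr_and_ppr(prof, est); pp2 <- pr_and_ppr(prof2, est2)
  expect_equal(pp2$p_r, pp$p_r, tolerance = 1e-12)
  expect_equal(pp2$ppr, pp$ppr, tolerance = 1e-12)
})

test_that("noisy five-train estimates stay within 10% median error", {
  errs <- vapply(1:100, function(sd) {
    p <- quantal_model_params(N0 = 500, pr = 0.5, q = 1, k_replenish = 0,
                              trial_noise_cv = 0.1, n_trains = 5, seed = sd)
    est <- rrp_from_cumulative(cumulative_profile(simulate_trains(p)$trains), 1)
    abs(est$rrp_quanta - 500) / 500
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
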