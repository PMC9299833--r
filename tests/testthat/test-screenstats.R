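# Screen statistics: volcano hit calling, factorial tests, gated
# comparisons, power-based sample size.

make_screen_fixture <- function(seed = 1, n_lines = 8) {
  simulate_screen(screen_sim_params(n_lines = n_lines, nmjs_per_line = 4,
                                    seed = seed))$table
}

test_that("a line identical to the reference is unflagged at ratio 1", {
  tab <- make_screen_fixture(seed = 2)
  ref <- tab[tab$line_id == "WT" & tab$condition == "PhTX", ]
  clone <- ref[ref$modality == "EPSC", ][1:4, ]
  clone$line_id <- "clone"
  clone$genotype_class <- "line"
  tab2 <- rbind(tab, clone,
                within(clone, {modality <- "mEPSP"; value <- 0.5}))
  v <- volcano_screen(tab2)
  row <- v[v$line_id == "clone", ]
  expect_equal(row$ratio, mean(clone$value) /
                 mean(ref$value[ref$modality == "EPSC"]))
  expect_equal(row$flag, "ns")
  expect_error(volcano_screen(tab[tab$line_id != "WT", ]), "reference")
})

test_that("volcano output is invariant to row order and rescaling", {
  tab <- make_screen_fixture(seed = 3)
  v1 <- volcano_screen(tab)
  set.seed(1)
  v2 <- volcano_screen(tab[sample(nrow(tab)), ])
  expect_equal(v1, v2)
  tab3 <- tab
  tab3$value[tab3$modality == "EPSC"] <- 5 * tab3$value[tab3$modality == "EPSC"]
  v3 <- volcano_screen(tab3)
  expect_equal(v3$ratio, v1$ratio, tolerance = 1e-12)
  expect_equal(v3$p_adj, v1$p_adj, tolerance = 1e-9)
})

test_that("Tukey-adjusted p values dominate unadjusted pairwise p values", {
  set.seed(8)
  g <- factor(rep(letters[1:5], each = 6))
  y <- rnorm(30) + rep(c(0, 0.2, 0.5, 0, 1), each = 6)
  tk <- TukeyHSD(aov(y ~ g))$g
  pw <- pairwise.t.test(y, g, p.adjust.method = "none")$p.value
  for (r in rownames(tk)) {
    ab <- strsplit(r, "-")[[1]]
    p_un <- pw[ab[1], ab[2]]
    if (is.na(p_un)) p_un <- pw[ab[2], ab[1]]
    expect_gte(tk[r, "p adj"] + 1e-12, p_un)
  }
})

test_that("two-way test handles degenerate and null designs", {
  g <- rep(c("wt", "mut"), each = 10)
  cond <- rep(c("ctrl", "phtx"), 10)
  expect_warning(res <- twoway_php_test(rep(5, 20), g, cond), "degenerate")
  expect_equal(res$p_interaction, 1)
  expect_error(twoway_php_test(rnorm(10), rep("a", 10), rep(c("c", "p"), 5)),
               "levels")
  set.seed(2)
  res2 <- twoway_php_test(rnorm(40), rep(c("a", "b"), each = 20),
                          rep(c("c", "p"), 20))
  expect_true(all(c("genotype", "condition") %in% res2$anova$term))
  expect_true(res2$p_interaction >= 0 && res2$p_interaction <= 1)
})

test_that("two-way interaction p is calibrated under the null", {
  set.seed(55)
  n_sim <- 1000
  rej <- vapply(seq_len(n_sim), function(i) {
    y <- rnorm(40)
    twoway_php_test(y, rep(c("a", "b"), each = 20),
                    rep(c("c", "p"), 20))$p_interaction < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej) - 0.05), 2 * se + 1e-12)
})

test_that("two-way interaction detects genotype-restricted treatment", {
  hits <- vapply(1:30, function(sd) {
    comp <- simulate_php_experiment(TRUE, n_per_arm = 15, seed = sd)
    defi <- simulate_php_experiment(FALSE, n_per_arm = 15, seed = sd + 1000)
    qc_rows <- function(tab) tab[tab$modality == "EPSC", ]
    d <- rbind(qc_rows(comp), qc_rows(defi))
    twoway_php_test(d$value, d$line_id, d$condition)$p_interaction < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the assumption gates route to the documented tests", {
  set.seed(17)
  x <- rnorm(20); y <- rnorm(20, 0.3)
  res <- compare_two(x, y)
  expect_gt(min(res$normality_p), 0.05) # fixture chosen to pass the gates
  expect_gt(res$levene_p, 0.05)
  expect_equal(res$test_used, "student_t")

  # strongly lognormal sample fails normality most of the time
  used <- vapply(1:20, function(sd) {
    set.seed(sd)
    compare_two(rlnorm(20, 0, 1.2), rnorm(20))$test_used
  }, character(1))
  expect_gt(mean(used == "mann_whitney"), 0.9)

  # identical samples: p near 1
  set.seed(18)
  z <- rnorm(12)
  expect_gt(compare_two(z, z)$p, 0.95)

  # zero-variance group falls through with a warning
  expect_warning(res0 <- compare_two(rep(1, 5), c(1, 2, 1.5, 1.7, 1.2)),
                 "Mann-Whitney")
  expect_equal(res0$test_used, "mann_whitney")
})

test_that("minimum n matches a noncentral-t integration oracle", {
  # oracle: power by numeric integration of the noncentral t density
  oracle_power <- function(d, n, alpha = 0.05) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    crit <- qt(1 - alpha / 2, df)
    suppressWarnings({
      upper <- integrate(function(t) dt(t, df, ncp), crit, Inf,
                         rel.tol = 1e-10)$value
      lower <- integrate(function(t) dt(t, df, ncp), -Inf, -crit,
                         rel.tol = 1e-10)$value
    })
    upper + lower
  }
  oracle_n <- function(d) {
    n <- 2L
    while (oracle_power(d, n) < 0.8) n <- n + 1L
    n
  }
  for (d in c(0.5, 0.8, 1.0)) expect_identical(min_n_power(d), oracle_n(d))
  expect_identical(min_n_power(10), 2L)
  # monotone in effect size and in target power
  ns <- vapply(c(0.3, 0.5, 0.8, 1, 2), min_n_power, integer(1))
  expect_true(all(diff(ns) <= 0))
  pw <- vapply(c(0.5, 0.8, 0.9, 0.99),
               function(p) min_n_power(0.7, power = p), integer(1))
  expect_true(all(diff(pw) >= 0))
})
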