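## Screen-level statistics: volcano hit calling by one-way ANOVA + Tukey,
## factorial PHP tests, assumption-gated two-group comparison, and
## power-based minimum sample size.

#' Volcano hit calling for a PHP screen
#'
#' Pools the evoked-amplitude groups of every screened line together with
#' the PhTX-treated WT reference in one one-way ANOVA, computes Tukey
#' HSD-adjusted p values for each line against the reference, and flags
#' lines whose amplitude ratio versus the reference is significant.
#'
#' @param table a `screen_table` data frame (see [simulate_screen()]);
#'   rows with `modality == "EPSC"` and `condition == "PhTX"` are used.
#' @param alpha_flag familywise significance level for flagging
#'   (default 0.01).
#' @param ref_id `line_id` of the reference group (default `"WT"`, i.e. the
#'   PhTX-treated WT reference).
#' @return a `volcano_screen` data frame with one row per line:
#'   `line_id`, `ratio` (line mean / reference mean), `p_adj`
#'   (Tukey-adjusted) and `flag` in {smaller, larger, ns}.
#' @export
volcano_screen <- function(table, alpha_flag = 0.01, ref_id = "WT") {
  check_that(all(c("line_id", "condition", "modality", "value") %in%
                   names(table)), "not a screen table")
  d <- table[table$modality == "EPSC" & table$condition == "PhTX", ]
  check_that(ref_id %in% d$line_id, "missing reference group in table")
  check_that(length(unique(d$line_id)) >= 2, "need at least one line")
  d$line_id <- factor(d$line_id)
  fit <- aov(value ~ line_id, data = d)
  tk <- TukeyHSD(fit)$line_id
  ## rows are "A-B" pairs; keep those involving the reference
  cmp <- rownames(tk)
  means <- tapply(d$value, d$line_id, mean)
  ref_mean <- means[[ref_id]]
  lines <- setdiff(levels(d$line_id), ref_id)
  p_adj <- vapply(lines, function(id) {
    hit <- cmp == paste0(id, "-", ref_id) | cmp == paste0(ref_id, "-", id)
    tk[hit, "p adj"][1]
  }, numeric(1))
  ratio <- as.numeric(means[lines]) / ref_mean
  flag <- ifelse(p_adj <= alpha_flag,
                 ifelse(ratio < 1, "smaller", "larger"), "ns")
  out <- data.frame(line_id = lines, ratio = ratio, p_adj = p_adj,
                    flag = flag, row.names = NULL)
  out <- out[order(out$line_id), ]
  rownames(out) <- NULL
  class(out) <- c("volcano_screen", "data.frame")
  out
}

#' @export
plot.volcano_screen <- function(x, alpha_flag = 0.01, ...) {
  col <- ifelse(x$flag == "ns", "grey50", "red")
  plot(log2(x$ratio), -log10(pmax(x$p_adj, 1e-16)), col = col, pch = 16,
       xlab = "log2 amplitude ratio vs reference",
       ylab = "-log10 adjusted p", ...)
  abline(h = -log10(alpha_flag), lty = 2)
  invisible(x)
}

#' Fraction of screened lines called as hits, in whole percent
#'
#' @param n_hits number of flagged lines.
#' @param n_total number of lines tested.
#' @return the hit fraction as a percentage truncated to a whole number.
#' @export
hit_rate_percent <- function(n_hits, n_total) {
  check_that(is_scalar_num(n_hits) && is_scalar_num(n_total) && n_total > 0,
             "need counts with n_total > 0")
  floor(100 * n_hits / n_total)
}

#' Two-way factorial test for PHP designs
#'
#' Type-II two-way ANOVA (genotype x condition) with Tukey HSD post hoc
#' comparisons, suited to the unbalanced group sizes typical of NMJ
#' recordings. A design in which every observation is identical is
#' degenerate and reported as p = 1 with a warning.
#'
#' @param values numeric response (per-cell metric).
#' @param genotype,condition factors of the 2-way design; at least two
#'   levels each and at least two observations per design cell.
#' @return a list with `anova` (type-II table: data frame with rows
#'   genotype, condition, interaction), `tukey` (TukeyHSD of the cell
#'   means) and `p_interaction`.
#' @export
twoway_php_test <- function(values, genotype, condition) {
  genotype <- factor(genotype); condition <- factor(condition)
  check_that(nlevels(genotype) >= 2 && nlevels(condition) >= 2,
             "need >= 2 levels per factor")
  cell_n <- table(genotype, condition)
  check_that(all(cell_n >= 2), "every design cell needs >= 2 observations")
  if (var(values) == 0) {
    warning("all observations identical: degenerate design, p = 1")
    an <- data.frame(term = c("genotype", "condition", "genotype:condition"),
                     F = NA_real_, p = 1)
    return(list(anova = an, tukey = NULL, p_interaction = 1))
  }
  fit <- lm(values ~ genotype * condition)
  a2 <- car::Anova(fit, type = 2)
  an <- data.frame(term = rownames(a2)[1:3],
                   F = a2[1:3, "F value"], p = a2[1:3, "Pr(>F)"])
  tukey <- TukeyHSD(aov(values ~ genotype:condition))
  list(anova = an, tukey = tukey, p_interaction = an$p[3])
}

#' Assumption-gated two-group comparison
#'
#' Chooses the two-group test the way screening practice does: if either
#' group fails a Shapiro-Wilk normality test at `alpha_gate`, a two-sided
#' Mann-Whitney U test is used; if normality passes but a Levene test
#' (classical, mean-centered) rejects variance homogeneity, a Welch t-test
#' is used; otherwise a two-sided Student's t-test. Constant groups make
#' Shapiro-Wilk undefined and fall through to Mann-Whitney with a warning.
#'
#' @param x,y numeric samples, each with at least 3 observations.
#' @param alpha_gate significance level of the assumption gates
#'   (default 0.05).
#' @return an object of class `two_group_test`: `test_used` in
#'   {student_t, welch_t, mann_whitney}, `p`, `normality_p` (length 2),
#'   `levene_p`, and the group means.
#' @export
compare_two <- function(x, y, alpha_gate = 0.05) {
  check_that(length(x) >= 3 && length(y) >= 3, "each group needs n >= 3")
  sw <- function(v) {
    if (length(unique(v)) == 1L) return(NA_real_)
    shapiro.test(v)$p.value
  }
  norm_p <- c(sw(x), sw(y))
  lev_p <- NA_real_
  if (anyNA(norm_p)) {
    warning("zero-variance group: falling back to Mann-Whitney")
    test_used <- "mann_whitney"
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
  } else if (any(norm_p < alpha_gate)) {
    test_used <- "mann_whitney"
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
  } else {
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    lev_p <- car::leveneTest(c(x, y), g, center = "mean")[1, "Pr(>F)"]
    if (lev_p < alpha_gate) {
      test_used <- "welch_t"
      p <- t.test(x, y, var.equal = FALSE)$p.value
    } else {
      test_used <- "student_t"
      p <- t.test(x, y, var.equal = TRUE)$p.value
    }
  }
  structure(list(test_used = test_used, p = p, normality_p = norm_p,
                 levene_p = lev_p, mean_x = mean(x), mean_y = mean(y)),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, ...) {
  cat(sprintf("two-group comparison: %s, p = %.4g (means %.4g vs %.4g)\n",
              x$test_used, x$p, x$mean_x, x$mean_y))
  invisible(x)
}

# Exact two-sided two-sample t-test power at effect size d, n per group.
# pnt's "full precision" warning fires at irrelevant magnitudes; silenced.
t_power <- function(d, n, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- qt(1 - alpha / 2, df)
  suppressWarnings(
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp))
}

#' Minimum sample size for a two-sample t-test
#'
#' Smallest integer group size n such that the two-sided two-sample
#' t-test reaches the target power at standardized effect size `cohens_d`,
#' evaluated with the noncentral t distribution. The smallest admissible
#' design is n = 2 per group (one residual degree of freedom per group).
#'
#' @param cohens_d standardized effect size, > 0.
#' @param power target power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @return integer n per group.
#' @export
min_n_power <- function(cohens_d, power = 0.8, alpha = 0.05) {
  check_that(is_scalar_num(cohens_d) && cohens_d > 0, "cohens_d must be > 0")
  check_that(is_scalar_num(power) && power > 0 && power < 1,
             "power must be in (0, 1)")
  n <- 2L
  while (t_power(cohens_d, n, alpha) < power) {
    n <- n + 1L
    if (n > 1e6L) stop("sample size exceeds 1e6; effect size too small")
  }
  n
}
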