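## Synthetic electrophysiology screen tables: per-line NMJ means under PhTX
## with WT reference groups, plus a two-arm PHP cohort generator.

#' Parameters for screen-table simulation
#'
#' Settings for [simulate_screen()]. Each screened line is recorded under
#' PhTX; the toxin scales quantal size by `phtx_q_scale` (~0.6, i.e. a ~40%
#' mEPSP reduction). PHP-competent lines homeostatically scale quantal
#' content by the reciprocal so their evoked amplitude is conserved;
#' PHP-deficient lines do not, so their EPSC falls to
#' `phtx_q_scale * wt_epsc`. WT reference groups with and without PhTX are
#' emitted alongside.
#'
#' @param n_lines number of screened lines (default 180).
#' @param nmjs_per_line NULL to draw counts with mean ~4 on range 3..12
#'   (3 + a geometric(1/2) excess, capped at 12), or a fixed integer.
#' @param wt_mepsp wild-type mean mEPSP amplitude (mV).
#' @param wt_epsc wild-type mean EPSC amplitude (nA).
#' @param phtx_q_scale multiplicative quantal-size factor under PhTX (0.6).
#' @param frac_php_deficient fraction of lines lacking PHP.
#' @param between_nmj_cv CV of per-NMJ multiplicative noise.
#' @param n_wt number of NMJs in each WT reference group (default 16).
#' @param seed integer RNG seed or NULL.
#' @return an object of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_lines = 180L, nmjs_per_line = NULL,
                              wt_mepsp = 0.8, wt_epsc = 70,
                              phtx_q_scale = 0.6, frac_php_deficient = 0,
                              between_nmj_cv = 0.15, n_wt = 16L,
                              seed = NULL) {
  check_that(is_scalar_num(n_lines) && n_lines >= 0, "n_lines must be >= 0")
  check_that(is.null(nmjs_per_line) ||
               (is_scalar_num(nmjs_per_line) && nmjs_per_line >= 3 &&
                  nmjs_per_line <= 12),
             "nmjs_per_line must be NULL or an integer in [3, 12]")
  check_that(is_scalar_num(wt_mepsp) && wt_mepsp > 0, "wt_mepsp must be > 0")
  check_that(is_scalar_num(wt_epsc) && wt_epsc > 0, "wt_epsc must be > 0")
  check_that(is_scalar_num(phtx_q_scale) && phtx_q_scale > 0 &&
               phtx_q_scale <= 1, "phtx_q_scale must be in (0, 1]")
  check_that(is_scalar_num(frac_php_deficient) && frac_php_deficient >= 0 &&
               frac_php_deficient <= 1, "frac_php_deficient must be in [0, 1]")
  check_that(is_scalar_num(between_nmj_cv) && between_nmj_cv >= 0,
             "between_nmj_cv must be >= 0")
  check_that(is_scalar_num(n_wt) && n_wt >= 3, "n_wt must be >= 3")
  structure(list(n_lines = as.integer(n_lines),
                 nmjs_per_line = nmjs_per_line,
                 wt_mepsp = wt_mepsp, wt_epsc = wt_epsc,
                 phtx_q_scale = phtx_q_scale,
                 frac_php_deficient = frac_php_deficient,
                 between_nmj_cv = between_nmj_cv,
                 n_wt = as.integer(n_wt), seed = seed),
            class = "screen_sim_params")
}

# NMJ-count draw: 3 + geometric(1/2) excess capped at 9 -> mean ~ 4,
# range [3, 12], mode 3 (small-cohort screening practice).
draw_nmj_counts <- function(n) 3L + pmin(rgeom(n, 0.5), 9L)

screen_rows <- function(line_id, genotype_class, condition, mepsp, epsc) {
  n <- length(mepsp)
  data.frame(line_id = line_id, genotype_class = genotype_class,
             condition = condition, nmj_id = seq_len(n),
             modality = rep(c("mEPSP", "EPSC"), each = n),
             value = c(mepsp, epsc))
}

#' Simulate a PHP screen table
#'
#' Generates per-NMJ mean mEPSP and mean EPSC amplitudes for `n_lines`
#' screened lines recorded under PhTX, together with WT reference groups
#' with and without PhTX, in the long screen-table format used throughout
#' the package.
#'
#' @param params a [screen_sim_params()] object.
#' @return a list with `table` (class `screen_table`: columns `line_id`,
#'   `genotype_class`, `condition`, `nmj_id`, `modality`, `value`) and
#'   `truth`, a data frame of per-line PHP labels and true EPSC scale.
#' @export
simulate_screen <- function(params) {
  stopifnot(inherits(params, "screen_sim_params"))
  p <- params
  with_seed(p$seed, {
    noise <- function(n) 1 + rnorm(n, 0, p$between_nmj_cv)
    out <- list()
    ## WT reference groups
    out$wt_ctrl <- screen_rows("WT", "wt_ref", "control",
                               p$wt_mepsp * noise(p$n_wt),
                               p$wt_epsc * noise(p$n_wt))
    out$wt_phtx <- screen_rows("WT", "wt_ref", "PhTX",
                               p$wt_mepsp * p$phtx_q_scale * noise(p$n_wt),
                               p$wt_epsc * noise(p$n_wt))
    truth <- NULL
    if (p$n_lines > 0) {
      deficient <- runif(p$n_lines) < p$frac_php_deficient
      counts <- if (is.null(p$nmjs_per_line)) draw_nmj_counts(p$n_lines)
                else rep(as.integer(p$nmjs_per_line), p$n_lines)
      ids <- sprintf("line%03d", seq_len(p$n_lines))
      line_rows <- lapply(seq_len(p$n_lines), function(i) {
        s <- if (deficient[i]) p$phtx_q_scale else 1
        n <- counts[i]
        screen_rows(ids[i], "line", "PhTX",
                    p$wt_mepsp * p$phtx_q_scale * noise(n),
                    p$wt_epsc * s * noise(n))
      })
      out <- c(out, line_rows)
      truth <- data.frame(line_id = ids, php_deficient = deficient,
                          epsc_scale = ifelse(deficient, p$phtx_q_scale, 1),
                          n_nmjs = counts)
    }
    table <- do.call(rbind, out)
    rownames(table) <- NULL
    class(table) <- c("screen_table", "data.frame")
    list(table = table, truth = truth, params = p)
  })
}

#' Simulate a two-arm PHP experiment for one genotype
#'
#' Generates per-NMJ mean mEPSC and EPSC amplitudes for an untreated
#' (control) and a PhTX-treated arm of a single genotype, mirroring the
#' paired PhTX experiments used to normalize quantal content to untreated
#' controls. PhTX scales quantal size by `phtx_q_scale`; if `php_competent`,
#' quantal content scales by the reciprocal so the evoked amplitude is
#' conserved, otherwise the EPSC falls proportionally.
#'
#' @param php_competent logical; does the genotype express PHP?
#' @param n_per_arm NMJs per arm (mEPSC and EPSC cells drawn separately, as
#'   the two modalities are recorded from different NMJs).
#' @param wt_mepsc,wt_epsc untreated means (signal units).
#' @param phtx_q_scale quantal-size factor under PhTX.
#' @param between_nmj_cv per-NMJ multiplicative noise CV.
#' @param seed integer RNG seed or NULL.
#' @return a `screen_table`-classed data frame with `condition` in
#'   {control, PhTX} and `modality` in {mEPSP, EPSC}; `line_id` is
#'   "competent" or "deficient".
#' @export
simulate_php_experiment <- function(php_competent = TRUE, n_per_arm = 20L,
                                    wt_mepsc = 0.8, wt_epsc = 70,
                                    phtx_q_scale = 0.6,
                                    between_nmj_cv = 0.1, seed = NULL) {
  check_that(is_scalar_num(n_per_arm) && n_per_arm >= 3,
             "n_per_arm must be >= 3")
  with_seed(seed, {
    noise <- function(n) 1 + rnorm(n, 0, between_nmj_cv)
    id <- if (php_competent) "competent" else "deficient"
    epsc_scale <- if (php_competent) 1 else phtx_q_scale
    tab <- rbind(
      screen_rows(id, "line", "control",
                  wt_mepsc * noise(n_per_arm), wt_epsc * noise(n_per_arm)),
      screen_rows(id, "line", "PhTX",
                  wt_mepsc * phtx_q_scale * noise(n_per_arm),
                  wt_epsc * epsc_scale * noise(n_per_arm)))
    rownames(tab) <- NULL
    class(tab) <- c("screen_table", "data.frame")
    tab
  })
}
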