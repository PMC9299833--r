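## Pipeline orchestration: a single config drives simulate -> detect ->
## quantify -> test stages with deterministic per-stage seeds and an
## output manifest.

# Deterministic per-stage seed: a 31-bit polynomial hash of the stage name
# folded into the global seed, so adding stages never shifts the streams
# of existing stages.
stage_seed <- function(global_seed, stage) {
  h <- as.double(global_seed) %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run a configured analysis pipeline
#'
#' Executes the configured stages in a fixed dependency order
#' (`minis`, `trains`, `screen`, `boutons`, `detect`, `quantal`,
#' `screen_stats`, `nnd`), writing every stage's outputs into `out_dir`
#' and collecting them in a manifest. All randomness derives from the
#' global seed via a stable per-stage hash, so a rerun with the same
#' config is byte-identical.
#'
#' `config` is a named list (or path to a JSON/YAML file) with fields
#' `seed`, `out_dir`, `stages` (character vector) and one optional
#' parameter block per stage. `detect` consumes the trace written by
#' `minis` unless `config$detect$trace` points at an existing file;
#' `quantal` consumes the `trains` output, `screen_stats` the `screen`
#' output, `nnd` the `boutons` output, under the same override rule.
#'
#' @param config named list or path to a JSON (or YAML) config file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return an object of class `pipeline_report`: `manifest` (named list of
#'   output files), `results` (per-stage R objects), `config`, `seed`,
#'   `elapsed_s`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(config) && length(config) == 1L) {
    check_that(file.exists(config), paste0("config file not found: ", config))
    config <- if (grepl("\\.ya?ml$", config)) yaml_read(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  check_that(is.list(config), "config must be a list or a file path")
  seed <- config$seed
  check_that(is_scalar_num(seed), "config$seed must be a single number")
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("minis", "trains", "screen", "boutons")
  known <- c("minis", "trains", "screen", "boutons",
             "detect", "quantal", "screen_stats", "nnd")
  bad <- setdiff(stages, known)
  check_that(length(bad) == 0, paste0("unknown stage(s): ",
                                      paste(bad, collapse = ", ")))
  stages <- known[known %in% stages]   # dependency order
  manifest <- list()
  results <- list()
  out <- function(name) file.path(out_dir, name)
  need_file <- function(path, stage) {
    check_that(file.exists(path),
               sprintf("dependency error in stage '%s': missing input %s",
                       stage, path))
    path
  }
  arg <- function(stage) config[[stage]] %||% list()

  for (stage in stages) {
    s <- stage_seed(seed, stage)
    if (stage == "minis") {
      p <- do.call(mini_sim_params, c(arg("minis"), list(seed = s)))
      sim <- simulate_minis(p)
      write_trace(sim$trace, out("trace.csv"), meta = list(seed = s))
      utils::write.csv(sim$truth, out("trace_truth.csv"), row.names = FALSE)
      manifest$minis <- c(out("trace.csv"), out("trace_truth.csv"))
      results$minis <- sim
    } else if (stage == "trains") {
      p <- do.call(quantal_model_params, c(arg("trains"), list(seed = s)))
      sim <- simulate_trains(p)
      write_trains(sim$trains, out("trains.csv"))
      manifest$trains <- out("trains.csv")
      results$trains <- sim
    } else if (stage == "screen") {
      p <- do.call(screen_sim_params, c(arg("screen"), list(seed = s)))
      sim <- simulate_screen(p)
      write_screen(sim$table, out("screen.csv"))
      if (!is.null(sim$truth))
        utils::write.csv(sim$truth, out("screen_truth.csv"),
                         row.names = FALSE)
      manifest$screen <- out("screen.csv")
      results$screen <- sim
    } else if (stage == "boutons") {
      a <- arg("boutons")
      n_boutons <- a$n_boutons %||% 13L
      a$n_boutons <- NULL
      sims <- lapply(seq_len(n_boutons), function(i) {
        p <- do.call(bouton_sim_params,
                     c(a, list(seed = stage_seed(s, paste0("bouton", i)))))
        simulate_boutons(p)
      })
      geoms <- lapply(sims, `[[`, "geometry")
      write_boutons(geoms, out("boutons.json"))
      manifest$boutons <- out("boutons.json")
      results$boutons <- sims
    } else if (stage == "detect") {
      a <- arg("detect")
      trace <- if (!is.null(a$trace))
        read_trace(need_file(a$trace, "detect"))
      else if (!is.null(results$minis)) results$minis$trace
      else read_trace(need_file(out("trace.csv"), "detect"))
      tmpl <- build_template(a$rise_tau %||% 0.5, a$decay_tau %||% 5,
                             dt = trace$dt)
      ev <- cb_detect(trace, tmpl, threshold = a$threshold %||% 4)
      utils::write.csv(as.data.frame(ev), out("events.csv"),
                       row.names = FALSE)
      manifest$detect <- out("events.csv")
      results$detect <- ev
    } else if (stage == "quantal") {
      a <- arg("quantal")
      trains <- if (!is.null(a$trains))
        read_trains(need_file(a$trains, "quantal"))
      else if (!is.null(results$trains)) results$trains$trains
      else read_trains(need_file(out("trains.csv"), "quantal"))
      fit <- rrp_fit(trains, group_mepsc = a$group_mepsc %||% 1,
                     last_k = a$last_k %||% 15L)
      metrics <- data.frame(intercept = fit$estimate$intercept,
                            slope = fit$estimate$slope,
                            rrp_quanta = fit$estimate$rrp_quanta,
                            p_r = fit$p_r, ppr = fit$ppr)
      utils::write.csv(metrics, out("rrp_metrics.csv"), row.names = FALSE)
      manifest$quantal <- out("rrp_metrics.csv")
      results$quantal <- fit
    } else if (stage == "screen_stats") {
      a <- arg("screen_stats")
      tab <- if (!is.null(a$table))
        read_screen(need_file(a$table, "screen_stats"))
      else if (!is.null(results$screen)) results$screen$table
      else read_screen(need_file(out("screen.csv"), "screen_stats"))
      volcano <- volcano_screen(tab, alpha_flag = a$alpha %||% 0.01)
      utils::write.csv(as.data.frame(volcano), out("volcano.csv"),
                       row.names = FALSE)
      manifest$screen_stats <- out("volcano.csv")
      results$screen_stats <- volcano
    } else if (stage == "nnd") {
      a <- arg("nnd")
      geoms <- if (!is.null(a$boutons))
        read_boutons(need_file(a$boutons, "nnd"))
      else if (!is.null(results$boutons))
        lapply(results$boutons, `[[`, "geometry")
      else read_boutons(need_file(out("boutons.json"), "nnd"))
      nt <- mc_nnd_test(geoms, n_rand = a$n_rand %||% 100L, seed = s)
      utils::write.csv(nt$boutons, out("nnd.csv"), row.names = FALSE)
      jsonlite::write_json(list(p = nt$p, t = nt$t, n_rand = nt$n_rand,
                                paired = nt$paired, seed = s),
                           out("nnd_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      manifest$nnd <- c(out("nnd.csv"), out("nnd_summary.json"))
      results$nnd <- nt
    }
  }
  report <- structure(
    list(manifest = manifest, results = results, config = config,
         seed = seed,
         version = as.character(utils::packageVersion("synhomeo")),
         elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "pipeline_report")
  missing <- unlist(manifest)[!file.exists(unlist(manifest))]
  check_that(length(missing) == 0,
             paste0("declared outputs missing: ",
                    paste(missing, collapse = ", ")))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %s, %.2f s): stages %s\n",
              format(x$seed), x$elapsed_s,
              paste(names(x$manifest), collapse = ", ")))
  for (nm in names(x$manifest))
    cat(sprintf("  %s: %s\n", nm,
                paste(basename(x$manifest[[nm]]), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

yaml_read <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML configs")
  yaml::read_yaml(path)
}
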