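#' Default pipeline configuration
#'
#' Stage toggles, output paths, module settings and the master seed for an
#' end-to-end run (simulate -> psychophysics -> RLF -> FRA -> spike distance
#' -> decode -> report). Decoder trial counts default to a reduced size
#' suitable for interactive runs; raise `decoder$n_trials` / `n_runs` for
#' full-scale experiments.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides merged into the defaults (named lists are merged
#'   recursively).
#' @return configuration list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("freqdisc_run_"), seed = 1,
                           ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    stages = list(simulate = TRUE, behavior = TRUE, psychophysics = TRUE,
                  rlf = TRUE, fra = TRUE, spikedist = TRUE, decode = TRUE),
    simulate = list(regimes = c("WT", "KO-ACx"), n_units = 8, n_trials = 30,
                    n_freqs = 20, f_range = c(1, 64),
                    levels = seq(0, 90, by = 10)),
    behavior = list(n_sessions = 4, n_trials = 300),
    decoder = list(n_neurons = 640, f_range = c(1, 64), n_trials = 1000,
                   n_runs = 5, go_freqs = c(4, 8, 16, 32),
                   offsets = c(-12:-1, 1:12)))
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      utils::modifyList(cfg[[nm]], overrides[[nm]]) else overrides[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return a `run_config` list (defaults filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on synthetic cohorts
#' and writes per-stage CSV outputs plus a JSON manifest recording files,
#' seeds and record counts. All randomness derives from the master seed, so
#' reruns with the same configuration are bit-identical.
#'
#' @param config a [default_config()] / [read_run_config()] configuration.
#' @return the manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, out_dir = config$out_dir,
                   package_version = as.character(utils::packageVersion("freqdisc")),
                   stages = list(), files = character())
  add_file <- function(path, n) {
    manifest$files <<- c(manifest$files, path)
    n
  }
  cohorts <- NULL
  stage <- function(name, fn) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      path <- file.path(config$out_dir, "manifest.json")
      jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- res
  }

  stage("simulate", function() {
    grid <- default_grid(config$simulate$n_freqs, config$simulate$f_range,
                         config$simulate$levels)
    cohorts <<- lapply(config$simulate$regimes, function(lab) {
      regime <- stock_regime(lab, n_units = config$simulate$n_units)
      co <- gen_cohort(regime, grid = grid,
                       n_trials = config$simulate$n_trials,
                       seed = derive_seed(config$seed, "cohort", lab))
      path <- file.path(config$out_dir, sprintf("spikes_%s.csv", lab))
      write_spike_table(co$matrices, path)
      add_file(path, NA)
      co
    })
    names(cohorts) <<- config$simulate$regimes
    list(status = "ok", n_units = config$simulate$n_units,
         regimes = config$simulate$regimes)
  })

  stage("behavior", function() {
    rows <- lapply(seq_len(config$behavior$n_sessions), function(i) {
      params <- behavior_gen_params(n_trials = config$behavior$n_trials)
      mode <- if (i %% 2 == 1) "detection" else "discrimination"
      gen_behavior_session(params, mode = mode,
                           seed = derive_seed(config$seed, "beh", i),
                           session_id = sprintf("s%02d", i))
    })
    tab <- do.call(rbind, rows)
    path <- file.path(config$out_dir, "behavior.csv")
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    add_file(path, NA)
    list(status = "ok", n_trials = nrow(tab))
  })

  stage("psychophysics", function() {
    path_in <- file.path(config$out_dir, "behavior.csv")
    tab <- utils::read.csv(path_in, stringsAsFactors = FALSE)
    out <- lapply(split(tab, tab$session_id), function(sess) {
      r <- compute_session_rates(sess)
      row <- data.frame(session_id = sess$session_id[1], n_go = r$n_go,
                        n_nogo = r$n_nogo, n_catch = r$n_catch,
                        hit_rate = r$hit_rate, fa_rate = r$fa_rate,
                        threshold_db = NA_real_)
      if (r$n_catch > 0 && length(unique(stats::na.omit(sess$level_db))) > 1) {
        thr <- detection_threshold(psychometric_table(sess))
        row$threshold_db <- thr$threshold_db
      }
      row
    })
    res <- do.call(rbind, out)
    path <- file.path(config$out_dir, "psychophysics.csv")
    utils::write.csv(res, path, row.names = FALSE, na = "")
    add_file(path, NA)
    list(status = "ok", n_sessions = nrow(res))
  })

  analysis_per_unit <- function() {
    lapply(cohorts, function(co) {
      mets <- lapply(co$matrices, extract_fra_metrics)
      fits <- lapply(seq_along(co$matrices), function(i) {
        m <- mets[[i]]
        if (!m$resolved) return(NULL)
        fit_rlf(build_cf_rlf(co$matrices[[i]], m$cf))
      })
      list(metrics = mets, fits = fits[!vapply(fits, is.null, logical(1))])
    })
  }
  analyses <- NULL
  get_analyses <- function() {
    if (is.null(analyses)) analyses <<- analysis_per_unit()
    analyses
  }

  stage("fra", function() {
    tab <- do.call(rbind, lapply(get_analyses(), function(a)
      fra_metrics_table(a$metrics)))
    path <- file.path(config$out_dir, "fra_metrics.csv")
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    add_file(path, NA)
    list(status = "ok", n_units = nrow(tab))
  })

  stage("rlf", function() {
    fits <- unlist(lapply(get_analyses(), `[[`, "fits"), recursive = FALSE)
    filt <- filter_fits(fits)
    tab <- rlf_fits_table(fits)
    path <- file.path(config$out_dir, "rlf_fits.csv")
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    add_file(path, NA)
    list(status = "ok", n_fits = length(fits),
         n_admitted = length(filt$admitted))
  })

  stage("spikedist", function() {
    a <- get_analyses()
    rows <- lapply(names(a), function(lab) {
      co <- cohorts[[lab]]
      mets <- a[[lab]]$metrics
      do.call(rbind, lapply(seq_along(co$matrices), function(i) {
        if (!mets[[i]]$resolved) return(NULL)
        tryCatch(delta_distance_vs_cf(co$matrices[[i]], mets[[i]]),
                 error = function(e) NULL)
      }))
    })
    tab <- do.call(rbind, rows)
    path <- file.path(config$out_dir, "spike_distance.csv")
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    add_file(path, NA)
    list(status = "ok", n_rows = nrow(tab))
  })

  stage("decode", function() {
    a <- get_analyses()
    rows <- lapply(names(a), function(lab) {
      fra_tab <- fra_metrics_table(a[[lab]]$metrics)
      rlf_tab <- rlf_fits_table(filter_fits(a[[lab]]$fits)$admitted)
      summ <- tuning_summary_from_analysis(fra_tab, rlf_tab, label = lab)
      pop <- build_population(summ, n = config$decoder$n_neurons,
                              f_range = config$decoder$f_range)
      res <- run_discrimination_experiment(
        pop, go_freqs = config$decoder$go_freqs,
        offsets = config$decoder$offsets,
        n_trials = config$decoder$n_trials, n_runs = config$decoder$n_runs,
        seed = derive_seed(config$seed, "decode", lab))
      res$population <- lab
      res
    })
    tab <- do.call(rbind, rows)
    path <- file.path(config$out_dir, "decoder_errors.csv")
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    add_file(path, NA)
    list(status = "ok", n_rows = nrow(tab))
  })

  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Reads the per-stage CSVs referenced by a run manifest and produces tidy
#' summary tables (and, when `ggplot2` is available and `make_plots` is
#' `TRUE`, summary figures: FA versus octave distance, Q-value distributions,
#' delta spike-distance curves and decoder error curves). Re-running the
#' report on the same manifest is idempotent.
#'
#' @param out_dir the run's output directory (containing `manifest.json`).
#' @param make_plots write PDF figures under `<out_dir>/figures/`.
#' @return list of summary data.frames, invisibly; summaries are also
#'   written as `summary_*.csv` files.
#' @export
pipeline_report <- function(out_dir, make_plots = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) stopf("missing file: %s", manifest_path)
  summaries <- list()
  grab <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  fra <- grab("fra_metrics.csv")
  if (!is.null(fra)) {
    qs <- lapply(c(10, 20, 30, 40), function(off) {
      col <- sprintf("q%d", off)
      do.call(rbind, lapply(split(fra, fra$genotype), function(g)
        data.frame(genotype = g$genotype[1], delta_db = off,
                   mean_q = mean(g[[col]], na.rm = TRUE),
                   n = sum(!is.na(g[[col]])))))
    })
    summaries$q_values <- do.call(rbind, qs)
  }
  sd_tab <- grab("spike_distance.csv")
  if (!is.null(sd_tab)) {
    sd_tab$abs_oct <- abs(sd_tab$octave_distance)
    summaries$spike_distance <- do.call(rbind, lapply(
      split(sd_tab, list(sd_tab$genotype, round(sd_tab$abs_oct, 3)),
            drop = TRUE),
      function(g) data.frame(genotype = g$genotype[1],
                             octave_distance = g$abs_oct[1],
                             mean_delta = mean(g$delta_distance),
                             n = nrow(g))))
  }
  dec <- grab("decoder_errors.csv")
  if (!is.null(dec)) {
    summaries$decoder <- do.call(rbind, lapply(
      split(dec, list(dec$population, dec$octave_distance), drop = TRUE),
      function(g) data.frame(population = g$population[1],
                             octave_distance = g$octave_distance[1],
                             mean_error = mean(g$error_rate),
                             n = nrow(g))))
  }
  psy <- grab("psychophysics.csv")
  if (!is.null(psy)) summaries$psychophysics <- psy
  for (nm in names(summaries)) {
    utils::write.csv(summaries[[nm]],
                     file.path(out_dir, sprintf("summary_%s.csv", nm)),
                     row.names = FALSE, na = "")
  }
  if (make_plots && requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create(file.path(out_dir, "figures"), showWarnings = FALSE)
    if (!is.null(summaries$decoder)) {
      p <- ggplot2::ggplot(summaries$decoder,
                           ggplot2::aes(octave_distance, mean_error,
                                        colour = population)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "octave distance", y = "decoder error rate")
      ggplot2::ggsave(file.path(out_dir, "figures", "decoder_error.pdf"), p,
                      width = 5, height = 4)
    }
    if (!is.null(summaries$spike_distance)) {
      p <- ggplot2::ggplot(summaries$spike_distance,
                           ggplot2::aes(octave_distance, mean_delta,
                                        colour = genotype)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "octave distance from CF",
                      y = "delta SPIKE-distance")
      ggplot2::ggsave(file.path(out_dir, "figures", "spike_distance.pdf"), p,
                      width = 5, height = 4)
    }
  }
  invisible(summaries)
}
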