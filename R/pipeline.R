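#' Validate a pipeline configuration
#'
#' Checks a configuration (a list, or a path to a YAML/JSON file) against the
#' pipeline schema and reports *all* problems at once. A configuration names
#' one or more groups; each group provides exactly one of `simulation` (a
#' [prw_sim_config()] field list) or `tracks` (a track-table path, with
#' optional `format` and `pixel_size`).
#'
#' Top-level keys: `seed` (integer), `output_dir`, `frame_interval` (min),
#' optional `msd` (`max_lag_fraction`, `pooling`), `fit` (`weighting`),
#' `stats` (`alpha`, `m_rule`), and `groups`.
#'
#' @param config A named list or a path to a YAML or JSON configuration
#'   file.
#' @return The validated configuration with defaults filled in, classed
#'   `pipeline_config`. Invalid configurations raise one error enumerating
#'   every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)

  if (is.null(config$seed) || !is.numeric(config$seed)) {
    add("missing or non-numeric key 'seed'")
  }
  if (is.null(config$frame_interval)) {
    add("missing key 'frame_interval'")
  } else if (!is.numeric(config$frame_interval) ||
             config$frame_interval <= 0) {
    add("'frame_interval' must be a positive number")
  }
  if (is.null(config$output_dir)) add("missing key 'output_dir'")
  if (is.null(config$groups) || !is.list(config$groups) ||
      length(config$groups) == 0 || is.null(names(config$groups))) {
    add("missing key 'groups' (named list of group specs)")
  } else {
    for (g in names(config$groups)) {
      spec <- config$groups[[g]]
      has_sim <- !is.null(spec$simulation)
      has_trk <- !is.null(spec$tracks)
      if (has_sim && has_trk) {
        add(paste0("group '", g,
                   "': give exactly one of 'simulation' or 'tracks', not both"))
      } else if (!has_sim && !has_trk) {
        add(paste0("group '", g, "': needs 'simulation' or 'tracks'"))
      }
      if (has_trk && !has_sim && !file.exists(spec$tracks)) {
        add(paste0("group '", g, "': track file not found: ", spec$tracks))
      }
      if (has_sim && !has_trk) {
        for (key in c("speed_S", "persistence_P")) {
          if (is.null(spec$simulation[[key]])) {
            add(paste0("group '", g, "': simulation is missing '", key, "'"))
          }
        }
      }
    }
  }
  msd <- config$msd %||% list()
  if (!is.null(msd$max_lag_fraction) &&
      (msd$max_lag_fraction <= 0 || msd$max_lag_fraction > 1)) {
    add("'msd.max_lag_fraction' must be in (0, 1]")
  }
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  config$msd <- list(max_lag_fraction = msd$max_lag_fraction %||% 0.5,
                     pooling = msd$pooling %||% "pooled")
  config$fit <- list(weighting = (config$fit %||% list())$weighting %||%
                       "none")
  config$stats <- list(alpha = (config$stats %||% list())$alpha %||% 0.05,
                       m_rule = (config$stats %||% list())$m_rule %||% "lags")
  class(config) <- "pipeline_config"
  config
}

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, digits = 10, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full motility analysis pipeline
#'
#' Orchestrates simulation (or track reading), MSD estimation, persistent
#' random walk fitting and between-group statistics for every group in a
#' validated configuration, writing all artifacts under
#' `config$output_dir`:
#'
#' * `tracks_<group>.csv` (+ sidecar) — the analyzed tracks;
#' * `msd_group_<group>.csv`, `msd_cells_<group>.csv` — pooled and per-cell
#'   MSD;
#' * `fits.csv` — S, P, mu and diagnostics per group;
#' * `per_lag_comparisons.csv`, `anova_overall.csv`, `speed_ttests.csv` —
#'   between-group statistics (when >= 2 groups);
#' * `report.md` — human-readable summary tables;
#' * `manifest.json` — seed, configuration, its MD5 hash and the package
#'   version (sufficient to reproduce the run);
#' * `log.txt` — per-stage log with exclusion counts.
#'
#' Simulated group `i` uses the derived seed `seed + i`, so a configuration
#' plus its seed fully determines every output byte. A stage failure halts
#' the run with the stage name and leaves a `FAILED` marker file next to the
#' partial outputs.
#'
#' @param config A [validate_config()] result, or a list/path accepted by
#'   it.
#' @param output_dir Optional override of `config$output_dir`.
#' @return Invisibly, a list with per-group `track_sets`, `curves`, `fits`,
#'   the `comparisons`, and `paths` of all written artifacts.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_add <- function(...) log_lines <<- c(log_lines, paste0(...))
  paths <- list()
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    groups <- names(config$groups)
    track_sets <- list()
    stage <- "tracks"
    for (i in seq_along(groups)) {
      g <- groups[i]
      spec <- config$groups[[g]]
      if (!is.null(spec$simulation)) {
        sim <- spec$simulation
        ts <- simulate_prw(prw_sim_config(
          speed_S = sim$speed_S, persistence_P = sim$persistence_P,
          n_cells = sim$n_cells %||% 50L, n_frames = sim$n_frames %||% 11L,
          frame_interval = sim$frame_interval %||% config$frame_interval,
          localization_noise_sd = sim$localization_noise_sd %||% 0,
          seed = sim$seed %||% (as.integer(config$seed) + i),
          group_label = g))
        log_add("tracks: simulated group '", g, "' (",
                length(ts), " cells, derived seed ",
                sim$seed %||% (as.integer(config$seed) + i), ")")
      } else {
        ts <- read_tracks(spec$tracks,
                          format = spec$format %||% "generic_csv",
                          pixel_size = spec$pixel_size,
                          frame_interval = config$frame_interval,
                          group_label = g)
        excl <- attr(ts, "excluded")
        log_add("tracks: read group '", g, "' from ", spec$tracks, " (",
                length(ts), " cells kept, ", nrow(excl), " excluded)")
        if (nrow(excl)) {
          log_add("  excluded: ",
                  paste(excl$cell_id, "-", excl$reason, collapse = "; "))
        }
      }
      track_sets[[g]] <- ts
      p <- file.path(out_dir, paste0("tracks_", g, ".csv"))
      write_tracks(ts, p)
      paths[[paste0("tracks_", g)]] <- p
    }

    stage <- "msd"
    curves <- list()
    cell_tables <- list()
    for (g in groups) {
      curves[[g]] <- msd_curve(track_sets[[g]],
                               max_lag_fraction = config$msd$max_lag_fraction,
                               pooling = config$msd$pooling)
      cell_tables[[g]] <- per_cell_msd_table(
        track_sets[[g]], max_lag_fraction = config$msd$max_lag_fraction)
      paths[[paste0("msd_group_", g)]] <- write_num_csv(
        as.data.frame(curves[[g]]),
        file.path(out_dir, paste0("msd_group_", g, ".csv")))
      paths[[paste0("msd_cells_", g)]] <- write_num_csv(
        cell_tables[[g]], file.path(out_dir, paste0("msd_cells_", g, ".csv")))
      log_add("msd: group '", g, "', ", nrow(curves[[g]]) - 1,
              " positive lags")
    }

    stage <- "fit"
    fits <- lapply(curves, fit_prw, weighting = config$fit$weighting)
    fit_tab <- do.call(rbind, lapply(groups, function(g) {
      f <- fits[[g]]
      data.frame(group = g, S = f$coefficients[["S"]],
                 P = f$coefficients[["P"]], mu = f$mu,
                 rss = f$residual_sum_squares, n_lags = f$n_lags_used,
                 converged = f$converged, degenerate = f$degenerate)
    }))
    paths$fits <- write_num_csv(fit_tab, file.path(out_dir, "fits.csv"))
    for (g in groups) {
      log_add("fit: group '", g, "': S = ",
              format(fits[[g]]$coefficients[["S"]], digits = 6), ", P = ",
              format(fits[[g]]$coefficients[["P"]], digits = 6), ", mu = ",
              format(fits[[g]]$mu, digits = 6),
              if (fits[[g]]$degenerate) paste0(" [",
                fits[[g]]$degenerate_reason, "]") else "")
    }

    comparisons <- NULL
    if (length(groups) >= 2) {
      stage <- "stats"
      per_cell <- do.call(rbind, cell_tables)
      anova_res <- msd_anova(per_cell, m_rule = config$stats$m_rule)
      paths$per_lag <- write_num_csv(
        anova_res$per_lag, file.path(out_dir, "per_lag_comparisons.csv"))
      paths$anova_overall <- write_num_csv(
        anova_res$overall, file.path(out_dir, "anova_overall.csv"))
      speeds <- lapply(track_sets, function(ts) {
        vapply(ts$trajectories, empirical_speed, numeric(1))
      })
      pairs <- utils::combn(groups, 2, simplify = FALSE)
      speed_tests <- do.call(rbind, lapply(pairs, function(pr) {
        ttest_unpaired(speeds[[pr[1]]], speeds[[pr[2]]],
                       metric = "empirical_speed",
                       group_a = pr[1], group_b = pr[2])
      }))
      paths$speed_ttests <- write_num_csv(
        speed_tests, file.path(out_dir, "speed_ttests.csv"))
      comparisons <- list(msd_anova = anova_res, speed_ttests = speed_tests)
      log_add("stats: overall group-effect p = ",
              format(anova_res$overall$p_value[1], digits = 4),
              "; Bonferroni family m = ", anova_res$m)
    }

    stage <- "report"
    rpt <- c("# Motility analysis report", "",
             "## Persistent random walk fits", "",
             paste0("| group | S (um/min) | P (min) | mu (um^2/min) | ",
                    "converged |"),
             "|---|---|---|---|---|",
             vapply(groups, function(g) {
               f <- fits[[g]]
               sprintf("| %s | %.4f | %.4f | %.4f | %s |", g,
                       f$coefficients[["S"]], f$coefficients[["P"]], f$mu,
                       f$converged)
             }, character(1)), "")
    if (!is.null(comparisons)) {
      pl <- comparisons$msd_anova$per_lag
      rpt <- c(rpt, "## Per-lag MSD comparisons (Bonferroni adjusted)", "",
               "| lag (min) | statistic | p | p_adj |", "|---|---|---|---|",
               sprintf("| %.3g | %.4f | %.4g | %.4g |", pl$lag_min,
                       pl$statistic, pl$p_value, pl$adjusted_p), "")
    }
    paths$report <- file.path(out_dir, "report.md")
    writeLines(rpt, paths$report)

    stage <- "manifest"
    cfg_path <- file.path(out_dir, "config.yaml")
    plain_cfg <- unclass(config)
    yaml::write_yaml(plain_cfg, cfg_path)
    manifest <- list(
      package = "prwfit",
      version = as.character(utils::packageVersion("prwfit")),
      seed = as.integer(config$seed),
      config_md5 = unname(tools::md5sum(cfg_path)),
      config = plain_cfg)
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    paths$log <- file.path(out_dir, "log.txt")
    writeLines(log_lines, paths$log)
  }, error = on_fail)

  invisible(list(track_sets = track_sets, curves = curves, fits = fits,
                 comparisons = comparisons, paths = paths))
}
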