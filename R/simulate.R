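#' Simulation settings for persistent-random-walk tracks
#'
#' Bundles the true motility parameters and acquisition settings used by
#' [simulate_prw()]. Defaults mirror a typical bone-marrow neutrophil
#' time-lapse experiment: a 15-minute observation window sampled every
#' 1.5 minutes, with 45-60 cells per group.
#'
#' @param speed_S Root-mean-square cell speed, um/min. Must be >= 0.
#' @param persistence_P Velocity correlation (persistence) time, min. Must be
#'   > 0.
#' @param n_cells Number of cells (tracks) to simulate.
#' @param n_frames Number of recorded positions per track (>= 2). The default
#'   11 covers t = 0 to 15 min at the default 1.5-min frame interval.
#' @param frame_interval Time between recorded frames, min. The alternative
#'   acquisition interval of 0.5 min (images every 30 s) is equally valid.
#' @param localization_noise_sd Standard deviation of independent Gaussian
#'   localization error added to each recorded coordinate, um. Models
#'   centroid-finding error of the microscopy; it perturbs recorded positions
#'   only, never the underlying dynamics.
#' @param seed Master integer seed. Per-cell random streams are derived from
#'   it deterministically by cell index, so the same configuration always
#'   yields bit-identical tracks.
#' @param group_label Label attached to the resulting [track_set()].
#' @param substeps Integer >= 1; number of exact simulation steps per recorded
#'   frame. Positions are simulated at `frame_interval / substeps` and
#'   subsampled, which lets tests probe sampling effects. The exact
#'   discretization makes the statistics of recorded positions independent of
#'   `substeps`.
#' @return An object of class `prw_sim_config` (a validated list).
#' @seealso [simulate_prw()]
#' @export
prw_sim_config <- function(speed_S, persistence_P, n_cells = 50L,
                           n_frames = 11L, frame_interval = 1.5,
                           localization_noise_sd = 0, seed = 1L,
                           group_label = "group", substeps = 1L) {
  cfg <- list(speed_S = speed_S, persistence_P = persistence_P,
              n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              localization_noise_sd = localization_noise_sd,
              seed = as.integer(seed), group_label = as.character(group_label),
              substeps = as.integer(substeps))
  validate_sim_config(cfg)
  class(cfg) <- "prw_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid simulation config: field '", field, "' ",
                          msg, call. = FALSE)
  }
  chk(is.numeric(cfg$speed_S) && length(cfg$speed_S) == 1 &&
        is.finite(cfg$speed_S) && cfg$speed_S >= 0, "speed_S",
      "must be a single finite number >= 0")
  chk(is.numeric(cfg$persistence_P) && length(cfg$persistence_P) == 1 &&
        is.finite(cfg$persistence_P) && cfg$persistence_P > 0,
      "persistence_P", "must be a single finite number > 0")
  chk(is.numeric(cfg$n_cells) && cfg$n_cells >= 1, "n_cells", "must be >= 1")
  chk(is.numeric(cfg$n_frames) && cfg$n_frames >= 2, "n_frames",
      "must be >= 2")
  chk(is.numeric(cfg$frame_interval) && cfg$frame_interval > 0,
      "frame_interval", "must be > 0")
  chk(is.numeric(cfg$localization_noise_sd) && cfg$localization_noise_sd >= 0,
      "localization_noise_sd", "must be >= 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single integer")
  chk(is.numeric(cfg$substeps) && cfg$substeps >= 1, "substeps",
      "must be >= 1")
  invisible(cfg)
}

# Deterministic per-cell seed derived from the master seed; keeps distinct
# cells on effectively independent sub-streams while preserving bit-level
# reproducibility of the whole track set.
cell_seed <- function(master, i) {
  as.integer((abs(as.double(master)) * 48271 + i * 16807) %% 2147483629 + 1)
}

# One 2D Ornstein-Uhlenbeck track sampled with the exact transition density.
# Per axis the velocity is stationary OU with sd sigma = S/sqrt(2) and
# correlation time P; the position increment over a step of length `delta`
# and the end-of-step velocity are drawn jointly from their exact bivariate
# Gaussian conditional on the start-of-step velocity, so recorded positions
# obey the Fuerth MSD at any step size (no Euler discretization bias).
ou_positions <- function(n_steps, delta, S, P) {
  if (S == 0) return(list(x = numeric(n_steps + 1), y = numeric(n_steps + 1)))
  sigma <- S / sqrt(2)
  a <- exp(-delta / P)
  sd_v <- sigma * sqrt(1 - a^2)
  var_x <- sigma^2 * (2 * P * delta - P^2 * (3 - 4 * a + a^2))
  cov_xv <- sigma^2 * P * (1 - a)^2
  s_resid <- sqrt(max(0, var_x - (cov_xv / sd_v)^2))
  one_axis <- function() {
    v0 <- stats::rnorm(1, 0, sigma)   # stationary initial velocity
    xi1 <- stats::rnorm(n_steps)
    xi2 <- stats::rnorm(n_steps)
    v <- c(v0, as.numeric(stats::filter(sd_v * xi1, a, "recursive",
                                        init = v0)))
    dx <- P * (1 - a) * v[seq_len(n_steps)] + (cov_xv / sd_v) * xi1 +
      s_resid * xi2
    c(0, cumsum(dx))
  }
  list(x = one_axis(), y = one_axis())
}

#' Simulate 2D persistent-random-walk cell tracks
#'
#' Generates trajectories whose velocity follows a stationary two-dimensional
#' Ornstein-Uhlenbeck process with root-mean-square speed `speed_S`
#' (per-axis standard deviation \eqn{S/\sqrt{2}}) and correlation time
#' `persistence_P`. The discretization is exact -- increments are drawn from
#' the true transition density, not an Euler scheme -- so the population MSD
#' of simulated tracks follows the closed-form Fuerth curve
#' \eqn{2 S^2 P [t - P(1 - e^{-t/P})]} at any step size, making the closed
#' form a usable oracle in tests. Optional Gaussian localization noise is
#' added to the recorded positions only.
#'
#' @param config A [prw_sim_config()] object.
#' @return A [track_set()] with `config$n_cells` trajectories of
#'   `config$n_frames` positions each, labelled `cell_1 ... cell_n`.
#' @examples
#' cfg <- prw_sim_config(speed_S = 10, persistence_P = 2, n_cells = 5,
#'                       n_frames = 11, frame_interval = 1.5, seed = 42)
#' ts <- simulate_prw(cfg)
#' ts
#' @export
simulate_prw <- function(config) {
  if (!inherits(config, "prw_sim_config")) {
    config <- do.call(prw_sim_config, config)
  }
  validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  delta <- config$frame_interval / config$substeps
  n_steps <- (config$n_frames - 1L) * config$substeps
  keep <- seq(1L, n_steps + 1L, by = config$substeps)
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  trajs <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(cell_seed(config$seed, i))
    pos <- ou_positions(n_steps, delta, config$speed_S, config$persistence_P)
    x <- pos$x[keep]
    y <- pos$y[keep]
    if (config$localization_noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, config$localization_noise_sd)
      y <- y + stats::rnorm(length(y), 0, config$localization_noise_sd)
    }
    trajs[[i]] <- data.frame(time_min = times, x_um = x, y_um = y)
  }
  names(trajs) <- paste0("cell_", seq_len(config$n_cells))
  track_set(trajs, frame_interval = config$frame_interval,
            group_label = config$group_label)
}

#' Simulate Transwell hemocytometer counts
#'
#' Draws hemocytometer counts for replicate bottom wells of a Transwell
#' migration assay. A hemocytometer count of `n` corresponds to
#' `n x 10^4` cells/ml, so counts are Poisson with mean
#' `true_concentration x 1e-4`.
#'
#' @param true_concentration True cell concentration in the sampled media,
#'   cells/ml. Must be >= 0.
#' @param n_replicates Number of replicate wells/counts.
#' @param seed Integer seed.
#' @return Integer vector of `n_replicates` hemocytometer counts.
#' @seealso [quantify_migrated()]
#' @export
simulate_transwell_counts <- function(true_concentration, n_replicates,
                                      seed = 1L) {
  if (!is.numeric(true_concentration) || length(true_concentration) != 1 ||
      !is.finite(true_concentration) || true_concentration < 0) {
    stop("invalid 'true_concentration': must be a single number >= 0",
         call. = FALSE)
  }
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  stats::rpois(as.integer(n_replicates), true_concentration * 1e-4)
}

#' Simulate a competitive in vivo migration experiment
#'
#' Produces the pair of congenic-marker count records for one competitive
#' transfer: donor CD45.1+ and reference CD45.2+ cells mixed at
#' `injected_ratio`, with tissue homing of the CD45.1+ population modified by
#' `tissue_enrichment`. Tissue counts are binomial draws with CD45.1
#' probability proportional to `injected_ratio * tissue_enrichment`; the
#' injected-mix record reflects `injected_ratio` exactly (up to integer
#' rounding of `n_cells_sampled`).
#'
#' @param injected_ratio CD45.1/CD45.2 ratio of the injected mix (positive;
#'   1 for the usual 1:1 mix).
#' @param tissue_enrichment Multiplicative change of the CD45.1/CD45.2 odds in
#'   tissue relative to the injected mix (positive; 1 = no differential
#'   migration).
#' @param n_cells_sampled Number of neutrophils gated per compartment.
#' @param seed Integer seed.
#' @param compartment Tissue compartment label for the tissue record.
#' @return List with elements `injected` and `tissue`, each a
#'   [competitive_record()].
#' @seealso [competitive_ratio()]
#' @export
simulate_competitive_counts <- function(injected_ratio, tissue_enrichment,
                                        n_cells_sampled, seed = 1L,
                                        compartment = "spleen") {
  for (nm in c("injected_ratio", "tissue_enrichment", "n_cells_sampled")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("invalid '", nm, "': must be a single positive number",
           call. = FALSE)
    }
  }
  n <- as.integer(n_cells_sampled)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  inj_1 <- round(n * injected_ratio / (1 + injected_ratio))
  inj_1 <- min(max(inj_1, 1L), n - 1L)  # both populations present in the mix
  odds <- injected_ratio * tissue_enrichment
  tis_1 <- stats::rbinom(1, n, odds / (1 + odds))
  list(
    injected = competitive_record(inj_1, n - inj_1,
                                  compartment = "injected_mix"),
    tissue = competitive_record(tis_1, n - tis_1, compartment = compartment)
  )
}
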