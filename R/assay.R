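#' Number of migrated cells from a hemocytometer count
#'
#' Converts a hemocytometer count `n` from the bottom well of a Transwell
#' chamber into the number of migrated cells:
#' \deqn{N = n \times 10^4 \times \frac{\mathrm{bottom\_volume}}{1000}.}
#' A hemocytometer count corresponds to `n x 10^4` cells/ml; with the
#' standard 29 ul of media in the bottom well this is the familiar
#' `N = n x 10^4 x 0.029`. The 0.029 coefficient is therefore derived (29 ul
#' expressed in ml), not magic, and other bottom volumes scale
#' proportionally.
#'
#' @param n Hemocytometer count(s), non-negative.
#' @param bottom_volume Volume of media in the bottom well, ul (default 29).
#' @return Number of migrated cells, same length as `n`.
#' @examples
#' quantify_migrated(100)       # 29000
#' quantify_migrated(1)         # 290
#' @export
quantify_migrated <- function(n, bottom_volume = 29) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0)) {
    stop("hemocytometer count n must be non-negative", call. = FALSE)
  }
  if (!is.numeric(bottom_volume) || bottom_volume <= 0) {
    stop("bottom_volume must be > 0", call. = FALSE)
  }
  n * 1e4 * (bottom_volume / 1000)
}

#' Fold increase of stimulated over spontaneous migration
#'
#' The ratio of the number of cells migrating in response to a stimulus to
#' the number migrating spontaneously (unstimulated). A zero spontaneous
#' count makes the ratio undefined and raises an explicit error rather than
#' silently dropping the well, so downstream statistics can exclude it with
#' a logged reason.
#'
#' @param stimulated_N Migrated cells under stimulation.
#' @param spontaneous_N Migrated cells without stimulation; must be > 0.
#' @return `stimulated_N / spontaneous_N`.
#' @export
fold_increase <- function(stimulated_N, spontaneous_N) {
  if (any(spontaneous_N == 0)) {
    stop("undefined fold increase: spontaneous migrated count is zero",
         call. = FALSE)
  }
  stimulated_N / spontaneous_N
}

#' Congenic-marker cell counts for one compartment
#'
#' Counts of CD45.1+ and CD45.2+ neutrophils gated from one compartment of a
#' competitive transfer experiment (the injected mix, or a tissue such as
#' spleen or lung).
#'
#' @param cd45_1,cd45_2 Non-negative integer counts.
#' @param compartment One of `"injected_mix"`, `"spleen"`, `"lung"` (other
#'   labels are accepted).
#' @return An object of class `competitive_record`.
#' @export
competitive_record <- function(cd45_1, cd45_2, compartment = "injected_mix") {
  for (nm in c("cd45_1", "cd45_2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("invalid '", nm, "': must be a single count >= 0", call. = FALSE)
    }
  }
  structure(list(cd45_1 = cd45_1, cd45_2 = cd45_2,
                 compartment = as.character(compartment)),
            class = "competitive_record")
}

#' @export
print.competitive_record <- function(x, ...) {
  cat("Competitive record [", x$compartment, "]: CD45.1+ = ", x$cd45_1,
      ", CD45.2+ = ", x$cd45_2, "\n", sep = "")
  invisible(x)
}

#' Normalized competitive migration ratio
#'
#' The CD45.1/CD45.2 ratio found in a tissue, normalized to the ratio of the
#' injected mix:
#' \deqn{\frac{\mathrm{tissue}_{45.1}/\mathrm{tissue}_{45.2}}
#'            {\mathrm{injected}_{45.1}/\mathrm{injected}_{45.2}}.}
#' The injected mix defines the baseline of 1: the function returns exactly 1
#' whenever the tissue composition equals the injected composition. Values
#' above 1 indicate preferential homing of the CD45.1+ (donor) population.
#'
#' @param tissue,injected [competitive_record()] objects. Both need
#'   `cd45_2 > 0`, and the injected record `cd45_1 > 0`.
#' @return The normalized ratio (dimensionless).
#' @examples
#' competitive_ratio(competitive_record(200, 100, "spleen"),
#'                   competitive_record(100, 100))  # 2
#' @export
competitive_ratio <- function(tissue, injected) {
  stopifnot(inherits(tissue, "competitive_record"),
            inherits(injected, "competitive_record"))
  if (tissue$cd45_2 == 0) {
    stop("undefined ratio: tissue record has cd45_2 = 0", call. = FALSE)
  }
  if (injected$cd45_2 == 0) {
    stop("undefined ratio: injected record has cd45_2 = 0", call. = FALSE)
  }
  if (injected$cd45_1 == 0) {
    stop("undefined ratio: injected record has cd45_1 = 0", call. = FALSE)
  }
  (tissue$cd45_1 / tissue$cd45_2) / (injected$cd45_1 / injected$cd45_2)
}
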