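#' Construct a single cell trajectory
#'
#' A trajectory is the time-ordered sequence of centroid positions of one
#' cell, stored as a data frame with columns `time_min`, `x_um`, `y_um`.
#' Times must be strictly increasing and uniformly spaced (to a relative
#' tolerance of 1e-6) and all positions finite.
#'
#' @param x,y Numeric coordinate vectors, um.
#' @param times Optional time vector, min. If omitted, `frame_interval` is
#'   used to build `0, dt, 2*dt, ...`.
#' @param frame_interval Frame interval in minutes (used when `times` is
#'   missing).
#' @return A data frame with columns `time_min`, `x_um`, `y_um`.
#' @export
trajectory <- function(x, y, times = NULL, frame_interval = 1.5) {
  if (is.null(times)) times <- (seq_along(x) - 1) * frame_interval
  traj <- data.frame(time_min = times, x_um = x, y_um = y)
  validate_trajectory(traj)
  traj
}

validate_trajectory <- function(traj, id = "trajectory") {
  if (!all(c("time_min", "x_um", "y_um") %in% names(traj))) {
    stop(id, ": missing required columns time_min/x_um/y_um", call. = FALSE)
  }
  n <- nrow(traj)
  if (n < 2) stop(id, ": needs at least 2 positions", call. = FALSE)
  if (!all(is.finite(traj$x_um)) || !all(is.finite(traj$y_um))) {
    stop(id, ": non-finite positions", call. = FALSE)
  }
  dt <- diff(traj$time_min)
  if (any(dt <= 0)) stop(id, ": times not strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * max(dt)) {
    stop(id, ": times not uniformly spaced", call. = FALSE)
  }
  invisible(traj)
}

#' Construct a set of cell tracks sharing one acquisition
#'
#' @param trajectories Named list of trajectories (see [trajectory()]); names
#'   are cell ids.
#' @param frame_interval Frame interval shared by all trajectories, min.
#' @param group_label Biological group (e.g. `"control"`, `"tumor"`).
#' @param replicate_id Mouse or field-of-view identifier (provenance).
#' @param pixel_size Pixel size used at calibration, um/px (provenance only;
#'   coordinates in a track set are always in um).
#' @return An object of class `track_set`.
#' @export
track_set <- function(trajectories, frame_interval, group_label = "group",
                      replicate_id = NA_character_, pixel_size = NA_real_) {
  if (!nzchar(group_label)) stop("group_label must be non-empty",
                                 call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0", call. = FALSE)
  }
  if (is.null(names(trajectories)) && length(trajectories) > 0) {
    names(trajectories) <- paste0("cell_", seq_along(trajectories))
  }
  for (id in names(trajectories)) {
    traj <- trajectories[[id]]
    validate_trajectory(traj, id = id)
    dt <- diff(traj$time_min)[1]
    if (abs(dt - frame_interval) > 1e-6 * frame_interval) {
      stop("trajectory '", id, "' has frame interval ", dt,
           " but the track set declares ", frame_interval, call. = FALSE)
    }
  }
  structure(list(trajectories = trajectories,
                 frame_interval = frame_interval,
                 group_label = as.character(group_label),
                 replicate_id = as.character(replicate_id),
                 pixel_size = pixel_size),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  nf <- vapply(x$trajectories, nrow, integer(1))
  cat("Track set '", x$group_label, "': ", length(x$trajectories),
      " cells, frame interval ", x$frame_interval, " min\n", sep = "")
  if (length(nf)) {
    cat("  frames per track: ", min(nf), "-", max(nf),
        " (", format((max(nf) - 1) * x$frame_interval), " min max duration)\n",
        sep = "")
  }
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$trajectories)

#' @export
as.data.frame.track_set <- function(x, ...) {
  if (length(x$trajectories) == 0) {
    return(data.frame(cell_id = character(), frame = integer(),
                      time_min = numeric(), x_um = numeric(),
                      y_um = numeric()))
  }
  do.call(rbind, lapply(names(x$trajectories), function(id) {
    traj <- x$trajectories[[id]]
    data.frame(cell_id = id, frame = seq_len(nrow(traj)),
               time_min = traj$time_min, x_um = traj$x_um, y_um = traj$y_um)
  }))
}

# Delimiter autodetection: tab if the header line contains one, else comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read cell tracks from a delimited table
#'
#' Reads either an ImageJ Manual Tracking export (pixel coordinates, 1-based
#' slice numbers) or the package's generic track table (micrometre
#' coordinates, as written by [write_tracks()]). Comma and tab delimiters are
#' autodetected. Tracks with fewer than 3 recorded positions are excluded
#' (two displacement increments are the minimum for any lag beyond the
#' first); exclusions are reported via [message()] and recorded in the
#' `"excluded"` attribute of the result.
#'
#' For the ImageJ dialect, pixel coordinates are multiplied by `pixel_size`
#' and 1-based slice numbers are converted to times as
#' `(slice - 1) * frame_interval`, so the first frame is t = 0. Coordinates
#' are stored as read (no y-axis flip): mean-squared displacement is
#' invariant to axis orientation. For the generic dialect, coordinates are
#' taken as already calibrated; `pixel_size` (default 1) still scales them,
#' which supports generic tables that carry raw pixel values.
#'
#' @param path Path to the track table.
#' @param format `"generic_csv"` or `"imagej_manual_tracking"`.
#' @param pixel_size Calibration, um/px. Required for the ImageJ dialect; the
#'   microscope objective determines it and no default is assumed.
#' @param frame_interval Frame interval, min. For the generic dialect it
#'   defaults to the metadata sidecar written by [write_tracks()], if present.
#' @param group_label,replicate_id Labels for the resulting track set;
#'   default to sidecar values when available.
#' @param imagej_columns Named character vector mapping the roles `track`,
#'   `slice`, `x`, `y` to header names of the ImageJ export. Matching is by
#'   prefix, so the default copes with the plugin's degree-sign headers
#'   ("Track n.", "Slice n.") under any encoding.
#' @return A [track_set()]; attribute `"excluded"` is a data frame of dropped
#'   cell ids and reasons.
#' @export
read_tracks <- function(path,
                        format = c("generic_csv", "imagej_manual_tracking"),
                        pixel_size = NULL, frame_interval = NULL,
                        group_label = NULL, replicate_id = NULL,
                        imagej_columns = c(track = "Track", slice = "Slice",
                                           x = "X", y = "Y")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  }
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval
  if (is.null(group_label)) group_label <- meta$group_label %||% "group"
  if (is.null(replicate_id)) replicate_id <- meta$replicate_id %||%
      NA_character_
  if (is.null(frame_interval)) {
    stop("frame_interval is required (not found in a metadata sidecar)",
         call. = FALSE)
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)

  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE)

  if (format == "imagej_manual_tracking") {
    if (is.null(pixel_size)) {
      stop("pixel_size is required for ImageJ Manual Tracking input ",
           "(calibration is objective-dependent and never defaulted)",
           call. = FALSE)
    }
    if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
    pick <- function(role) {
      hits <- which(startsWith(trimws(names(tab)), imagej_columns[[role]]))
      if (length(hits) == 0) NA_integer_ else hits[1]
    }
    idx <- vapply(c("track", "slice", "x", "y"), pick, integer(1))
    if (anyNA(idx)) {
      stop("ImageJ input is missing required column(s): ",
           paste(imagej_columns[c("track", "slice", "x", "y")[is.na(idx)]],
                 collapse = ", "), call. = FALSE)
    }
    df <- data.frame(cell_id = paste0("track_", tab[[idx[["track"]]]]),
                     frame = as.integer(tab[[idx[["slice"]]]]),
                     x_um = tab[[idx[["x"]]]] * pixel_size,
                     y_um = tab[[idx[["y"]]]] * pixel_size)
    df$time_min <- (df$frame - 1L) * frame_interval
  } else {
    needed <- c("cell_id", "frame", "x_um", "y_um")
    missing_cols <- setdiff(needed, names(tab))
    if (length(missing_cols)) {
      stop("generic track table is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    scale <- if (is.null(pixel_size)) 1 else pixel_size
    df <- data.frame(cell_id = as.character(tab$cell_id),
                     frame = as.integer(tab$frame),
                     x_um = tab$x_um * scale, y_um = tab$y_um * scale)
    df$time_min <- if ("time_min" %in% names(tab)) tab$time_min else
      (df$frame - 1L) * frame_interval
  }

  trajs <- list()
  excluded <- data.frame(cell_id = character(), reason = character())
  for (id in unique(df$cell_id)) {
    sub <- df[df$cell_id == id, ]
    if (is.unsorted(sub$frame, strictly = TRUE)) {
      stop("non-monotone frame numbers within track '", id, "'",
           call. = FALSE)
    }
    if (nrow(sub) < 3) {
      excluded <- rbind(excluded, data.frame(
        cell_id = id, reason = "fewer than 3 recorded positions"))
      next
    }
    trajs[[id]] <- data.frame(time_min = sub$time_min, x_um = sub$x_um,
                              y_um = sub$y_um)
  }
  if (nrow(excluded) > 0) {
    message("read_tracks: excluded ", nrow(excluded),
            " track(s) with fewer than 3 positions: ",
            paste(excluded$cell_id, collapse = ", "))
  }
  ts <- track_set(trajs, frame_interval = frame_interval,
                  group_label = group_label, replicate_id = replicate_id,
                  pixel_size = if (is.null(pixel_size))
                    meta$pixel_size %||% NA_real_ else pixel_size)
  attr(ts, "excluded") <- excluded
  ts
}

#' Write cell tracks as a generic CSV track table
#'
#' Writes the generic dialect (`cell_id, frame, time_min, x_um, y_um`, comma
#' separated, all numbers fixed at 6 decimal places) plus a YAML metadata
#' sidecar `<path>.meta.yaml` recording `pixel_size`, `frame_interval`,
#' `group_label` and `replicate_id`. [read_tracks()] inverts it exactly (at
#' the written 6-decimal precision). An empty track set produces a
#' header-only file.
#'
#' @param trackset A [track_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trackset, path) {
  stopifnot(inherits(trackset, "track_set"))
  df <- as.data.frame(trackset)
  out <- data.frame(cell_id = df$cell_id, frame = df$frame,
                    time_min = sprintf("%.6f", df$time_min),
                    x_um = sprintf("%.6f", df$x_um),
                    y_um = sprintf("%.6f", df$y_um))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(pixel_size = trackset$pixel_size,
                        frame_interval = trackset$frame_interval,
                        group_label = trackset$group_label,
                        replicate_id = trackset$replicate_id),
                   sidecar_path(path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
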