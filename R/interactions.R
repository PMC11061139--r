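#' Geometric interaction criteria
#'
#' An ordered fly pair (interactor -> interactee) is interacting on a frame
#' when (1) the angle between the interactor's long axis and the segment
#' joining the two centres is at most `max_angle` degrees, and (2) that
#' segment is at most `max_distance` body lengths of the interactor; a bout
#' is an interaction event when both conditions hold for at least
#' `min_duration` seconds.  Both thresholds are boundary-inclusive.  The
#' interactor's body length is scalarized as the median of its per-frame
#' body-length track.
#'
#' @param max_angle maximum heading angle, degrees, in (0, 180].
#' @param max_distance maximum separation in interactor body lengths (> 0).
#' @param min_duration minimum bout duration in seconds (> 0).
#' @param max_gap number of consecutive criterion-violating frames that may
#'   be bridged inside a bout (default 0: conditions must hold on every
#'   frame).
#' @return an `interaction_criteria` object.
#' @export
interaction_criteria <- function(max_angle = 90, max_distance = 2,
                                 min_duration = 1.5, max_gap = 0L) {
  bad <- function(field, why) {
    stop(sprintf("invalid interaction criterion '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(max_angle) || length(max_angle) != 1L ||
      max_angle <= 0 || max_angle > 180) bad("max_angle", "must be in (0, 180]")
  if (!is.numeric(max_distance) || length(max_distance) != 1L ||
      max_distance <= 0) bad("max_distance", "must be > 0")
  if (!is.numeric(min_duration) || length(min_duration) != 1L ||
      min_duration <= 0) bad("min_duration", "must be > 0")
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap < 0) {
    bad("max_gap", "must be >= 0")
  }
  structure(list(max_angle = max_angle, max_distance = max_distance,
                 min_duration = min_duration, max_gap = as.integer(max_gap)),
            class = "interaction_criteria")
}

#' Build criteria from a configuration mapping
#'
#' Accepts either a flat mapping of criterion fields or a nested mapping
#' `genotype -> fields` (select with `genotype=`).  Missing fields fall back
#' to the defaults of [interaction_criteria()]; unknown keys are a
#' configuration error.
#'
#' @param config named list (possibly empty).
#' @param genotype optional genotype label selecting a sub-mapping.
#' @return an `interaction_criteria` object.
#' @export
load_criteria <- function(config = list(), genotype = NULL) {
  if (is.null(config)) config <- list()
  if (!is.list(config)) {
    stop("criteria config must be a named list", call. = FALSE)
  }
  fields <- c("max_angle", "max_distance", "min_duration", "max_gap")
  if (!is.null(genotype)) {
    if (!is.null(config[[genotype]])) {
      config <- config[[genotype]]
    } else if (length(config) > 0L && all(names(config) %in% fields)) {
      # flat config applies to every genotype
    } else {
      config <- list()
    }
  }
  if (length(config) > 0L) {
    if (is.null(names(config)) || any(names(config) == "")) {
      stop("criteria config entries must be named", call. = FALSE)
    }
    unknown <- setdiff(names(config), fields)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown criteria config keys: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  do.call(interaction_criteria, config)
}

#' Angle between an interactor's heading and the segment to an interactee
#'
#' @param interactor numeric vector `c(x, y, orientation)` (orientation in
#'   radians) or a 3-column matrix of such states.
#' @param interactee numeric vector `c(x, y)` or a 2-column matrix.
#' @return absolute angle(s) in degrees, in \[0, 180\].
#' @export
relative_angle <- function(interactor, interactee) {
  im <- if (is.matrix(interactor)) interactor else matrix(interactor, ncol = 3)
  tm <- if (is.matrix(interactee)) interactee else matrix(interactee, ncol = 2)
  dx <- tm[, 1] - im[, 1]
  dy <- tm[, 2] - im[, 2]
  d <- sqrt(dx * dx + dy * dy)
  if (any(d == 0)) {
    stop("degenerate geometry: interactor and interactee positions coincide",
         call. = FALSE)
  }
  o <- im[, 3]
  cosang <- (cos(o) * dx + sin(o) * dy) / d
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# close FALSE gaps of length <= max_gap that are flanked by TRUE runs
bridge_gaps <- function(ok, max_gap) {
  if (max_gap <= 0L || !any(ok)) return(ok)
  r <- rle(ok)
  nr <- length(r$lengths)
  for (k in seq_len(nr)) {
    if (!r$values[k] && r$lengths[k] <= max_gap && k > 1L && k < nr) {
      r$values[k] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Detect directed interaction events in a trajectory
#'
#' Evaluates the per-frame geometric predicate for every ordered fly pair and
#' emits maximal runs (optionally bridging up to `max_gap` violating frames)
#' lasting at least `min_duration` seconds.  Events are directional: the
#' angle condition uses only the interactor's heading, so A->B can hold while
#' B->A does not.
#'
#' @param traj a `fly_trajectory`.
#' @param criteria an `interaction_criteria` object.
#' @return an `interaction_events` data.frame with columns `interactor`,
#'   `interactee`, `start_frame`, `end_frame` (inclusive), `start_s`,
#'   `end_s`, sorted by `start_frame` then (interactor, interactee);
#'   attributes `frame_rate`, `n_flies`, `n_frames`.
#' @export
detect_interactions <- function(traj, criteria = interaction_criteria()) {
  stopifnot(inherits(criteria, "interaction_criteria"))
  if (!inherits(traj, "fly_trajectory") || nrow(traj) == 0L) {
    stop("empty or invalid trajectory input", call. = FALSE)
  }
  fr <- attr(traj, "frame_rate")
  min_frames <- as.integer(ceiling(criteria$min_duration * fr - 1e-9))
  frames <- sort(unique(traj$frame))
  if (length(frames) < min_frames) {
    stop(sprintf("trajectory too short: %d frames < %d required for %.3g s",
                 length(frames), min_frames, criteria$min_duration),
         call. = FALSE)
  }
  flies <- sort(unique(traj$fly_id))
  n <- length(flies)
  nf <- length(frames)

  ord <- order(traj$fly_id, traj$frame)
  if (nrow(traj) != n * nf) {
    stop("trajectory is not a complete frame x fly grid", call. = FALSE)
  }
  X <- matrix(traj$x_mm[ord], nf, n)
  Y <- matrix(traj$y_mm[ord], nf, n)
  CO <- cos(matrix(traj$orientation_rad[ord], nf, n))
  SO <- sin(matrix(traj$orientation_rad[ord], nf, n))
  BL <- vapply(seq_len(n),
               function(i) median(traj$body_length_mm[ord][((i - 1) * nf + 1):(i * nf)]),
               numeric(1))

  cos_thresh <- cos(criteria$max_angle * pi / 180)
  res <- vector("list", n * (n - 1L))
  k <- 0L
  for (i in seq_len(n)) {
    max_d <- criteria$max_distance * BL[i]
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- X[, j] - X[, i]
      dy <- Y[, j] - Y[, i]
      d <- sqrt(dx * dx + dy * dy)
      # boundary-inclusive on both thresholds; coincident centres fail
      ok <- d > 0 & d <= max_d & (CO[, i] * dx + SO[, i] * dy) >= cos_thresh * d
      ok <- bridge_gaps(ok, criteria$max_gap)
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_frames
      if (any(keep)) {
        k <- k + 1L
        res[[k]] <- data.frame(interactor = flies[i], interactee = flies[j],
                               start_frame = frames[starts[keep]],
                               end_frame = frames[ends[keep]])
      }
    }
  }
  ev <- if (k > 0L) {
    do.call(rbind, res[seq_len(k)])
  } else {
    data.frame(interactor = integer(0), interactee = integer(0),
               start_frame = integer(0), end_frame = integer(0))
  }
  ev <- ev[order(ev$start_frame, ev$interactor, ev$interactee), , drop = FALSE]
  rownames(ev) <- NULL
  ev$start_s <- ev$start_frame / fr
  ev$end_s <- ev$end_frame / fr
  structure(ev, frame_rate = fr, n_flies = n, fly_ids = flies,
            n_frames = nf, class = c("interaction_events", "data.frame"))
}

#' Write / read interaction events as CSV
#' @param events an `interaction_events` data.frame.
#' @param path file path.
#' @return `path` (writer) or an `interaction_events` object (reader).
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "interaction_events"))
  con <- file(path, "w")
  writeLines(c(sprintf("# frame_rate=%.10g", attr(events, "frame_rate")),
               sprintf("# n_flies=%d", attr(events, "n_flies")),
               sprintf("# n_frames=%d", attr(events, "n_frames"))), con)
  close(con)
  data.table::fwrite(as.data.frame(events), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("events file not found: %s", path), call. = FALSE)
  }
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(m) == 0L) return(default)
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
  }
  ev <- data.table::fread(path, skip = length(meta), header = TRUE,
                          data.table = FALSE)
  n_flies <- as.integer(get_meta("n_flies", max(c(ev$interactor, ev$interactee, 0))))
  structure(ev, frame_rate = get_meta("frame_rate", 30),
            n_flies = n_flies, fly_ids = seq_len(n_flies),
            n_frames = as.integer(get_meta("n_frames", NA)),
            class = c("interaction_events", "data.frame"))
}
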