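# Independent oracles and fixture builders shared across the test files.

# Betweenness oracle by shortest-path counting with adjacency-matrix powers:
# the number of length-k walks s->t is (A^k)_st, and minimal-length walks are
# exactly the geodesics, so lambda_st = (A^d)_st with d the first power with
# a nonzero entry, and paths through v factor as lambda_sv * lambda_vt when
# d(s,v) + d(v,t) = d(s,t).  Entirely independent of the Brandes kernel.
bc_oracle <- function(edges, n) {
  A <- matrix(0, n, n)
  if (length(edges) > 0) A[matrix(edges, ncol = 2)] <- 1
  pows <- vector("list", max(1L, n - 1L))
  pows[[1]] <- A
  for (k in seq_len(n - 1L)) {
    if (k >= 2L) pows[[k]] <- pows[[k - 1L]] %*% A
  }
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    for (k in seq_len(n - 1)) {
      if (pows[[k]][s, t] > 0) { D[s, t] <- k; S[s, t] <- pows[[k]][s, t]; break }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == v || t == v || s == t || !is.finite(D[s, t])) next
    if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
        D[s, v] + D[v, t] == D[s, t]) {
      bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  bc
}

# all simple digraphs on n nodes as edge matrices (2^(n(n-1)) graphs)
all_digraphs <- function(n) {
  slots <- expand.grid(from = seq_len(n), to = seq_len(n))
  slots <- slots[slots$from != slots$to, ]
  ns <- nrow(slots)
  lapply(seq_len(2^ns) - 1L, function(mask) {
    pick <- bitwAnd(mask, bitwShiftL(1L, seq_len(ns) - 1L)) != 0L
    as.matrix(slots[pick, , drop = FALSE])
  })
}

random_digraph_edges <- function(n, m) {
  slots <- expand.grid(from = seq_len(n), to = seq_len(n))
  slots <- slots[slots$from != slots$to, ]
  as.matrix(slots[sample(nrow(slots), m), , drop = FALSE])
}

# Brute-force interaction oracle: evaluates the geometric predicate frame by
# frame with scalar arithmetic and run-length-encodes it (max_gap = 0 only).
detect_oracle <- function(traj, criteria) {
  fr <- attr(traj, "frame_rate")
  min_frames <- ceiling(criteria$min_duration * fr - 1e-9)
  flies <- sort(unique(traj$fly_id))
  frames <- sort(unique(traj$frame))
  ev <- list()
  bl <- sapply(flies, function(f) median(traj$body_length_mm[traj$fly_id == f]))
  for (i in flies) for (j in flies) {
    if (i == j) next
    di <- traj[traj$fly_id == i, ]; di <- di[order(di$frame), ]
    dj <- traj[traj$fly_id == j, ]; dj <- dj[order(dj$frame), ]
    ok <- logical(length(frames))
    for (k in seq_along(frames)) {
      dx <- dj$x_mm[k] - di$x_mm[k]; dy <- dj$y_mm[k] - di$y_mm[k]
      d <- sqrt(dx^2 + dy^2)
      if (d == 0 || d > criteria$max_distance * bl[match(i, flies)]) next
      ang <- acos(max(-1, min(1, (cos(di$orientation_rad[k]) * dx +
                                    sin(di$orientation_rad[k]) * dy) / d))) * 180 / pi
      ok[k] <- ang <= criteria$max_angle
    }
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (q in which(r$values & r$lengths >= min_frames)) {
      ev[[length(ev) + 1]] <- data.frame(interactor = i, interactee = j,
                                         start_frame = frames[starts[q]],
                                         end_frame = frames[ends[q]])
    }
  }
  if (length(ev) == 0) {
    return(data.frame(interactor = integer(0), interactee = integer(0),
                      start_frame = integer(0), end_frame = integer(0)))
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$start_frame, out$interactor, out$interactee), ]
  rownames(out) <- NULL
  out
}

# hand-built trajectory from per-fly state functions of frame index
make_traj <- function(n_frames, frame_rate, states, body_length = 2.5) {
  rows <- do.call(rbind, lapply(seq_along(states), function(i) {
    st <- t(sapply(0:(n_frames - 1), states[[i]]))
    data.frame(frame = 0:(n_frames - 1), fly_id = i,
               x_mm = st[, 1], y_mm = st[, 2], orientation_rad = st[, 3],
               body_length_mm = body_length)
  }))
  rows <- rows[order(rows$frame, rows$fly_id), ]
  structure(rows, frame_rate = frame_rate, arena_diameter = 60,
            class = c("fly_trajectory", "data.frame"))
}

# two stationary flies facing each other, a canonical interacting pair
facing_pair_traj <- function(n_frames, frame_rate = 30, separation = 3.75) {
  make_traj(n_frames, frame_rate, list(
    function(f) c(0, 0, 0),                 # fly 1 at origin facing +x
    function(f) c(separation, 0, pi)        # fly 2 facing -x (toward fly 1)
  ))
}

edge_stream_fixture <- function(edges, n_flies = 12L) {
  df <- data.frame(interactor = edges[, 1], interactee = edges[, 2],
                   start_frame = seq_len(nrow(edges)))
  structure(df, n_flies = n_flies, fly_ids = seq_len(n_flies),
            frame_rate = 30,
            class = c("edge_stream", "data.frame"))
}

fast_sim <- function(duration = 30, seed = 1, ...) {
  simulate_arena(simulation_params(duration = duration, rng_seed = seed, ...))
}
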