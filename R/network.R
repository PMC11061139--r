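#' Simple directed network over the flies of one recording
#'
#' @param n_nodes number of nodes (flies).
#' @param edges 2-column integer matrix of ordered (from, to) pairs,
#'   1-based; must be simple (no self-loops, no duplicates).
#' @param validate check simplicity (disable only on internally constructed
#'   graphs).
#' @return a `directed_network` object.
#' @export
directed_network <- function(n_nodes, edges, validate = TRUE) {
  edges <- matrix(as.integer(edges), ncol = 2)
  n_nodes <- as.integer(n_nodes)
  if (validate) {
    if (n_nodes < 1L) stop("n_nodes must be >= 1", call. = FALSE)
    if (nrow(edges) > 0L) {
      if (any(edges < 1L) || any(edges > n_nodes)) {
        stop("edge endpoints must lie in 1..n_nodes", call. = FALSE)
      }
      if (any(edges[, 1] == edges[, 2])) {
        stop("self-loops are not allowed", call. = FALSE)
      }
      key <- (edges[, 1] - 1) * n_nodes + edges[, 2]
      if (anyDuplicated(key)) {
        stop("duplicate edges are not allowed", call. = FALSE)
      }
    }
  }
  structure(list(n_nodes = n_nodes, edges = edges),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' In- and out-degree sequences
#' @param net a `directed_network`.
#' @return list with integer vectors `out` and `in_` of length `n_nodes`.
#' @export
degree_sequences <- function(net) {
  list(out = tabulate(net$edges[, 1], net$n_nodes),
       in_ = tabulate(net$edges[, 2], net$n_nodes))
}

#' Stream of first-occurrence (unique) directed interactions
#'
#' An interaction is unique if the interactor had not previously interacted
#' with that interactee; uniqueness is per ordered pair, so A->B and B->A
#' are distinct (for 12 flies this gives the 132 possible directed edges of
#' which a 33-edge boxcar window is 25%).
#'
#' @param events an `interaction_events` data.frame (sorted by start time,
#'   as produced by [detect_interactions()]).
#' @return an `edge_stream` data.frame with columns `interactor`,
#'   `interactee`, `start_frame`, in order of first occurrence.
#' @export
unique_interaction_stream <- function(events) {
  if (nrow(events) == 0L) {
    out <- data.frame(interactor = integer(0), interactee = integer(0),
                      start_frame = integer(0))
  } else {
    if (is.unsorted(events$start_frame)) {
      events <- events[order(events$start_frame, events$interactor,
                             events$interactee), , drop = FALSE]
    }
    nmax <- max(events$interactor, events$interactee) + 1L
    key <- events$interactor * nmax + events$interactee
    first <- !duplicated(key)
    out <- data.frame(interactor = events$interactor[first],
                      interactee = events$interactee[first],
                      start_frame = events$start_frame[first])
    rownames(out) <- NULL
  }
  structure(out, n_flies = attr(events, "n_flies"),
            fly_ids = attr(events, "fly_ids"),
            frame_rate = attr(events, "frame_rate"),
            class = c("edge_stream", "data.frame"))
}

#' Boxcar network iterations over the unique-interaction stream
#'
#' The i-th iteration network contains unique edges i .. i+window_size-1 of
#' the stream; with U unique edges there are max(0, U - window_size + 1)
#' iterations.  The default window of 33 edges is 25% density for 12 flies
#' (0.25 x 12 x 11 = 33).
#'
#' @param stream an `edge_stream` (or a 2-column edge matrix).
#' @param window_size edges per network (>= 1), default 33.
#' @param n_nodes number of nodes; taken from the stream's `n_flies`
#'   attribute when absent.
#' @return list of `directed_network` objects (possibly empty, with a
#'   warning, when the recording has fewer unique interactions than the
#'   window).
#' @export
boxcar_networks <- function(stream, window_size = 33L, n_nodes = NULL) {
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("window_size must be >= 1", call. = FALSE)
  if (is.data.frame(stream)) {
    n_nodes <- n_nodes %||% attr(stream, "n_flies")
    ids <- attr(stream, "fly_ids") %||% seq_len(n_nodes %||% 0L)
    edges <- cbind(match(stream$interactor, ids),
                   match(stream$interactee, ids))
  } else {
    edges <- matrix(as.integer(stream), ncol = 2)
  }
  if (is.null(n_nodes)) n_nodes <- max(edges, 0L)
  u <- nrow(edges)
  if (u < window_size) {
    warning(sprintf(
      "recording too sparse: %d unique interactions < window of %d; no networks",
      u, window_size), call. = FALSE)
    return(list())
  }
  lapply(seq_len(u - window_size + 1L), function(i) {
    directed_network(n_nodes, edges[i:(i + window_size - 1L), , drop = FALSE],
                     validate = FALSE)
  })
}

#' Betweenness centrality of every node
#'
#' Unnormalized directed betweenness: for node v, the sum over ordered pairs
#' (s, t), s != v != t, of the fraction of shortest s->t paths that pass
#' through v (pairs with no s->t path contribute 0).  Computed with Brandes'
#' algorithm on the unweighted digraph.
#'
#' @param net a `directed_network`.
#' @return numeric vector of length `n_nodes`.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  as.numeric(bc_brandes_cpp(net$edges - 1L, net$n_nodes))
}

#' Global efficiency
#'
#' Mean over ordered node pairs i != j of 1 / d(i, j), with 1/Inf = 0 for
#' unreachable pairs.
#'
#' @param net a `directed_network`.
#' @return a scalar in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n_nodes
  if (n < 2L) return(NA_real_)
  D <- bfs_distances_cpp(net$edges - 1L, n)
  inv <- ifelse(D > 0, 1 / D, 0)   # unreachable coded -1 -> 0; diagonal 0
  sum(inv) / (n * (n - 1))
}

#' Directed clustering coefficient (all-triangle variant)
#'
#' Fagiolo's directed generalization: for node i,
#' C_i = (A + A^T)^3_ii / (2 * (d_tot(i) * (d_tot(i) - 1) - 2 * d_bi(i)))
#' with d_tot the total degree and d_bi the number of bilateral links;
#' nodes with a zero denominator contribute 0.  Returns the mean over nodes.
#'
#' @param net a `directed_network`.
#' @return a scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n_nodes
  A <- matrix(0, n, n)
  A[net$edges] <- 1
  S <- A + t(A)
  tri <- diag(S %*% S %*% S)
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  denom <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  ci <- ifelse(denom > 0, tri / denom, 0)
  mean(ci)
}

#' Directed degree assortativity (out-in variant)
#'
#' Pearson correlation, over edges, of the source's out-degree with the
#' target's in-degree.
#'
#' @param net a `directed_network`.
#' @return a scalar in \[-1, 1\], or `NA` when either endpoint degree has
#'   zero variance across edges.
#' @export
degree_assortativity <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  if (nrow(net$edges) < 2L) return(NA_real_)
  deg <- degree_sequences(net)
  x <- deg$out[net$edges[, 1]]
  y <- deg$in_[net$edges[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Group movement rate
#'
#' Mean over flies of the mean per-frame displacement times the frame rate,
#' in mm/s.
#'
#' @param traj a `fly_trajectory`.
#' @return mm/s scalar.
#' @export
movement_rate <- function(traj) {
  stopifnot(inherits(traj, "fly_trajectory"))
  fr <- attr(traj, "frame_rate")
  per_fly <- vapply(split(traj[c("x_mm", "y_mm", "frame")], traj$fly_id),
                    function(d) {
                      d <- d[order(d$frame), ]
                      if (nrow(d) < 2L) return(0)
                      mean(sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2)) * fr
                    }, numeric(1))
  mean(per_fly)
}

#' Group interaction rate
#'
#' Total interaction events per fly per minute of recording.
#'
#' @param events an `interaction_events` data.frame.
#' @param traj the matching `fly_trajectory` (supplies the number of flies
#'   and the recording duration).
#' @return events/min per fly.
#' @export
interaction_rate <- function(events, traj) {
  stopifnot(inherits(traj, "fly_trajectory"))
  n_flies <- length(unique(traj$fly_id))
  minutes <- length(unique(traj$frame)) / attr(traj, "frame_rate") / 60
  nrow(events) / n_flies / minutes
}
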