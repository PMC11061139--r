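#' Degree-preserving null distribution of a network metric
#'
#' Randomizes the observed digraph by directed double-edge swaps (rewiring
#' (a,b),(c,d) to (a,d),(c,b) when no self-loop or duplicate would result),
#' which preserves every node's in- and out-degree exactly.  Each sample
#' restarts from the observed graph and performs `swaps_per_edge * |E|` swap
#' attempts.  The metric is evaluated on the observed graph and on each
#' randomized sample.
#'
#' @param net a `directed_network` with at least 2 edges.
#' @param metric function `directed_network -> scalar`; default mean node
#'   betweenness centrality.
#' @param n_random number of randomized samples (default 10000 as used for
#'   per-iteration standardization; tests use a few hundred).
#' @param rng_seed optional seed for reproducibility.
#' @param swaps_per_edge swap attempts per edge per sample.
#' @param metric_name label stored in the result.
#' @return a `null_distribution` object: list with `metric_name`,
#'   `observed`, `null_mean`, `null_sd`, `n_random`, `degenerate` (TRUE when
#'   the null has zero spread, e.g. no valid swap exists), and the raw
#'   `samples`.
#' @export
random_null <- function(net, metric = function(g) mean(betweenness_centrality(g)),
                        n_random = 10000L, rng_seed = NULL,
                        swaps_per_edge = 10L, metric_name = "metric") {
  stopifnot(inherits(net, "directed_network"))
  m <- nrow(net$edges)
  if (m < 2L) stop("null model requires a network with >= 2 edges", call. = FALSE)
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("n_random must be >= 1", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  samples <- vapply(seq_len(n_random), function(k) {
    metric(randomize_degree_preserving(net, swaps_per_edge))
  }, numeric(1))

  observed <- metric(net)
  null_sd <- if (n_random > 1L) sd(samples, na.rm = TRUE) else 0
  if (!is.finite(null_sd)) null_sd <- 0
  structure(list(metric_name = metric_name,
                 observed = observed,
                 null_mean = mean(samples, na.rm = TRUE),
                 null_sd = null_sd,
                 n_random = n_random,
                 degenerate = null_sd == 0,
                 samples = samples),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: observed %.4g, null %.4g +/- %.4g (n=%d%s)\n",
              x$metric_name, x$observed, x$null_mean, x$null_sd, x$n_random,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' One degree-preserving randomization of a directed network
#'
#' Applies `swaps_per_edge * |E|` directed double-edge-swap attempts starting
#' from the observed graph, using the current RNG state (seed with
#' `set.seed()` for reproducibility).
#'
#' @param net a `directed_network`.
#' @param swaps_per_edge swap attempts per edge.
#' @return a `directed_network` with identical in- and out-degree sequences.
#' @export
randomize_degree_preserving <- function(net, swaps_per_edge = 10L) {
  stopifnot(inherits(net, "directed_network"))
  m <- nrow(net$edges)
  re <- swap_randomize_cpp(net$edges - 1L, net$n_nodes,
                           as.integer(swaps_per_edge * m))
  directed_network(net$n_nodes, re + 1L, validate = FALSE)
}

#' Standardize an observed metric against its null distribution
#'
#' z = (observed - mean(null)) / sd(null).  A degenerate null (zero sd)
#' yields 0 when the observed value equals the null mean and `NA` (the
#' undefined-value sentinel) otherwise; such iterations are dropped from
#' series averaging.
#'
#' @param observed observed metric value (defaults to the one stored in
#'   `null`).
#' @param null a `null_distribution`.
#' @return scalar z-score, possibly `NA`.
#' @export
zscore <- function(observed = NULL, null) {
  stopifnot(inherits(null, "null_distribution"))
  observed <- observed %||% null$observed
  if (null$null_sd == 0) {
    if (isTRUE(all.equal(observed, null$null_mean))) return(0)
    return(NA_real_)
  }
  (observed - null$null_mean) / null$null_sd
}

# named metric registry used by metric_series / summarize_recording
metric_function <- function(name) {
  switch(name,
         bc = function(g) mean(betweenness_centrality(g)),
         assortativity = degree_assortativity,
         clustering = clustering_coefficient,
         efficiency = global_efficiency,
         stop(sprintf("unknown metric '%s'", name), call. = FALSE))
}

#' Per-iteration z-scored metric series over boxcar networks
#'
#' For every boxcar iteration the metric (node-level metrics are averaged
#' over the nodes, e.g. mean betweenness over the 12 flies) is z-scored
#' against that iteration's own degree-preserving null ensemble; the series
#' mean is the recording-level summary (one recording = one sample).
#' Iterations with an undefined z (degenerate null at a different observed
#' value) are dropped from the mean with a message.
#'
#' @param networks list of `directed_network` (>= 1).
#' @param metric metric name (`"bc"`, `"assortativity"`, `"clustering"`,
#'   `"efficiency"`) or a function `directed_network -> scalar`.
#' @param n_random null samples per iteration.
#' @param rng_seed master seed; per-iteration seeds are derived from it.
#' @param swaps_per_edge swap attempts per edge per null sample.
#' @return a `metric_series` object: `metric_name`, `per_iteration_z`,
#'   `mean_z`, `n_dropped`.
#' @export
metric_series <- function(networks, metric = "bc", n_random = 10000L,
                          rng_seed = NULL, swaps_per_edge = 10L) {
  if (!is.list(networks) || length(networks) == 0L) {
    stop("empty network series: no boxcar iterations to score", call. = FALSE)
  }
  metric_name <- if (is.character(metric)) metric else "custom"
  fn <- if (is.character(metric)) metric_function(metric) else metric
  rng_seed <- rng_seed %||% sample.int(2^31 - 1, 1)

  z <- vapply(seq_along(networks), function(i) {
    null <- random_null(networks[[i]], metric = fn, n_random = n_random,
                        rng_seed = derive_seed(rng_seed, i),
                        swaps_per_edge = swaps_per_edge,
                        metric_name = metric_name)
    zscore(null$observed, null)
  }, numeric(1))

  n_dropped <- sum(is.na(z))
  if (n_dropped > 0L) {
    message(sprintf("metric_series(%s): dropped %d/%d iterations with undefined z",
                    metric_name, n_dropped, length(z)))
  }
  structure(list(metric_name = metric_name,
                 per_iteration_z = z,
                 mean_z = mean(z, na.rm = TRUE),
                 n_dropped = n_dropped),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s: %d iterations, mean z = %.4g (%d dropped)\n",
              x$metric_name, length(x$per_iteration_z), x$mean_z, x$n_dropped))
  invisible(x)
}

#' Per-recording summary of z-scored network metrics
#'
#' Runs the full single-recording pipeline: detect events, take the unique
#' interaction stream, build boxcar networks, z-score the requested metrics
#' per iteration, and add movement and interaction rate.
#'
#' @param traj a `fly_trajectory`.
#' @param criteria an `interaction_criteria`.
#' @param window_size boxcar window (default 33 unique interactions, i.e.
#'   25% density for 12 flies).
#' @param n_random null samples per iteration.
#' @param rng_seed master seed for the null ensembles.
#' @param metrics character vector among `"bc"`, `"assortativity"`,
#'   `"clustering"`, `"efficiency"`.
#' @param genotype optional label stored in the summary row.
#' @return one-row data.frame: genotype, n_events, n_unique, n_iterations,
#'   movement, interaction_rate, and `<metric>_z` columns (NA when the
#'   recording is too sparse for any boxcar window).
#' @export
summarize_recording <- function(traj, criteria = interaction_criteria(),
                                window_size = 33L, n_random = 10000L,
                                rng_seed = NULL,
                                metrics = c("bc", "assortativity",
                                            "clustering", "efficiency"),
                                genotype = NA_character_) {
  events <- detect_interactions(traj, criteria)
  stream <- unique_interaction_stream(events)
  networks <- boxcar_networks(stream, window_size = window_size)
  rng_seed <- rng_seed %||% sample.int(2^31 - 1, 1)

  row <- data.frame(genotype = genotype,
                    n_events = nrow(events),
                    n_unique = nrow(stream),
                    n_iterations = length(networks),
                    movement = movement_rate(traj),
                    interaction_rate = interaction_rate(events, traj))
  for (k in seq_along(metrics)) {
    m <- metrics[k]
    col <- paste0(m, "_z")
    row[[col]] <- if (length(networks) > 0L) {
      metric_series(networks, metric = m, n_random = n_random,
                    rng_seed = derive_seed(rng_seed, 1000L + k))$mean_z
    } else {
      NA_real_
    }
  }
  row
}
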