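#' Parameters for the agent-based arena simulator
#'
#' The simulator emulates one group recording: `n_flies` walkers in a
#' circular arena, moving by a correlated random walk (heading diffusion +
#' multiplicative speed noise) with an attraction term that steers a fly
#' toward a neighbour within `attraction_radius`.  Flies aggregate at one of
#' two home sites (local clustering, as in real fly groups), which spatially
#' assorts interactions into two resident communities.  A neighbour's pull
#' is weighted by its attractiveness `1 + hub_bias`; when `hub_bias > 0` the
#' hub flies become highly attractive home-less rovers that residents engage
#' whenever they visit, so the hubs act as gatekeepers bridging the two
#' communities and raise the group's standardized betweenness centrality.
#' With `hub_bias = 0` the hub designation is inert and all flies follow
#' identical rules.
#'
#' @param n_flies number of flies in the arena (>= 2).
#' @param arena_diameter arena diameter in mm.
#' @param duration recording length in seconds.
#' @param frame_rate frames per second.
#' @param mean_body_length mean fly body length in mm.
#' @param speed_mean mean walking speed in mm/s; per-frame speeds are
#'   `speed_mean * max(0, 1 + cv * eps)` with `cv = speed_sd / speed_mean`,
#'   so `speed_mean = 0` gives perfectly stationary flies.
#' @param speed_sd approximate s.d. of walking speed in mm/s.
#' @param turn_sd heading diffusion per frame, radians.
#' @param attraction_strength per-fly steering gain toward the chosen
#'   neighbour (scalar or length-`n_flies` vector, dimensionless, each in
#'   \[0, 1\] after the hub weighting is applied it is clamped at 1).
#' @param attraction_radius neighbour cutoff radius in mm.
#' @param hub_bias extra attractiveness of the hub flies (dimensionless,
#'   >= 0); 0 makes all flies exchangeable.
#' @param hub_flies indices of the flies carrying `hub_bias` (default flies
#'   1 and 2).
#' @param engage_time mean duration in seconds of a social (attraction-on)
#'   bout; flies decelerate within `pause_radius` of their target while
#'   engaged, emulating the near-stationary contact bouts of real fly
#'   groups.
#' @param roam_time mean duration in seconds of the roaming
#'   (attraction-off) state between bouts, which remixes the group.
#' @param pause_radius distance in mm below which an engaged fly slows
#'   down proportionally to its distance from the target.
#' @param rng_seed master seed; per-fly noise substreams are derived from it
#'   so runs are reproducible and per-fly streams are stable under changes of
#'   `n_flies`.
#' @param fly_seeds optional explicit per-fly seeds (length `n_flies`),
#'   overriding the derivation from `rng_seed`; used to test exchangeability.
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
simulation_params <- function(n_flies = 12L,
                              arena_diameter = 60,
                              duration = 1800,
                              frame_rate = 30,
                              mean_body_length = 2.5,
                              speed_mean = 4,
                              speed_sd = 2,
                              turn_sd = 0.15,
                              attraction_strength = 0.35,
                              attraction_radius = 10,
                              hub_bias = 0,
                              hub_flies = c(1L, 2L),
                              engage_time = 4,
                              roam_time = 6,
                              pause_radius = 3,
                              rng_seed = 1L,
                              fly_seeds = NULL) {
  p <- list(n_flies = as.integer(n_flies), arena_diameter = arena_diameter,
            duration = duration, frame_rate = frame_rate,
            mean_body_length = mean_body_length, speed_mean = speed_mean,
            speed_sd = speed_sd, turn_sd = turn_sd,
            attraction_strength = attraction_strength,
            attraction_radius = attraction_radius, hub_bias = hub_bias,
            hub_flies = as.integer(hub_flies), engage_time = engage_time,
            roam_time = roam_time, pause_radius = pause_radius,
            rng_seed = as.integer(rng_seed),
            fly_seeds = if (!is.null(fly_seeds)) as.integer(fly_seeds))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  bad <- function(field, why) {
    stop(sprintf("invalid simulation parameter '%s': %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(field, "must be a single finite number")
    }
    v
  }
  if (num1("n_flies") < 2) bad("n_flies", "must be >= 2")
  if (num1("arena_diameter") <= 0) bad("arena_diameter", "must be > 0")
  if (num1("duration") <= 0) bad("duration", "must be > 0")
  if (num1("frame_rate") <= 0) bad("frame_rate", "must be > 0")
  if (num1("mean_body_length") <= 0) bad("mean_body_length", "must be > 0")
  if (num1("speed_mean") < 0) bad("speed_mean", "must be >= 0")
  if (num1("speed_sd") < 0) bad("speed_sd", "must be >= 0")
  if (num1("turn_sd") < 0) bad("turn_sd", "must be >= 0")
  if (num1("attraction_radius") <= 0) bad("attraction_radius", "must be > 0")
  if (num1("hub_bias") < 0) bad("hub_bias", "must be >= 0")
  if (num1("engage_time") <= 0) bad("engage_time", "must be > 0")
  if (num1("roam_time") <= 0) bad("roam_time", "must be > 0")
  if (num1("pause_radius") <= 0) bad("pause_radius", "must be > 0")
  a <- p$attraction_strength
  if (!is.numeric(a) || !(length(a) %in% c(1L, p$n_flies)) ||
      any(!is.finite(a)) || any(a < 0)) {
    bad("attraction_strength", "must be a non-negative scalar or per-fly vector")
  }
  if (any(p$hub_flies < 1L) || any(p$hub_flies > p$n_flies)) {
    bad("hub_flies", "indices must lie in 1..n_flies")
  }
  if (!is.null(p$fly_seeds) && length(p$fly_seeds) != p$n_flies) {
    bad("fly_seeds", "must have one seed per fly")
  }
  invisible(p)
}

#' Preset simulation parameters emulating the two centrality phenotypes
#'
#' `"high_bc"` raises `hub_bias` (two highly attractive roving flies become
#' the gatekeepers that bridge the group's two resident communities),
#' `"low_bc"` keeps `hub_bias = 0` (exchangeable flies, communities bridged
#' only by chance encounters).  All other fields are identical, so the
#' presets differ only in induced social structure.
#'
#' @param name `"high_bc"` or `"low_bc"`.
#' @return a `sim_params` object.
#' @export
genotype_preset <- function(name) {
  presets <- list(
    high_bc = simulation_params(hub_bias = 30),
    low_bc  = simulation_params(hub_bias = 0)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop(sprintf("unknown genotype preset '%s'; available: %s",
                 paste(name, collapse = ","),
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

wrap_angle <- function(a) {
  # wrap to [-pi, pi)
  ((a + pi) %% (2 * pi)) - pi
}

#' Simulate one arena recording
#'
#' Runs the correlated random walk with neighbour attraction and reflective
#' arena boundary.  All randomness is drawn up-front from per-fly substreams
#' derived from `rng_seed`, making the coupled dynamics deterministic given
#' the seed and equivariant under joint permutation of fly labels and seeds
#' when `hub_bias = 0`.
#'
#' @param params a `sim_params` object.
#' @return a `fly_trajectory` data.frame with columns `frame` (0-based,
#'   contiguous), `fly_id`, `x_mm`, `y_mm`, `orientation_rad` in
#'   \[-pi, pi), `body_length_mm`; attributes `frame_rate` and
#'   `arena_diameter`.
#' @export
simulate_arena <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  n  <- params$n_flies
  fr <- params$frame_rate
  n_steps <- as.integer(round(params$duration * fr))
  dt <- 1 / fr
  radius <- params$arena_diameter / 2
  r_eff  <- radius * 0.98          # keep centres strictly inside the wall

  seeds <- params$fly_seeds %||%
    vapply(seq_len(n), function(i) derive_seed(params$rng_seed, i), integer(1))

  # Social geography: every fly carries a home range centred on one of two
  # aggregation sites (a well-documented feature of fly groups is local
  # clustering), so interactions are spatially assorted into two resident
  # communities.  When hub_bias > 0 the hub flies instead become highly
  # attractive rovers with no home range: residents engage them whenever
  # they visit, making the hubs the gatekeepers that bridge the two
  # communities.  With hub_bias = 0 the hub designation is inert and all
  # flies follow identical (seed-exchangeable) rules.
  home_centres <- cbind(c(-0.5, 0.5) * r_eff, c(0, 0))
  home_radius <- 8
  home_gain <- 0.6

  # per-fly noise substreams, drawn up-front
  turn_noise  <- matrix(0, n_steps, n)
  speed_noise <- matrix(0, n_steps, n)
  state_noise <- matrix(0, n_steps, n)
  x <- y <- theta <- numeric(n)
  body_len <- numeric(n)
  community <- integer(n)
  is_hub <- rep(FALSE, n)
  if (params$hub_bias > 0) is_hub[params$hub_flies] <- TRUE
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    community[i] <- 1L + (runif(1) >= 0.5)
    rr  <- r_eff * 0.9 * sqrt(runif(1))
    phi <- runif(1, -pi, pi)
    scatter <- rnorm(2, 0, 3)
    if (is_hub[i]) {          # rovers start anywhere in the arena
      x[i] <- rr * cos(phi); y[i] <- rr * sin(phi)
    } else {                  # residents start inside their home range
      x[i] <- home_centres[community[i], 1] + scatter[1]
      y[i] <- home_centres[community[i], 2] + scatter[2]
    }
    theta[i] <- runif(1, -pi, pi)
    body_len[i] <- params$mean_body_length * exp(rnorm(1, 0, 0.03))
    turn_noise[, i]  <- rnorm(n_steps)
    speed_noise[, i] <- rnorm(n_steps)
    state_noise[, i] <- runif(n_steps)
  }
  rr0 <- sqrt(x^2 + y^2)
  clip <- rr0 > r_eff * 0.95
  if (any(clip)) {
    x[clip] <- x[clip] * r_eff * 0.95 / rr0[clip]
    y[clip] <- y[clip] * r_eff * 0.95 / rr0[clip]
  }

  gain <- rep_len(params$attraction_strength, n)
  attractiveness <- rep(1, n)
  attractiveness[is_hub] <- 1 + params$hub_bias
  gain[is_hub] <- 0          # rovers patrol instead of chasing neighbours
  hx <- home_centres[community, 1]
  hy <- home_centres[community, 2]
  cv <- if (params$speed_mean > 0) params$speed_sd / params$speed_mean else 0
  p_disengage <- min(1, dt / params$engage_time)
  p_engage <- min(1, dt / params$roam_time)
  social <- rep(TRUE, n)

  X <- matrix(0, n_steps, n); Y <- matrix(0, n_steps, n)
  TH <- matrix(0, n_steps, n)
  X[1, ] <- x; Y[1, ] <- y; TH[1, ] <- theta

  for (t in seq_len(n_steps - 1L)) {
    dx <- outer(x, x, function(a, b) b - a)
    dy <- outer(y, y, function(a, b) b - a)
    d2 <- dx * dx + dy * dy
    diag(d2) <- Inf
    # w[i, j]: pull of neighbour j on fly i within the sensing radius,
    # distance-discounted and weighted by the neighbour's attractiveness;
    # with hub_bias = 0 the chosen target is exactly the nearest neighbour
    w <- sweep(1 / sqrt(d2), 2, attractiveness, "*")
    w[d2 > params$attraction_radius^2] <- 0
    target <- max.col(w, ties.method = "first")
    # two-state bout dynamics: social flies steer toward a neighbour and
    # pause near it; roaming flies ignore neighbours, which remixes the
    # group and rotates crowd membership
    social <- ifelse(social, state_noise[t, ] >= p_disengage,
                     state_noise[t, ] < p_engage)
    # residents outside their home range head home and ignore neighbours
    dhx <- hx - x; dhy <- hy - y
    homing <- !is_hub & (dhx * dhx + dhy * dhy > home_radius^2)
    has_target <- w[cbind(seq_len(n), target)] > 0 & social & gain > 0 &
      !homing

    kappa <- pmin(1, gain * attractiveness[target]) * has_target
    phi_t <- atan2(y[target] - y, x[target] - x)
    phi_h <- atan2(dhy, dhx)
    theta <- wrap_angle(theta + params$turn_sd * turn_noise[t, ] +
                          kappa * wrap_angle(phi_t - theta) +
                          (home_gain * homing) * wrap_angle(phi_h - theta))

    step <- params$speed_mean * pmax(0, 1 + cv * speed_noise[t, ]) * dt
    d_target <- sqrt(d2[cbind(seq_len(n), target)])
    slow <- ifelse(has_target,
                   pmax(0.1, pmin(1, d_target / params$pause_radius)), 1)
    step <- step * slow
    xn <- x + cos(theta) * step
    yn <- y + sin(theta) * step

    rn <- sqrt(xn * xn + yn * yn)
    out <- rn > r_eff
    if (any(out)) {
      sc <- pmax(2 * r_eff - rn[out], 0.1 * r_eff) / rn[out]
      xn[out] <- xn[out] * sc
      yn[out] <- yn[out] * sc
      alpha <- atan2(yn[out], xn[out])
      theta[out] <- wrap_angle(2 * alpha + pi - theta[out])
    }
    x <- xn; y <- yn
    X[t + 1L, ] <- x; Y[t + 1L, ] <- y; TH[t + 1L, ] <- theta
  }

  traj <- data.frame(
    frame = rep(0:(n_steps - 1L), each = n),
    fly_id = rep(seq_len(n), times = n_steps),
    x_mm = as.vector(t(X)),
    y_mm = as.vector(t(Y)),
    orientation_rad = as.vector(t(TH)),
    body_length_mm = rep(body_len, times = n_steps)
  )
  structure(traj,
            frame_rate = fr,
            arena_diameter = params$arena_diameter,
            class = c("fly_trajectory", "data.frame"))
}

#' @export
print.fly_trajectory <- function(x, ...) {
  cat(sprintf("<fly_trajectory> %d flies, %d frames @ %g Hz (%.1f min)\n",
              length(unique(x$fly_id)), length(unique(x$frame)),
              attr(x, "frame_rate"),
              length(unique(x$frame)) / attr(x, "frame_rate") / 60))
  invisible(x)
}

#' Write / read a trajectory table as headered CSV
#'
#' The frame rate and arena diameter ride along as `#`-prefixed comment
#' lines ahead of the CSV header, so a file round-trips without a sidecar.
#'
#' @param traj a `fly_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "fly_trajectory"))
  con <- file(path, "w")
  writeLines(c(sprintf("# frame_rate=%.10g", attr(traj, "frame_rate")),
               sprintf("# arena_diameter=%.10g", attr(traj, "arena_diameter"))),
             con)
  close(con)
  data.table::fwrite(as.data.frame(traj), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("trajectory file not found: %s", path), call. = FALSE)
  }
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(m) == 0L) return(default)
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
  }
  dt <- data.table::fread(path, skip = length(meta), header = TRUE,
                          data.table = FALSE)
  need <- c("frame", "fly_id", "x_mm", "y_mm", "orientation_rad",
            "body_length_mm")
  if (!all(need %in% names(dt))) {
    stop(sprintf("malformed trajectory CSV '%s': missing columns %s", path,
                 paste(setdiff(need, names(dt)), collapse = ", ")),
         call. = FALSE)
  }
  structure(dt[need],
            frame_rate = get_meta("frame_rate", 30),
            arena_diameter = get_meta("arena_diameter", 60),
            class = c("fly_trajectory", "data.frame"))
}
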