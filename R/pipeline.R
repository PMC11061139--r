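#' Write simulated trajectory recordings for a genotype preset
#'
#' Produces `n_recordings` seeded trajectory CSVs named
#' `<preset>_<k>.csv` under `out_dir`; each recording's seed is derived
#' from `rng_seed` and the file index, so a fixed seed reproduces the file
#' set byte for byte.
#'
#' @param preset `"high_bc"` or `"low_bc"`.
#' @param n_recordings number of recordings (0 writes nothing).
#' @param rng_seed master seed.
#' @param out_dir output directory (created if needed).
#' @param params optional `sim_params` overriding the preset.
#' @return character vector of written paths, invisibly.
#' @export
simulate_command <- function(preset, n_recordings, rng_seed = 1L,
                             out_dir = ".", params = NULL) {
  base <- params %||% genotype_preset(preset)
  n_recordings <- as.integer(n_recordings)
  if (n_recordings < 0L) stop("n_recordings must be >= 0", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (k in seq_len(n_recordings)) {
    p <- base
    p$rng_seed <- derive_seed(rng_seed, k)
    traj <- simulate_arena(p)
    path <- file.path(out_dir, sprintf("%s_%03d.csv", preset, k))
    write_trajectory_csv(traj, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

default_pipeline_config <- function() {
  list(paths = list(trajectory_dir = ".", output_dir = "flynetbc_out"),
       criteria = list(),
       window_size = 33L,
       n_random = 10000L,
       rng_seed = 1L,
       alpha_context = "default",
       metrics = c("bc", "assortativity", "clustering", "efficiency"),
       stat_metric = "bc_z",
       outlier_scope = "per_genotype",
       n_workers = 1L)
}

#' Load and validate a pipeline configuration
#'
#' Configuration is a JSON file (or an R list); omitted fields take the
#' defaults (window 33, n_random 10000, alpha context "default").
#'
#' @param config path to a JSON file or a named list.
#' @return validated config list.
#' @export
load_pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or JSON path", call. = FALSE)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  cfg$window_size <- as.integer(cfg$window_size)
  cfg$n_random <- as.integer(cfg$n_random)
  if (cfg$window_size < 1L) stop("config violation: window_size must be >= 1",
                                 call. = FALSE)
  if (cfg$n_random < 1L) stop("config violation: n_random must be >= 1",
                              call. = FALSE)
  if (!cfg$outlier_scope %in% c("per_genotype", "pooled")) {
    stop("config violation: outlier_scope must be 'per_genotype' or 'pooled'",
         call. = FALSE)
  }
  # n_workers is a contract, not an optimization: null-model sampling is
  # sequential and seeded, so results are independent of the worker count
  if (as.integer(cfg$n_workers) < 1L) {
    stop("config violation: n_workers must be >= 1", call. = FALSE)
  }
  context_alpha(cfg$alpha_context)   # validates the label
  cfg
}

genotype_from_filename <- function(path) {
  sub("_[0-9]+$", "", tools::file_path_sans_ext(basename(path)))
}

#' Run the full trajectory-to-statistics pipeline
#'
#' For every trajectory CSV: detect interactions with the genotype's
#' criteria, build the unique-interaction stream and boxcar networks,
#' z-score the configured metrics against degree-preserving nulls, and emit
#' one summary row; recordings are grouped by genotype (parsed from the file
#' name prefix) and compared on `stat_metric` with outlier removal, one-way
#' ANOVA and Tukey-Kramer at the context alpha.  A manifest with the config
#' hash and seed is written alongside the outputs.
#'
#' @param config pipeline config (list or JSON path), see
#'   [load_pipeline_config()]; `trajectories` may list explicit files,
#'   otherwise all `*.csv` under `paths$trajectory_dir` are used.
#' @param quiet suppress per-stage progress messages.
#' @return the summary data.frame, invisibly; artifacts are written under
#'   `paths$output_dir` (`summary.csv`, per-recording iteration CSVs,
#'   `stats_report.csv` / `stats_report.txt`, `manifest.json`).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  files <- cfg$trajectories %||% {
    if (!dir.exists(cfg$paths$trajectory_dir)) {
      stop(sprintf("input stage: trajectory directory not found: %s",
                   cfg$paths$trajectory_dir), call. = FALSE)
    }
    sort(list.files(cfg$paths$trajectory_dir, pattern = "\\.csv$",
                    full.names = TRUE))
  }
  if (length(files) == 0L) {
    stop("input stage: no trajectory CSV files found", call. = FALSE)
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop(sprintf("input stage: missing trajectory file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out_dir <- cfg$paths$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    gt <- genotype_from_filename(f)
    t0 <- Sys.time()
    traj <- read_trajectory_csv(f)
    crit <- load_criteria(cfg$criteria, genotype = gt)
    row <- summarize_recording(traj, crit,
                               window_size = cfg$window_size,
                               n_random = cfg$n_random,
                               rng_seed = derive_seed(cfg$rng_seed, i),
                               metrics = cfg$metrics,
                               genotype = gt)
    row$recording <- basename(f)
    rows[[i]] <- row
    say("network stage: %s -> %d events, %d unique, %d iterations [%.1fs]",
        basename(f), row$n_events, row$n_unique, row$n_iterations,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  summary_df <- do.call(rbind, rows)
  data.table::fwrite(summary_df, file.path(out_dir, "summary.csv"))

  stat_col <- cfg$stat_metric
  report_txt <- character(0)
  groups <- split(summary_df[[stat_col]], summary_df$genotype)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (cfg$outlier_scope == "pooled") {
    pooled <- unlist(groups, use.names = FALSE)
    if (length(pooled) >= 4L) {
      kept <- remove_outliers(pooled)
      groups <- lapply(groups, function(g) g[g %in% kept])
    }
  } else {
    groups <- lapply(groups, function(g) if (length(g) >= 4L) remove_outliers(g) else g)
  }
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) >= 2L) {
    cmp <- apply_alpha(tukey_kramer(groups), cfg$alpha_context)
    pw <- cmp$pairwise
    data.table::fwrite(pw, file.path(out_dir, "stats_report.csv"))
    report_txt <- c(
      sprintf("metric: %s", stat_col),
      sprintf("one-way ANOVA: F(%d,%d) = %.4f, p = %.4g, alpha = %g",
              cmp$df_between, cmp$df_within, cmp$f_stat, cmp$p_value,
              cmp$alpha),
      "group means / letters:",
      sprintf("  %-14s %9.4f  n=%-3d %s", names(cmp$letters),
              cmp$means, cmp$ns, cmp$letters))
    writeLines(report_txt, file.path(out_dir, "stats_report.txt"))
    say("stats stage: F(%d,%d) = %.3f, p = %.3g", cmp$df_between,
        cmp$df_within, cmp$f_stat, cmp$p_value)
  } else {
    say("stats stage: skipped (fewer than 2 genotypes with >= 2 recordings)")
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(package = "flynetbc",
                   version = as.character(utils::packageVersion("flynetbc")),
                   rng_seed = cfg$rng_seed,
                   config_md5 = unname(tools::md5sum(tf)),
                   n_recordings = nrow(summary_df))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary_df)
}
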