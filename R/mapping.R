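#' Recombinant chromosome line
#'
#' Describes one recombinant line as an ordered tiling of chromosome-3
#' segments by strain of origin (CS, OR, or unknown for unsequenced gaps)
#' plus its betweenness-centrality phenotype call.  Coordinates are 1-based
#' inclusive bp on input (genotyping-marker convention) and stored half-open
#' internally.
#'
#' @param line_id label.
#' @param segments data.frame with columns `start`, `end` (1-based
#'   inclusive, start <= end), `origin` in {"CS", "OR", "unknown"};
#'   segments must be sorted and non-overlapping.
#' @param phenotype `"CS_like"`, `"OR_like"` or `"intermediate"`.
#' @return a `recombinant_line` object.
#' @export
recombinant_line <- function(line_id, segments, phenotype) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "origin") %in% names(segments)))
  if (!phenotype %in% c("CS_like", "OR_like", "intermediate")) {
    stop(sprintf("line %s: unknown phenotype '%s'", line_id, phenotype),
         call. = FALSE)
  }
  if (!all(segments$origin %in% c("CS", "OR", "unknown"))) {
    stop(sprintf("line %s: segment origins must be CS, OR or unknown", line_id),
         call. = FALSE)
  }
  s0 <- as.numeric(segments$start) - 1   # half-open [s0, e)
  e <- as.numeric(segments$end)
  if (any(s0 >= e)) {
    stop(sprintf("line %s: segments need start <= end", line_id), call. = FALSE)
  }
  ord <- order(s0)
  s0 <- s0[ord]; e <- e[ord]
  origin <- as.character(segments$origin)[ord]
  if (any(s0[-1] < e[-length(e)])) {
    stop(sprintf("line %s: segments overlap", line_id), call. = FALSE)
  }
  structure(list(line_id = as.character(line_id),
                 start0 = s0, end = e, origin = origin,
                 phenotype = phenotype),
            class = "recombinant_line")
}

# interval-set helpers on half-open [start, end) rows of a 2-col matrix
merge_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (r in seq_len(nrow(m))[-1]) {
    last <- nrow(out)
    if (m[r, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], m[r, 2])
    } else {
      out <- rbind(out, m[r, ])
    }
  }
  out
}

intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(a[0, , drop = FALSE])
  res <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    keep <- lo < hi
    if (any(keep)) res <- rbind(res, cbind(lo[keep], hi[keep]))
  }
  merge_intervals(res)
}

#' Chromosomal region implicated by one recombinant line
#'
#' A line phenotypically matching one parental strain implicates the
#' segments inherited from that strain (CS_like -> CS segments, OR_like ->
#' OR segments).  Unsequenced (`unknown`) segments are compatible with
#' either origin and are therefore included, so downstream intersections are
#' never wrongly emptied by a genotyping gap.
#'
#' @param line a `recombinant_line` with an informative phenotype.
#' @return data.frame `start`, `end` (1-based inclusive), merged.
#' @export
implicated_region <- function(line) {
  stopifnot(inherits(line, "recombinant_line"))
  if (line$phenotype == "intermediate") {
    stop(sprintf("line %s: intermediate phenotype is uninformative", line$line_id),
         call. = FALSE)
  }
  want <- if (line$phenotype == "CS_like") "CS" else "OR"
  keep <- line$origin %in% c(want, "unknown")
  m <- cbind(line$start0[keep], line$end[keep])
  m <- merge_intervals(m)
  data.frame(start = m[, 1] + 1, end = m[, 2])
}

#' Candidate locus interval from a set of recombinant lines
#'
#' Intersects the implicated regions of every informative line; lines with
#' intermediate phenotype are skipped with a message.  An empty intersection
#' means the phenotype calls are mutually inconsistent and raises an error
#' naming the first line that emptied it.
#'
#' @param lines list of `recombinant_line` objects (>= 1 informative).
#' @return data.frame `start`, `end` (1-based inclusive).
#' @export
candidate_interval <- function(lines) {
  if (inherits(lines, "recombinant_line")) lines <- list(lines)
  informative <- Filter(function(l) l$phenotype != "intermediate", lines)
  skipped <- length(lines) - length(informative)
  if (skipped > 0L) {
    message(sprintf("candidate_interval: skipped %d intermediate-phenotype line(s)",
                    skipped))
  }
  if (length(informative) == 0L) {
    stop("no informative recombinant lines", call. = FALSE)
  }
  regions <- lapply(informative, function(l) {
    r <- implicated_region(l)
    cbind(r$start - 1, r$end)
  })
  acc <- regions[[1]]
  if (nrow(acc) == 0L) {
    stop(sprintf(
      "inconsistent recombinant lines: line %s implicates no region",
      informative[[1]]$line_id), call. = FALSE)
  }
  for (i in seq_along(regions)[-1]) {
    acc <- intersect_intervals(acc, regions[[i]])
    if (nrow(acc) == 0L) {
      stop(sprintf(
        "inconsistent recombinant lines: intersection emptied by line %s",
        informative[[i]]$line_id), call. = FALSE)
    }
  }
  data.frame(start = acc[, 1] + 1, end = acc[, 2])
}

#' Read recombinant line descriptions from CSV
#'
#' Expected columns: `line_id`, `seg_start`, `seg_end`, `origin`,
#' `phenotype` (one phenotype per line id; coordinates 1-based inclusive).
#'
#' @param path CSV file.
#' @return list of `recombinant_line` objects.
#' @export
read_recombinant_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("recombinant CSV not found: %s", path), call. = FALSE)
  }
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("line_id", "seg_start", "seg_end", "origin", "phenotype")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed recombinant CSV: missing columns %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  lapply(split(df, df$line_id), function(d) {
    recombinant_line(d$line_id[1],
                     data.frame(start = d$seg_start, end = d$seg_end,
                                origin = d$origin),
                     d$phenotype[1])
  })
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame `start`, `end` in 1-based inclusive bp.
#' @param path output file.
#' @param chrom chromosome name (default `"3L"`).
#' @param name feature name column.
#' @export
write_bed <- function(intervals, path, chrom = "3L", name = "candidate_locus") {
  bed <- data.frame(chrom = chrom,
                    start = as.integer(intervals$start - 1),
                    end = as.integer(intervals$end),
                    name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
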