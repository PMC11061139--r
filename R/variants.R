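#' Read a multi-FASTA file as a named character vector
#'
#' Uses Biostrings when available, with a plain-text fallback parser.
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    return(setNames(toupper(as.character(ss)), names(ss)))
  }
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records found", call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    toupper(paste0(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
  }, character(1))
  setNames(seqs, sub("^>\\s*", "", lines[hdr]))
}

#' Tally nucleotides at one gene position, per locality
#'
#' Sequences whose character at `position` (1-based by convention; see
#' `index_base`) is not A, C, G or T (case-insensitive) are excluded for
#' nucleotide ambiguity and counted in `n_removed`; this covers IUPAC
#' ambiguity codes, N and alignment gaps.  Sequences shorter than the
#' position are collected as per-record errors and excluded from both the
#' tally and `n_removed`.
#'
#' @param sequences a FASTA path, a named character vector, or a
#'   Biostrings XStringSet.
#' @param position nucleotide index within the gene region (default 1049,
#'   the site distinguishing the two strain alleles).
#' @param locality optional explicit per-sequence locality labels;
#'   otherwise parsed from the sequence names.
#' @param locality_delim,locality_field header field split rule used when
#'   `locality` is not given (default: field 2 split on `"|"`).
#' @param index_base 1 (default) or 0; with 0, `position` is interpreted
#'   0-based and shifted.
#' @return an `allele_table`: list with `position`, `counts` (locality x
#'   ACGT integer matrix), `n_removed`, `errors` (character), `n_input`.
#' @export
tally_position <- function(sequences, position = 1049L, locality = NULL,
                           locality_delim = "|", locality_field = 2L,
                           index_base = 1L) {
  if (is.character(sequences) && length(sequences) == 1L && is.null(names(sequences)) &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  if (!is.character(sequences)) {
    sequences <- setNames(toupper(as.character(sequences)), names(sequences))
  } else {
    sequences <- setNames(toupper(sequences), names(sequences))
  }
  if (!index_base %in% c(0L, 1L)) {
    stop("index_base must be 0 or 1", call. = FALSE)
  }
  pos <- as.integer(position) + (1L - as.integer(index_base))
  if (pos < 1L) stop("position must be positive", call. = FALSE)

  nseq <- length(sequences)
  if (is.null(locality)) {
    locality <- vapply(names(sequences) %||% rep("", nseq), function(nm) {
      parts <- strsplit(nm, locality_delim, fixed = TRUE)[[1]]
      if (length(parts) >= locality_field) parts[locality_field] else "unknown"
    }, character(1), USE.NAMES = FALSE)
  }
  if (length(locality) != nseq) {
    stop("locality labels must match the number of sequences", call. = FALSE)
  }

  nts <- c("A", "C", "G", "T")
  locs <- unique(locality)
  counts <- matrix(0L, length(locs), 4L, dimnames = list(locs, nts))
  n_removed <- 0L
  errors <- character(0)
  for (i in seq_len(nseq)) {
    s <- sequences[[i]]
    if (nchar(s) < pos) {
      errors <- c(errors, sprintf(
        "record %d (%s): length %d < position %d",
        i, names(sequences)[i] %||% "?", nchar(s), pos))
      next
    }
    ch <- substr(s, pos, pos)
    if (ch %in% nts) {
      counts[locality[i], ch] <- counts[locality[i], ch] + 1L
    } else {
      n_removed <- n_removed + 1L
    }
  }
  if (length(errors) > 0L) {
    warning(sprintf("%d sequence(s) shorter than position %d were skipped",
                    length(errors), pos), call. = FALSE)
  }
  structure(list(position = as.integer(position), counts = counts,
                 n_removed = n_removed, errors = errors, n_input = nseq),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> position %d: %d localities, %d retained, %d removed for ambiguity\n",
              x$position, nrow(x$counts), sum(x$counts), x$n_removed))
  invisible(x)
}

#' Overall frequency of a nucleotide in an allele table
#'
#' @param table an `allele_table`.
#' @param nucleotide one of "A", "C", "G", "T".
#' @return proportion of retained sequences carrying `nucleotide` at the
#'   tallied position.
#' @export
allele_frequency <- function(table, nucleotide) {
  stopifnot(inherits(table, "allele_table"))
  nucleotide <- toupper(nucleotide)
  if (!nucleotide %in% colnames(table$counts)) {
    stop(sprintf("unknown nucleotide '%s'", nucleotide), call. = FALSE)
  }
  total <- sum(table$counts)
  if (total == 0L) {
    stop("undefined allele frequency: no retained sequences", call. = FALSE)
  }
  sum(table$counts[, nucleotide]) / total
}

#' Chi-square homogeneity test over the locality x nucleotide table
#'
#' Pearson chi-square on the contingency table of retained counts;
#' all-zero rows and columns are dropped first, df = (rows-1)(cols-1).
#' N is reported as the retained-sequence count.
#'
#' @param table an `allele_table` or a counts matrix.
#' @return list with `x2`, `df`, `p`, `n`, `observed`, `expected`.
#' @export
chi_square_homogeneity <- function(table) {
  counts <- if (inherits(table, "allele_table")) table$counts else as.matrix(table)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("degenerate contingency table: need >= 2 localities and >= 2 nucleotides with nonzero totals",
         call. = FALSE)
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  x2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(x2 = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE), n = n,
       observed = counts, expected = expected)
}

#' Generate a synthetic variant FASTA set with controlled composition
#'
#' Builds `n_per_locality` sequences per locality over a common random gene
#' region, planting nucleotide A at `position` with per-locality probability
#' `freq_a` (otherwise C) and replacing the position by an ambiguity symbol
#' (N or -) with probability `ambig_rate`.  Headers are
#' `sample<i>|<locality>`, matching the default header parsing of
#' [tally_position()].
#'
#' @param localities character vector of locality labels.
#' @param n_per_locality sequences per locality (recycled).
#' @param freq_a per-locality probability of the A allele (recycled).
#' @param ambig_rate probability that the focal position is ambiguous.
#' @param seq_length gene-region length (>= position).
#' @param position focal position (1-based).
#' @param rng_seed seed.
#' @param path optional file to write; when given, returns the path.
#' @return named character vector of sequences (or `path`).
#' @export
simulate_variant_fasta <- function(localities, n_per_locality = 10L,
                                   freq_a = 0.1, ambig_rate = 0.1,
                                   seq_length = 1100L, position = 1049L,
                                   rng_seed = 1L, path = NULL) {
  if (seq_length < position) stop("seq_length must be >= position", call. = FALSE)
  set.seed(rng_seed)
  n_loc <- length(localities)
  n_per <- rep_len(as.integer(n_per_locality), n_loc)
  fa <- rep_len(freq_a, n_loc)
  base <- paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
                collapse = "")
  seqs <- character(0)
  for (l in seq_len(n_loc)) {
    for (k in seq_len(n_per[l])) {
      ch <- if (runif(1) < ambig_rate) {
        sample(c("N", "-", "Y", "R"), 1)
      } else if (runif(1) < fa[l]) "A" else "C"
      s <- base
      substr(s, position, position) <- ch
      seqs <- c(seqs, setNames(s, sprintf("sample%d|%s", length(seqs) + 1L,
                                          localities[l])))
    }
  }
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
    return(invisible(path))
  }
  seqs
}

#' Write an allele table's contingency counts as CSV
#' @param table an `allele_table`.
#' @param path output file.
#' @export
write_allele_csv <- function(table, path) {
  stopifnot(inherits(table, "allele_table"))
  df <- data.frame(locality = rownames(table$counts), table$counts,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}
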