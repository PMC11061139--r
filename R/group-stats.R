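#' Remove IQR outliers
#'
#' Drops values >= Q3 + 1.5 IQR or <= Q1 - 1.5 IQR, with quartiles computed
#' once on the input by linear interpolation (quantile type 7).  When
#' IQR = 0 the rule would remove every value under the boundary-inclusive
#' reading, so the input is returned unchanged (the rule's intent is tail
#' trimming).
#'
#' @param values numeric vector with at least 4 values.
#' @return the remaining values, in their original order.
#' @export
remove_outliers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    stop("too few samples for outlier screening (need >= 4)", call. = FALSE)
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(values)
  keep <- values < q[2] + 1.5 * iqr & values > q[1] - 1.5 * iqr
  values[keep]
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop(sprintf("every group needs >= 2 values (offending: %s)",
                 paste(names(groups)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  }
  groups
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA: F = MS_between / MS_within with
#' df_between = k - 1, df_within = N - k; p from the F distribution.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return a `group_comparison` object with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `ms_within`, per-group `means` and `ns`.
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- k - 1L
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f_stat <- if (ms_within == 0) {
    if (ms_between == 0) 0 else Inf
  } else {
    ms_between / ms_within
  }
  p <- pf(f_stat, df_between, df_within, lower.tail = FALSE)
  structure(list(groups = groups, f_stat = f_stat,
                 df_between = df_between, df_within = df_within,
                 p_value = p, ms_within = ms_within,
                 means = means, ns = ns, alpha = 0.05),
            class = "group_comparison")
}

#' Tukey-Kramer post hoc comparisons with compact letter display
#'
#' All pairwise comparisons via the studentized-range distribution with
#' unequal-n (Tukey-Kramer) standard errors
#' `SE_ij = sqrt(MS_within / 2 * (1/n_i + 1/n_j))`; two groups share a
#' letter iff they are not significantly different at `alpha`.
#'
#' @param groups named list of numeric vectors, or a `group_comparison`
#'   from [one_way_anova()].
#' @param alpha significance level for the letter display.
#' @return the `group_comparison` augmented with `pairwise` (data.frame:
#'   group1, group2, difference, se, q, p, significant) and `letters`
#'   (named character vector).
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  cmp <- if (inherits(groups, "group_comparison")) groups else one_way_anova(groups)
  k <- length(cmp$groups)
  labs <- names(cmp$groups)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]])
  pw$difference <- cmp$means[pairs[2, ]] - cmp$means[pairs[1, ]]
  pw$se <- sqrt(cmp$ms_within / 2 *
                  (1 / cmp$ns[pairs[1, ]] + 1 / cmp$ns[pairs[2, ]]))
  pw$q <- ifelse(pw$se > 0, abs(pw$difference) / pw$se,
                 ifelse(pw$difference == 0, 0, Inf))
  pw$p <- ptukey(pw$q, nmeans = k, df = cmp$df_within, lower.tail = FALSE)
  rownames(pw) <- NULL
  cmp$alpha <- alpha
  cmp$pairwise <- transform(pw, significant = p < alpha)
  cmp$letters <- letter_display(labs, cmp$means, cmp$pairwise, alpha)
  cmp
}

# Compact letter display by greedy clique cover over the non-significance
# graph, smallest mean first, with a repair pass guaranteeing that every
# non-significant pair shares at least one letter.
letter_display <- function(labs, means, pairwise, alpha) {
  k <- length(labs)
  nonsig <- matrix(TRUE, k, k, dimnames = list(labs, labs))
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise$p[r] < alpha) {
      nonsig[pairwise$group1[r], pairwise$group2[r]] <- FALSE
      nonsig[pairwise$group2[r], pairwise$group1[r]] <- FALSE
    }
  }
  ord <- order(means)
  cliques <- list()
  for (g in ord) {
    placed <- FALSE
    for (c in seq_along(cliques)) {
      if (all(nonsig[g, cliques[[c]]])) {
        cliques[[c]] <- c(cliques[[c]], g)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- g
  }
  for (i in seq_len(k - 1)) {        # repair: cover stray non-sig pairs
    for (j in (i + 1):k) {
      if (nonsig[i, j] &&
          !any(vapply(cliques, function(cl) all(c(i, j) %in% cl), logical(1)))) {
        cliques[[length(cliques) + 1L]] <- c(i, j)
      }
    }
  }
  cliques <- cliques[order(vapply(cliques, function(cl) min(means[cl]), numeric(1)))]
  out <- setNames(rep("", k), labs)
  for (c in seq_along(cliques)) {
    out[cliques[[c]]] <- paste0(out[cliques[[c]]], letters[c])
  }
  out
}

#' Two-sample two-tailed t-test
#'
#' Classical equal-variance (pooled) t by default, with the Welch
#' approximation as an option.
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @param var_equal pool the variances (default TRUE).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_tailed_t_test <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- if (se == 0) {
    if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
  } else {
    (mean(a) - mean(b)) / se
  }
  p <- if (is.finite(tt)) 2 * pt(abs(tt), df, lower.tail = FALSE) else 0
  if (tt == 0) p <- 1
  list(t = tt, df = df, p = p, mean_a = mean(a), mean_b = mean(b))
}

#' Significance level for a named experimental context
#'
#' `default` experiments use alpha = 0.05; the allele-swap experiment, where
#' several measurements are taken from the same data set, uses a Bonferroni
#' corrected alpha = 0.008; the hydrocarbon experiment uses alpha = 0.01.
#'
#' @param context `"default"`, `"swap_experiment"` or `"hydrocarbon"`.
#' @return the alpha value.
#' @export
context_alpha <- function(context = "default") {
  alphas <- c(default = 0.05, swap_experiment = 0.008, hydrocarbon = 0.01)
  if (!is.character(context) || length(context) != 1L ||
      !context %in% names(alphas)) {
    stop(sprintf("unknown alpha context '%s'; use one of: %s",
                 paste(context, collapse = ","),
                 paste(names(alphas), collapse = ", ")), call. = FALSE)
  }
  unname(alphas[context])
}

#' Re-evaluate significance decisions under a context's alpha
#'
#' @param comparison a `group_comparison` (ideally from [tukey_kramer()]).
#' @param context experimental context, see [context_alpha()].
#' @return the comparison with `alpha`, pairwise `significant` flags,
#'   `letters` and `anova_significant` recomputed at the context's alpha.
#' @export
apply_alpha <- function(comparison, context = "default") {
  stopifnot(inherits(comparison, "group_comparison"))
  alpha <- context_alpha(context)
  comparison$alpha <- alpha
  comparison$anova_significant <- comparison$p_value < alpha
  if (!is.null(comparison$pairwise)) {
    comparison$pairwise$significant <- comparison$pairwise$p < alpha
    comparison$letters <- letter_display(names(comparison$groups),
                                         comparison$means,
                                         comparison$pairwise, alpha)
  }
  comparison
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d,%d) = %.4g, p = %.3g (alpha = %g)\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$alpha))
  if (!is.null(x$letters)) {
    for (g in names(x$letters)) {
      cat(sprintf("  %-16s mean %8.4g  n %3d  %s\n", g, x$means[g],
                  x$ns[g], x$letters[g]))
    }
  }
  invisible(x)
}
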