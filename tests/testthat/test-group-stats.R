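test_that("IQR outlier rule matches hand-computed type-7 quartiles", {
  expect_equal(remove_outliers(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  # type 7 quartiles of c(1,2,3,4,100): Q1 = 2, Q3 = 4, IQR = 2, so the
  # fences are -1 and 7: only 100 is removed (1 > -1 survives)
  expect_equal(remove_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(remove_outliers(c(100, 1, 2, 3, 4)), c(1, 2, 3, 4))
  # IQR = 0 guard: a constant vector maps to itself
  expect_equal(remove_outliers(rep(7, 6)), rep(7, 6))
  expect_error(remove_outliers(c(1, 2, 3)), "too few samples")
})

test_that("one-way ANOVA matches hand computation and stats::aov", {
  cmp <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(cmp$f_stat, 13.5)
  expect_equal(cmp$df_between, 1L)
  expect_equal(cmp$df_within, 4L)
  expect_equal(cmp$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  same <- one_way_anova(list(a = c(2, 4, 6), b = c(2, 4, 6)))
  expect_equal(same$f_stat, 0)

  set.seed(10)
  groups <- list(g1 = rnorm(8, 0), g2 = rnorm(6, 0.5), g3 = rnorm(9, 1.5))
  cmp <- one_way_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- summary(stats::aov(y ~ g, data = df))[[1]]
  expect_equal(cmp$f_stat, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(cmp$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), ">= 2 values")
  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("F is invariant under shifts and location-scale changes", {
  set.seed(3)
  groups <- list(a = rnorm(7), b = rnorm(7, 1), c = rnorm(5, 2))
  f0 <- one_way_anova(groups)$f_stat
  expect_equal(one_way_anova(lapply(groups, function(g) g + 100))$f_stat, f0)
  expect_equal(one_way_anova(lapply(groups, function(g) 3.7 * g))$f_stat, f0)
})

test_that("Tukey-Kramer agrees with the q = |t| * sqrt(2) identity for two groups", {
  set.seed(4)
  a <- rnorm(9, 0); b <- rnorm(9, 0.8)
  tk <- tukey_kramer(list(a = a, b = b))
  tt <- two_tailed_t_test(a, b)
  expect_equal(tk$pairwise$q, abs(tt$t) * sqrt(2), tolerance = 1e-10)
  expect_equal(tk$pairwise$p,
               ptukey(abs(tt$t) * sqrt(2), 2, 16, lower.tail = FALSE),
               tolerance = 1e-10)
  # and the studentized-range p equals the two-sided t p for k = 2
  expect_equal(tk$pairwise$p, tt$p, tolerance = 1e-8)
})

test_that("Tukey-Kramer pairwise p-values match stats::TukeyHSD on unbalanced groups", {
  set.seed(5)
  groups <- list(g1 = rnorm(7, 0), g2 = rnorm(10, 0.6), g3 = rnorm(5, 2.2))
  tk <- tukey_kramer(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups))))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  key <- paste(tk$pairwise$group2, tk$pairwise$group1, sep = "-")
  expect_equal(tk$pairwise$p, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(tk$pairwise$difference, unname(ref[key, "diff"]),
               tolerance = 1e-10)
})

test_that("compact letter display is consistent with pairwise decisions", {
  same <- tukey_kramer(list(a = c(1, 2, 3), b = c(1.1, 2, 2.9),
                            c = c(0.9, 2.1, 3)))
  expect_true(all(same$letters == same$letters[1]))
  expect_equal(nchar(same$letters[[1]]), 1L)

  set.seed(6)
  apart <- tukey_kramer(list(lo = rnorm(8, 0, 0.1), mid = rnorm(8, 5, 0.1),
                             hi = rnorm(8, 10, 0.1)))
  expect_length(unique(apart$letters), 3)

  # property: share a letter iff not significantly different
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(4:9, 1), mean = i * runif(1, 0, 2)))
    names(groups) <- paste0("g", seq_len(k))
    tk <- tukey_kramer(groups)
    share <- function(x, y) {
      any(strsplit(tk$letters[[x]], "")[[1]] %in% strsplit(tk$letters[[y]], "")[[1]])
    }
    for (r in seq_len(nrow(tk$pairwise))) {
      expect_equal(share(tk$pairwise$group1[r], tk$pairwise$group2[r]),
                   !tk$pairwise$significant[r],
                   label = sprintf("seed %d pair %s-%s", seed,
                                   tk$pairwise$group1[r], tk$pairwise$group2[r]))
    }
  }
})

test_that("two-sample t-test matches its closed forms and stats::t.test", {
  expect_equal(two_tailed_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(two_tailed_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  jit <- two_tailed_t_test(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                           c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_gt(abs(jit$t), 100)
  expect_lt(jit$p, 0.001)

  set.seed(7)
  a <- rnorm(9); b <- rnorm(12, 0.7, 2)
  for (ve in c(TRUE, FALSE)) {
    got <- two_tailed_t_test(a, b, var_equal = ve)
    ref <- stats::t.test(a, b, var.equal = ve)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(two_tailed_t_test(1, c(1, 2)), ">= 2 values")
})

test_that("alpha contexts select the documented thresholds and re-score decisions", {
  expect_equal(context_alpha("default"), 0.05)
  expect_equal(context_alpha("swap_experiment"), 0.008)
  expect_equal(context_alpha("hydrocarbon"), 0.01)
  expect_error(context_alpha("other"), "unknown alpha context")

  # a comparison with p between 0.008 and 0.05 flips between contexts
  set.seed(123)
  repeat {
    groups <- list(a = rnorm(8, 0), b = rnorm(8, 1))
    tk <- tukey_kramer(groups)
    if (tk$pairwise$p > 0.008 && tk$pairwise$p < 0.05) break
  }
  def <- apply_alpha(tk, "default")
  swp <- apply_alpha(tk, "swap_experiment")
  expect_true(def$pairwise$significant)
  expect_false(swp$pairwise$significant)
  expect_equal(swp$alpha, 0.008)
  expect_length(unique(def$letters), 2)
  expect_length(unique(swp$letters), 1)
})
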