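#' Group summary grid (mean, SD, range, N)
#'
#' Summarizes every numeric property of a population table per group, the
#' layout used for the electrophysiological and morphological summary
#' tables: mean, SD, min, max and the number of non-missing observations.
#'
#' @param table a tibble (one row per cell).
#' @param group_by character vector of grouping columns (e.g.
#'   `c("genotype", "pattern")`).
#' @param properties columns to summarize; defaults to all numeric columns.
#' @return a tibble with one row per group x property.
#' @export
#' @examples
#' cells <- sample_population(group_spec("WT", "immediate"), 20, seed = 1)
#' summarize_population(cells, c("genotype", "pattern"),
#'                      properties = c("rheobase_true", "g_in"))
summarize_population <- function(table, group_by = c("genotype", "pattern"),
                                 properties = NULL) {
  stopifnot(all(group_by %in% names(table)))
  if (is.null(properties)) {
    properties <- names(table)[vapply(table, is.numeric, logical(1))]
    properties <- setdiff(properties, c("seed"))
  }
  grouped <- dplyr::group_by(table, dplyr::across(dplyr::all_of(group_by)))
  if (any(dplyr::group_size(grouped) == 0) || nrow(table) == 0) {
    abort("empty group in population table")
  }
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c(group_by, properties))),
    cols = dplyr::all_of(properties),
    names_to = "property", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(group_by, "property")))),
    mean = mean(.data$value, na.rm = TRUE),
    sd = dplyr::coalesce(sd(.data$value, na.rm = TRUE), 0),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    n = sum(is.finite(.data$value)),
    .groups = "drop")
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact two-tailed p-value by complete enumeration for small samples
#' (combined n below 20 and no ties), normal approximation with continuity
#' and tie correction otherwise.
#'
#' @param a,b numeric samples.
#' @return p-value.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("empty sample")
  exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Two-tailed Fisher exact test on a 2x2 contingency table
#'
#' Probability-mass method: the p-value sums the hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one.
#'
#' @param k11,k12,k21,k22 cell counts (first row, then second row).
#' @return p-value.
#' @export
#' @examples
#' fisher_exact(13, 2, 3, 8)
fisher_exact <- function(k11, k12, k21, k22) {
  k <- c(k11, k12, k21, k22)
  if (any(k < 0) || any(k != round(k))) abort("counts must be non-negative integers")
  m <- matrix(k, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has an all-zero margin")
  }
  fisher.test(m, alternative = "two.sided")$p.value
}

#' Two-sample two-sided Kolmogorov-Smirnov test
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("empty sample")
  res <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Zero-intercept regression of rheobase on input conductance
#'
#' Fits `I = U * G` with the intercept constrained to zero, so that the slope
#' `U` has the dimension of a voltage: with `G` in nS and `I` in nA,
#' `U = 1000 * sum(G*I) / sum(G^2)` is expressed in mV. On cells sharing a
#' common threshold depolarization delta-V, `U` equals it exactly; in general
#' it is the G^2-weighted mean of the per-cell delta-V.
#'
#' @param g input conductances (nS).
#' @param i rheobases (nA).
#' @return an `mn_zfit` object: `slope_mv`, `slope` (nA/nS), `residuals`,
#'   `n`, `ssr`, and the raw data.
#' @export
zero_intercept_fit <- function(g, i) {
  if (length(g) != length(i)) abort("g and i must have equal length")
  ok <- is.finite(g) & is.finite(i)
  g <- g[ok]; i <- i[ok]
  if (length(g) < 1) abort("no complete observations")
  if (sum(g^2) == 0) abort("degenerate predictor: all conductances zero")
  slope <- sum(g * i) / sum(g^2)     # nA per nS = V
  res <- i - slope * g
  structure(list(slope_mv = 1000 * slope, slope = slope, residuals = res,
                 n = length(g), ssr = sum(res^2), g = g, i = i),
            class = "mn_zfit")
}

#' @export
print.mn_zfit <- function(x, ...) {
  cat("<mn_zfit> I = G * U, U = ", signif(x$slope_mv, 4), " mV (n = ",
      x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.mn_zfit <- function(x, ...) {
  tibble::tibble(term = "U", estimate = x$slope_mv,
                 std.error = 1000 * zfit_se(x))
}

#' @export
glance.mn_zfit <- function(x, ...) {
  tibble::tibble(slope_mv = x$slope_mv, n = x$n, ssr = x$ssr,
                 sigma = sqrt(x$ssr / max(x$n - 1, 1)))
}

# Standard error of the zero-intercept slope (nA/nS scale):
# SE(U) = sqrt(SSR/(n-1) / sum(G^2)).
zfit_se <- function(fit) {
  sqrt(fit$ssr / max(fit$n - 1, 1) / sum(fit$g^2))
}

#' Compare zero-intercept regression slopes between two groups
#'
#' Three-part comparison of the rheobase-conductance laws of two cell
#' groups: (i) Shapiro-Wilk normality of each group's residuals,
#' (ii) a t test on the slope difference using the standard errors of the two
#' zero-intercept slopes, and (iii) a Chow test with
#' `F = [(SSR_pooled - SSR_A - SSR_B)/k] / [(SSR_A + SSR_B)/(n_A + n_B - 2k)]`
#' and `k = 1` (slope-only model).
#'
#' @param g_a,i_a conductances (nS) and rheobases (nA) of group A.
#' @param g_b,i_b likewise for group B.
#' @return an `mn_slope_comparison` list: the two fits, `t_stat`, `t_p`,
#'   `chow_f`, `chow_p`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
compare_slopes <- function(g_a, i_a, g_b, i_b) {
  if (length(g_a) < 3 || length(g_b) < 3) {
    abort("need at least 3 points per group")
  }
  fa <- zero_intercept_fit(g_a, i_a)
  fb <- zero_intercept_fit(g_b, i_b)
  fp <- zero_intercept_fit(c(fa$g, fb$g), c(fa$i, fb$i))
  se <- sqrt(zfit_se(fa)^2 + zfit_se(fb)^2)
  tval <- (fa$slope - fb$slope) / se
  df_t <- fa$n + fb$n - 2
  t_p <- 2 * pt(-abs(tval), df_t)
  k <- 1
  num <- (fp$ssr - fa$ssr - fb$ssr) / k
  den <- (fa$ssr + fb$ssr) / (fa$n + fb$n - 2 * k)
  chow_f <- max(num / den, 0)
  chow_p <- pf(chow_f, k, fa$n + fb$n - 2 * k, lower.tail = FALSE)
  sw <- function(r) {
    if (length(unique(r)) < 3) return(NA_real_)
    shapiro.test(r)$p.value
  }
  structure(list(fit_a = fa, fit_b = fb, t_stat = tval, t_df = df_t,
                 t_p = t_p, chow_f = chow_f, chow_p = chow_p,
                 shapiro_p_a = sw(fa$residuals),
                 shapiro_p_b = sw(fb$residuals)),
            class = "mn_slope_comparison")
}

#' @export
print.mn_slope_comparison <- function(x, ...) {
  cat("<mn_slope_comparison> U_A = ", signif(x$fit_a$slope_mv, 3),
      " mV vs U_B = ", signif(x$fit_b$slope_mv, 3), " mV\n",
      "  t = ", signif(x$t_stat, 3), " (df ", x$t_df, "), p = ",
      signif(x$t_p, 3), "\n",
      "  Chow F = ", signif(x$chow_f, 3), ", p = ", signif(x$chow_p, 3), "\n",
      "  Shapiro-Wilk residuals: p_A = ", signif(x$shapiro_p_a, 3),
      ", p_B = ", signif(x$shapiro_p_b, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mn_slope_comparison <- function(x, ...) {
  tibble::tibble(
    test = c("slope_t", "chow", "shapiro_a", "shapiro_b"),
    statistic = c(x$t_stat, x$chow_f, NA, NA),
    p.value = c(x$t_p, x$chow_p, x$shapiro_p_a, x$shapiro_p_b)
  )
}

#' Pairwise group comparison report for a population table
#'
#' For every numeric property, compares the two levels of `compare` within
#' each level of `within` by a two-tailed Mann-Whitney test — the layout of
#' the published summary tables (WT vs mSOD1 within each firing pattern).
#'
#' @param table population tibble.
#' @param compare column with exactly two levels to compare.
#' @param within optional stratification column.
#' @param properties columns to test; defaults to all numeric.
#' @return tibble with `within`, `property`, group means and `p.value`.
#' @export
compare_groups <- function(table, compare = "genotype", within = "pattern",
                           properties = NULL) {
  if (is.null(properties)) {
    properties <- names(table)[vapply(table, is.numeric, logical(1))]
    properties <- setdiff(properties, "seed")
  }
  strata <- if (is.null(within)) list(table) else
    split(table, table[[within]])
  purrr::imap_dfr(strata, function(df, stratum) {
    lv <- unique(df[[compare]])
    if (length(lv) != 2) {
      abort(sprintf("'%s' must have exactly 2 levels within '%s'",
                    compare, stratum))
    }
    purrr::map_dfr(properties, function(p) {
      a <- df[[p]][df[[compare]] == lv[1]]
      b <- df[[p]][df[[compare]] == lv[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) == 0 || length(b) == 0) {
        return(tibble::tibble(within = stratum, property = p,
                              mean_a = NA_real_, mean_b = NA_real_,
                              p.value = NA_real_))
      }
      tibble::tibble(within = stratum, property = p,
                     mean_a = mean(a), mean_b = mean(b),
                     p.value = mann_whitney(a, b))
    })
  })
}
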