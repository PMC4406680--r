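#' Spearman rank correlation
#'
#' Association between field-measured and airborne-derived values on the
#' rank scale: ties get average ranks and rho is the Pearson correlation
#' of the ranks.  The two-sided p-value uses the t approximation
#' `t = rho sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of freedom; an
#' exact permutation p-value is available for very small samples.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   enumeration, `n <= 8`).
#' @return list of class `canopy_stat` with `statistic = "spearman_rho"`,
#'   `value`, `p_value`, `n`, `ties` flag.
#' @export
spearman_rho <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs (got %d)", n)
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (p_method == "exact") {
    if (n > 8L)
      abort("exact permutation p-value limited to n <= 8 (got %d)", n)
    perms <- permutations_of(n)
    obs <- abs(rho)
    stat <- apply(perms, 1, function(p) abs(cor(rx, ry[p])))
    p <- mean(stat >= obs - 1e-12)
  } else {
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), df = n - 2)
    }
  }
  structure(list(statistic = "spearman_rho", value = rho, p_value = p,
                 n = n, ties = ties), class = "canopy_stat")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Root-mean-square error of paired values
#'
#' @param x,y paired numeric vectors.
#' @return `canopy_stat` with `statistic = "rmse"`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (!length(x)) abort("need at least one pair")
  structure(list(statistic = "rmse", value = sqrt(mean((x - y)^2)),
                 p_value = NA_real_, n = length(x), ties = NA),
            class = "canopy_stat")
}

#' Kruskal-Wallis rank test
#'
#' Tests whether several samples (e.g. field-measured versus
#' segmentation-derived crown widths) come from the same distribution.
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)` on midranks,
#' with the usual tie correction `1 - sum(t^3 - t) / (N^3 - N)`.  Both
#' the corrected and uncorrected statistics are reported; the p-value
#' (chi-square, `k - 1` df) uses the corrected one.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @return `canopy_stat` with `value` (tie-corrected H), `H_uncorrected`,
#'   `p_value`, `df`, `ties` flag.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    abort("need a list of at least 2 groups")
  if (any(!vapply(groups, length, 1L)))
    abort("every group needs at least one observation")
  v <- unlist(groups, use.names = FALSE)
  N <- length(v)
  if (N < 3L) abort("need at least 3 observations in total")
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  r <- rank(v)
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie_tab <- table(v)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  ties <- any(tie_tab > 1)
  if (corr <= 0) {
    warning("all observations identical; H is 0")
    Hc <- 0
  } else Hc <- H / corr
  df <- length(groups) - 1L
  structure(list(statistic = "kruskal_wallis_H", value = Hc,
                 H_uncorrected = H, p_value = pchisq(Hc, df,
                                                    lower.tail = FALSE),
                 df = df, n = N, ties = ties), class = "canopy_stat")
}

#' Mood's median test
#'
#' Tests whether groups share a common median — the directional check
#' for whether a delineation method under- or overestimates
#' field-measured crown widths.  Counts per group above versus not above
#' the grand median (observations equal to the grand median are dropped
#' under the default `"drop"` convention, or counted as below with
#' `"below"`), then applies Pearson's chi-square without continuity
#' correction on the `2 x k` table.
#'
#' @param groups named or unnamed list of numeric vectors (>= 2).
#' @param ties `"drop"` or `"below"`.
#' @return `canopy_stat` with `value` (chi-square), `p_value`, `df`,
#'   `grand_median`, per-group `medians` and the contingency `table`.
#' @export
mood_median <- function(groups, ties = c("drop", "below")) {
  ties <- match.arg(ties)
  if (!is.list(groups) || length(groups) < 2L)
    abort("need a list of at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  gm <- median(v)
  counts <- vapply(groups, function(x) {
    if (ties == "drop") x <- x[x != gm]
    c(above = sum(x > gm), not_above = sum(x <= gm))
  }, numeric(2))
  if (any(colSums(counts) == 0))
    abort("a group is empty after dropping ties at the grand median")
  if (all(counts["above", ] == 0) || all(counts["not_above", ] == 0)) {
    chi2 <- 0; p <- 1        # degenerate margin: no evidence either way
  } else {
    ct <- suppressWarnings(chisq.test(t(counts), correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(statistic = "mood_chi2", value = chi2, p_value = p,
                 df = length(groups) - 1L, grand_median = gm,
                 medians = vapply(groups, median, numeric(1)),
                 table = t(counts), ties = ties), class = "canopy_stat")
}

#' QQ points of residuals against the standard normal
#'
#' Ordered residuals paired with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`; returned as a table for plotting and
#' visual normality assessment, not auto-judged.
#'
#' @param residuals numeric vector, `n >= 3`.
#' @return data frame with `theoretical` and `sample` columns.
#' @export
qq_points <- function(residuals) {
  r <- residuals[is.finite(residuals)]
  n <- length(r)
  if (n < 3L) abort("need at least 3 residuals (got %d)", n)
  data.frame(theoretical = qnorm((seq_len(n) - 0.5) / n),
             sample = sort(r))
}

#' @export
print.canopy_stat <- function(x, ...) {
  cat(sprintf("<canopy_stat> %s = %.4f", x$statistic, x$value))
  if (is.finite(x$p_value)) cat(sprintf("  (p = %.4g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Study-style mensuration comparison report
#'
#' Reproduces the statistical battery comparing airborne-derived and
#' field-measured mensuration variables: Spearman's rho and RMSE per
#' paired variable; Kruskal-Wallis and Mood's median tests across the
#' crown-width samples of the different sources (field, region-merging
#' segmentation, watershed segmentation) with per-group medians; and an
#' optional per-species summary (mean +/- standard error of each
#' variable, rho between field and airborne values).
#'
#' @param paired named list of data frames, each with columns `field`
#'   and `airborne` (plus optionally `species`).
#' @param width_groups named list of crown-width vectors by source.
#' @return nested list of class `mensuration_report`.
#' @export
compare_report <- function(paired = list(), width_groups = NULL) {
  per_var <- lapply(paired, function(d) {
    ok <- complete.cases(d[c("field", "airborne")])
    d <- d[ok, , drop = FALSE]
    if (nrow(d) < 3L)
      abort("fewer than 3 matched pairs (%d); refusing to compare",
            nrow(d))
    out <- list(rho = spearman_rho(d$field, d$airborne),
                rmse = rmse(d$field, d$airborne), n = nrow(d))
    if ("species" %in% names(d)) {
      out$by_species <- do.call(rbind, lapply(
        split(d, d$species), function(s) {
          data.frame(
            species = s$species[1], n = nrow(s),
            field_mean = mean(s$field),
            field_se = sd(s$field) / sqrt(nrow(s)),
            airborne_mean = mean(s$airborne),
            airborne_se = sd(s$airborne) / sqrt(nrow(s)),
            rho = if (nrow(s) >= 3 && sd(s$field) > 0 &&
                      sd(s$airborne) > 0)
              spearman_rho(s$field, s$airborne)$value else NA_real_)
        }))
      rownames(out$by_species) <- NULL
    }
    out
  })
  out <- list(variables = per_var)
  if (!is.null(width_groups)) {
    out$width_kw <- kruskal_wallis(width_groups)
    out$width_mood <- mood_median(width_groups)
    pairswise <- utils::combn(names(width_groups), 2, simplify = FALSE)
    out$width_mood_pairwise <- lapply(pairswise, function(p)
      mood_median(width_groups[p]))
    names(out$width_mood_pairwise) <-
      vapply(pairswise, paste, "", collapse = "_vs_")
    out$width_medians <- vapply(width_groups, median, numeric(1))
  }
  structure(out, class = "mensuration_report")
}
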