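# Group-level statistics: exact small-sample Mann-Whitney U, percent change,
# correlation, and the two-group comparison report.

#' Exact Mann-Whitney U test by complete enumeration
#'
#' Computes U = min(U_a, U_b) from (mid-)ranks and the exact two-sided p
#' value by enumerating all choose(n1 + n2, n1) group labelings of the
#' observed values: the one-sided tail is the proportion of labelings whose
#' first-group U is at most the observed U, and the two-sided p doubles it
#' (capped at 1).  With ties the mid-rank U is enumerated over the observed
#' multiset, which keeps the test exact conditional on the data.
#'
#' @param a,b Numeric samples; combined size at most 20 (the exact
#'   enumeration regime).
#' @return List with \code{u} (the U statistic) and \code{p} (exact
#'   two-sided p value).
#' @export
#' @examples
#' mannwhitney_exact(1:5, 6:10)$p   # 2/252 = 0.0079...
mannwhitney_exact <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 + n2 > 20L)
    stop("exact enumeration supported for combined n <= 20")
  r <- rank(c(a, b))
  u_from_ranks <- function(ra_sum) ra_sum - n1 * (n1 + 1) / 2
  ua <- u_from_ranks(sum(r[seq_len(n1)]))
  ub <- n1 * n2 - ua
  u_obs <- min(ua, ub)
  combos <- utils::combn(n1 + n2, n1)
  ua_perm <- u_from_ranks(colSums(matrix(r[combos], nrow = n1)))
  p_one <- mean(ua_perm <= u_obs + 1e-9)
  list(u = u_obs, p = min(1, 2 * p_one))
}

#' Percent change between two group means
#'
#' Change due to the second condition, relative to the first:
#' 100 * (after - before) / before.
#'
#' @param before,after Group means; \code{before} must be nonzero.
#' @return Percent change (unrounded; round to integer for display).
#' @export
#' @examples
#' percent_change(100, 115)   # +15
#' percent_change(25, 21)     # -16
percent_change <- function(before, after) {
  if (!is.numeric(before) || before == 0)
    stop("zero baseline: percent change undefined")
  100 * (after - before) / before
}

#' Pearson correlation with t-based p value
#'
#' Product-moment correlation R with the two-sided p value from the
#' t-transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return List with \code{r} and \code{p}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired samples of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-group comparison report
#'
#' Builds one comparison row per metric -- group means and SDs, percent
#' change relative to the reference group, the exact Mann-Whitney U and its
#' two-sided p -- from a per-subject metrics table with exactly two groups.
#'
#' @param metrics data.frame: one row per subject, one column per metric,
#'   plus a group column.
#' @param group_col Name of the group column.
#' @param reference Reference group label (the percent-change denominator);
#'   defaults to the first group encountered.
#' @return data.frame of class \code{comparison_report}: metric, group
#'   means/SDs, percent_change, u_statistic, p_two_sided.
#' @export
build_report <- function(metrics, group_col = "group", reference = NULL) {
  stopifnot(is.data.frame(metrics))
  if (!nrow(metrics)) stop("empty metrics table")
  if (!group_col %in% names(metrics))
    stop(sprintf("no '%s' column", group_col))
  groups <- unique(as.character(metrics[[group_col]]))
  if (length(groups) != 2L)
    stop(sprintf("need exactly two groups, found %d", length(groups)))
  if (is.null(reference)) reference <- groups[1]
  other <- setdiff(groups, reference)
  cols <- setdiff(names(metrics), group_col)
  cols <- cols[vapply(metrics[cols], is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    a <- metrics[[cn]][metrics[[group_col]] == reference]
    b <- metrics[[cn]][metrics[[group_col]] == other]
    mw <- mannwhitney_exact(a, b)
    data.frame(metric = cn,
               mean_ref = mean(a), sd_ref = stats::sd(a),
               mean_other = mean(b), sd_other = stats::sd(b),
               percent_change = percent_change(mean(a), mean(b)),
               u_statistic = mw$u, p_two_sided = mw$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(reference = reference, comparison = other)
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Group comparison: %s (reference) vs %s\n", g[1], g[2]))
  df <- as.data.frame(x)
  df$percent_change <- sprintf("%+.0f%%", df$percent_change)
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}
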