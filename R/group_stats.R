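# qPCR delta-delta-Ct relative quantification and the group-comparison
# statistics used alongside it: equal-variance two-tailed Student t, exact
# and normal-approximation Wilcoxon rank-sum, Bonferroni correction.

#' Relative quantity (delta-delta-Ct) per sample
#'
#' `dCt = ct_target - ct_reference` per sample; `ddCt = dCt - mean(dCt)` over
#' the calibrator group; `RQ = 2^(-ddCt)` (perfect-doubling amplification
#' efficiency). The reference gene is typically U6 snRNA or GAPDH.
#'
#' @param measurements Data frame with columns `sample_id`, `group`,
#'   `ct_target`, `ct_reference` (finite Ct cycle values).
#' @param calibrator_group Group label whose mean dCt anchors RQ = 1.
#' @return The input with added columns `dct`, `ddct`, `rq`.
#' @export
relative_quantity <- function(measurements, calibrator_group) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% colnames(measurements)))
    stop_mc("relative_quantity: need columns %s", paste(need, collapse = ", "))
  ct <- c(measurements$ct_target, measurements$ct_reference)
  if (any(!is.finite(ct))) stop_mc("relative_quantity: Ct values must be finite")
  cal <- measurements$group == calibrator_group
  if (!any(cal)) stop_mc("relative_quantity: calibrator group '%s' is empty",
                         calibrator_group)
  out <- measurements
  out$dct <- out$ct_target - out$ct_reference
  out$ddct <- out$dct - mean(out$dct[cal])
  out$rq <- 2^(-out$ddct)
  out
}

new_group_comparison <- function(method, statistic, p, df = NA_real_,
                                 adjusted_p = NA_real_) {
  structure(list(method = method, statistic = statistic, df = df, p = p,
                 adjusted_p = adjusted_p), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p))
  if (!is.na(x$adjusted_p)) cat(sprintf("  adjusted p = %.4g\n", x$adjusted_p))
  invisible(x)
}

#' Two-tailed two-sample Student t-test
#'
#' Equal-variance (pooled) Student t by default, the common convention
#' behind "two-tailed t-test" for small qPCR replicate groups; Welch
#' available via `var_equal = FALSE`. If both samples have zero variance:
#' equal means give `t = 0, p = 1` by convention, unequal means are a
#' degenerate-variance error.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return A `group_comparison` with the t statistic, degrees of freedom and
#'   two-tailed p.
#' @export
t_test_two_tailed <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop_mc("t_test_two_tailed: each sample needs >= 2 observations")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(new_group_comparison("student_t_two_tailed", 0, 1, nx + ny - 2))
    stop_mc("t_test_two_tailed: both samples have zero variance with unequal means")
  }
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    method <- "student_t_two_tailed"
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    method <- "welch_t_two_tailed"
  }
  t_stat <- (mean(x) - mean(y)) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  new_group_comparison(method, t_stat, min(1, p), df)
}

#' Wilcoxon rank-sum test (exact or normal approximation)
#'
#' For tie-free samples with both sizes `<= exact_limit` the exact two-sided
#' p is computed by enumerating all `choose(nx+ny, nx)` rank labelings of
#' the Mann-Whitney U statistic, with two-sided p = `2 * min(P(U <= u),
#' P(U >= u))` capped at 1. Otherwise the normal approximation with tie
#' correction and continuity correction is used. The branch taken is
#' recorded in `method`.
#'
#' @param x,y Numeric samples, each of size >= 1.
#' @param exact_limit Maximum per-group size for the exact branch
#'   (default 10).
#' @return A `group_comparison` with the U statistic and two-sided p.
#' @export
rank_sum_test <- function(x, y, exact_limit = 10) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop_mc("rank_sum_test: each sample needs >= 1 observation")
  combined <- c(x, y)
  r <- rank(combined)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(combined) > 0L
  if (!ties && nx <= exact_limit && ny <= exact_limit) {
    labelings <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(labelings, nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    return(new_group_comparison("rank_sum_exact", u, p))
  }
  mu <- nx * ny / 2
  n_tot <- nx + ny
  tie_tab <- table(combined)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n_tot * (n_tot - 1))
  sigma2 <- nx * ny / 12 * ((n_tot + 1) - tie_term)
  if (sigma2 <= 0)  # all values identical
    return(new_group_comparison("rank_sum_normal", u, 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_group_comparison("rank_sum_normal", u, p)
}

#' Bonferroni correction
#'
#' `adjusted_i = min(1, p_i * m)` with `m` the number of comparisons.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length/order.
#' @export
bonferroni <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_mc("bonferroni: p-values must lie in (0, 1]")
  pmin(1, p_values * length(p_values))
}
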