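# The study's statistical layer: mean +/- SD summaries, two-group t-tests,
# one-way ANOVA, and significance flagging.

#' Mean, sample SD and n
#'
#' @param values Non-empty numeric vector. SD uses the n-1 denominator and
#'   is `NA` for a single observation.
#' @return List with `mean`, `sd`, `n`.
#' @export
mean_sd <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Two-group t-test
#'
#' Welch by default (Welch-Satterthwaite degrees of freedom); the pooled
#' (equal-variance) variant is available. Two-sided p value.
#'
#' @param a,b Numeric vectors, each n >= 2, with nonzero variance in at
#'   least one group.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p`.
#' @export
t_test <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      stop("degenerate: both variances zero and means equal", call. = FALSE)
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way fixed-effects ANOVA
#'
#' Classic omnibus F = MS_between / MS_within. No post-hoc test is attached.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0)
    stop("all values identical", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1L]),
       df2 = unname(ht$parameter[2L]), p = unname(ht$p.value))
}

#' Significance stars
#'
#' `*`, `**`, `***` at strict p < 0.05 / 0.01 / 0.001; otherwise `"ns"`.
#'
#' @param p A p value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
star_flags <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("p must be in [0, 1]", call. = FALSE)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Group comparison summary
#'
#' Mean +/- SD per group plus the omnibus test: Welch t-test for two groups,
#' one-way ANOVA for more. P values are uncorrected, as labelled in the
#' output; an optional Holm correction over a family of comparisons is
#' available via [stats::p.adjust()] downstream.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @param test `"auto"` (t-test for 2 groups, ANOVA otherwise), `"ttest"`,
#'   or `"anova"`.
#' @return List of class `group_comparison` with elements `summary` (data
#'   frame: group, n, mean, sd), `test`, `statistic`, `df`, `p`, `stars`,
#'   `p_correction = "none"`.
#' @export
group_comparison <- function(values, groups, test = c("auto", "ttest", "anova")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(groups))
  g <- factor(groups, levels = unique(groups))
  parts <- split(values, g)
  if (test == "auto") test <- if (length(parts) == 2L) "ttest" else "anova"
  summ <- data.frame(
    group = names(parts),
    n = lengths(parts),
    mean = vapply(parts, mean, 0),
    sd = vapply(parts, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_, 0),
    row.names = NULL)
  if (test == "ttest") {
    if (length(parts) != 2L) stop("t-test needs exactly 2 groups", call. = FALSE)
    res <- t_test(parts[[1L]], parts[[2L]])
    out <- list(test = "welch_t", statistic = res$t, df = res$df, p = res$p)
  } else {
    res <- one_way_anova(parts)
    out <- list(test = "one_way_anova", statistic = res$F,
                df = c(res$df1, res$df2), p = res$p)
  }
  structure(c(list(summary = summ), out,
              list(stars = star_flags(out$p), p_correction = "none")),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic=%.4g, p=%.4g %s (uncorrected)\n",
              x$test, x$statistic, x$p, x$stars))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
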