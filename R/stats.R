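#' @name stats_battery
#' @title Nonparametric statistics for paired-delineation studies
#' @description
#' The inferential toolkit used in lesion-agreement analyses: a paired
#' two-sided Wilcoxon signed-rank test (exact null for small samples),
#' a Hodges-Lehmann-style confidence interval for a median difference
#' (signed-rank inversion over Walsh averages), a Mann-Whitney U test with
#' an eta-squared effect size, per-class least-squares fits of SDI on
#' log10 volume with pointwise confidence bands, and a two-group MANOVA
#' on (log10 volume, SDI).
#'
#' Conventions (stated, since they matter for small samples): zero paired
#' differences are dropped before ranking; ties receive mid-ranks with the
#' usual variance correction in the normal approximation; exact null
#' distributions are used for n <= 25 without ties, the tie-corrected
#' normal approximation with continuity correction otherwise.
NULL

cnt_test_result <- function(method, statistic, p.value, n,
                            effect_size = NULL, conf.int = NULL,
                            estimate = NULL, exact = NA, extra = NULL) {
  stopifnot(p.value >= 0, p.value <= 1)
  out <- c(list(method = method, statistic = statistic, p.value = p.value,
                n = n, effect_size = effect_size, conf.int = conf.int,
                estimate = estimate, exact = exact,
                data.name = "", alternative = "two.sided"), extra)
  class(out) <- c("cnt_test", "htest")
  out
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Tests whether the paired differences have zero median. Zero differences
#' are dropped; the exact signed-rank null is used for n <= 25 when the
#' nonzero |differences| are untied, otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param a,b equal-length paired samples, or `b = NULL` with `a` the
#'   differences.
#' @param alternative only `"two.sided"` is offered (the study design).
#' @return a `cnt_test` (inherits `htest`): statistic `V` (sum of positive
#'   ranks), `p.value`, `n` (after zero removal), `exact` flag.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, alternative = "two.sided") {
  stopifnot(alternative == "two.sided")
  d <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop(structure(class = c("cnt_degenerate_test", "error", "condition"),
                   list(message = "all paired differences are zero",
                        call = sys.call(-1))))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        1 - stats::psignrank(V - 1, n)))
    exact <- TRUE; z <- NULL
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  cnt_test_result(
    method = paste0("Paired Wilcoxon signed-rank test (",
                    if (exact) "exact" else "normal approximation", ")"),
    statistic = c(V = V), p.value = p, n = n, exact = exact)
}

#' Hodges-Lehmann-style confidence interval for a median difference
#'
#' Point estimate: the median of the Walsh averages (pairwise means) of
#' the differences. Interval: signed-rank inversion — order statistics of
#' the Walsh averages at ranks chosen from the exact signed-rank
#' distribution at the requested level (Bauer-style). The achieved
#' confidence level of the discrete procedure is reported.
#'
#' @param differences numeric vector (n >= 6 for a nondegenerate 95\%
#'   interval).
#' @param level confidence level.
#' @return list `estimate`, `conf.int` (length 2, with attribute
#'   `achieved.level`), `n`.
#' @export
hl_median_ci <- function(differences, level = 0.95) {
  d <- differences[!is.na(differences)]
  n <- length(d)
  alpha <- 1 - level
  # smallest n with 2 * 2^-n <= alpha gives a nondegenerate interval
  nmin <- ceiling(log2(2 / alpha))
  if (n < nmin)
    stop("need n >= ", nmin, " differences for a ", level * 100,
         "% interval (got ", n, ")", call. = FALSE)
  w <- outer(d, d, "+")[lower.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  M <- n * (n + 1) / 2
  qu <- stats::qsignrank(alpha / 2, n)
  if (qu == 0) qu <- 1
  achieved <- 1 - 2 * stats::psignrank(qu - 1, n)
  ci <- c(w[qu], w[M - qu + 1])
  attr(ci, "achieved.level") <- achieved
  list(estimate = stats::median(w), conf.int = ci, n = n)
}

#' Mann-Whitney U test with eta-squared effect size
#'
#' Two-sided rank-sum comparison of two independent samples. The reported
#' statistic `W` counts pairwise wins of the first sample (ties count
#' half), matching the usual rank-sum convention. The p-value is exact for
#' small untied samples, otherwise a tie-corrected normal approximation
#' with continuity correction. The effect size is
#' `eta^2 = Z^2 / (n1 + n2)` with Z the (tie-corrected, uncorrected for
#' continuity) standardized statistic; the rank-biserial correlation
#' `1 - 2U/(n1 n2)` is also reported.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative only `"two.sided"`.
#' @return a `cnt_test`: statistic `W` (= U), `p.value`, `effect_size`
#'   (eta-squared), `rank_biserial`, `n` per group.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  stopifnot(alternative == "two.sided")
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty",
                                 call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- anyDuplicated(c(x, y)) > 0L
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z_eff <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  if (!ties && n1 <= 25 && n2 <= 25) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    exact <- TRUE
  } else {
    cc <- sign(U - mu) * 0.5
    z <- if (sig2 > 0) (U - mu - cc) / sqrt(sig2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  cnt_test_result(
    method = paste0("Mann-Whitney U test (",
                    if (exact) "exact" else
                      "normal approximation, tie-corrected", ")"),
    statistic = c(W = U), p.value = p, n = c(n1 = n1, n2 = n2),
    effect_size = c(eta_squared = z_eff^2 / N),
    exact = exact,
    extra = list(rank_biserial = 1 - 2 * U / (n1 * n2)))
}

#' Least-squares fit with pointwise confidence band
#'
#' Ordinary least squares of `y` on `x` (in class plots, SDI on log10
#' volume) with the pointwise confidence band for the mean response.
#'
#' @param x,y numeric vectors, >= 3 points, `x` nonconstant.
#' @param level band level.
#' @param newx abscissae for the band (default: sorted `x`).
#' @return list `slope`, `intercept`, `level`, `band` (data.frame `x`,
#'   `fit`, `lwr`, `upr`), `model` (the `lm` fit).
#' @export
linear_fit_ci <- function(x, y, level = 0.95, newx = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("x is constant: fit is rank-deficient", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  if (is.null(newx)) newx <- sort(x)
  pr <- stats::predict(fit, newdata = data.frame(x = newx),
                       interval = "confidence", level = level)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       level = level,
       band = data.frame(x = newx, fit = pr[, "fit"],
                         lwr = pr[, "lwr"], upr = pr[, "upr"]),
       model = fit)
}

#' Two-group MANOVA on bivariate lesion responses
#'
#' One-way two-group multivariate analysis of variance, typically on
#' per-lesion (log10 volume, SDI) between two conditions. Pillai's trace
#' is reported (in the two-group case a monotone transform of Hotelling's
#' T-squared) with its F approximation.
#'
#' @param responses numeric matrix/data.frame, n x 2.
#' @param group length-n factor/vector with exactly 2 levels, >= 2
#'   observations per group.
#' @return a `cnt_test`: statistic `Pillai`, `approx_F`, `df`, `p.value`.
#' @export
manova_two_group <- function(responses, group) {
  Y <- as.matrix(responses)
  if (ncol(Y) != 2) stop("expected 2 response dimensions", call. = FALSE)
  group <- factor(group)
  if (nlevels(group) != 2) stop("expected exactly 2 groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("need >= 2 observations per group", call. = FALSE)
  fit <- stats::manova(Y ~ group)
  sm <- tryCatch(summary(fit, test = "Pillai"), error = function(e)
    stop("singular pooled covariance: ", conditionMessage(e), call. = FALSE))
  st <- sm$stats
  cnt_test_result(
    method = "Two-group one-way MANOVA (Pillai's trace)",
    statistic = c(Pillai = st["group", "Pillai"]),
    p.value = st["group", "Pr(>F)"],
    n = as.vector(table(group)),
    extra = list(approx_F = st["group", "approx F"],
                 df = st["group", c("num Df", "den Df")]))
}

#' @export
print.cnt_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n")
  cat(paste(names(x$statistic), "=", format(x$statistic)),
      " p-value =", format.pval(x$p.value), "\n")
  if (!is.null(x$effect_size))
    cat(paste(names(x$effect_size), "=",
              format(x$effect_size, digits = 4)), "\n")
  if (!is.null(x$conf.int))
    cat("confidence interval: [", x$conf.int[1], ",", x$conf.int[2], "]\n")
  cat("n =", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}
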