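#' Mann-Whitney U test for two count samples
#'
#' Rank-sum test chosen because cell-count distributions are not normal.
#' `U` is the smaller of the two one-sided statistics, with midranks for
#' ties. The two-sided p-value is exact (distribution enumeration) when
#' the combined sample size is at most `exactMax` and there are no ties;
#' otherwise the normal approximation with tie-corrected variance is used
#' (no continuity correction, so identical samples give p = 1). If all
#' pooled values are identical the test is degenerate and p = 1.
#'
#' @param a,b numeric samples (both nonempty).
#' @param exactMax combined-size limit for the exact branch.
#' @return list with `U`, `p`, and `method` ("exact" or "normal").
#' @export
mannWhitneyU <- function(a, b, exactMax = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n <= exactMax) {
    p <- min(1, 2 * stats::pwilcox(U, na, nb))
    return(list(U = U, p = p, method = "exact"))
  }
  tieTab <- table(pooled)
  tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tieCorr)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - na * nb / 2) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#'
#' @param xs numeric vector, length >= 2.
#' @return standard error.
#' @export
standardError <- function(xs) {
  if (length(xs) < 2L) stop("need at least 2 values")
  stats::sd(xs) / sqrt(length(xs))
}

#' Ordinary least-squares line with R-squared
#'
#' `R^2 = 1 - SS_res / SS_tot`; used to quantify the correlation between
#' manual and algorithmic counts pooled over conditions.
#'
#' @param x,y numeric vectors, length >= 3; `x` must not be constant.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linearRegressionR2 <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) stop("need n >= 3 pairs")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ssTot == 0) 0 else 1 - ssRes / ssTot)
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p <= 0.05) "*"
  else "ns"
}

#' Compare manual and algorithmic counts per experimental group
#'
#' Per group: mean, standard error and n for each source, a Mann-Whitney U
#' test between the two count sets, and a significance label (star
#' convention: `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****`
#' p <= 0.0001, else `ns`). Groups where one side is all-zero are reported
#' but flagged untested (the rank test is degenerate against an all-zero
#' sample). The pooled manual-vs-algorithmic relation is summarized by an
#' OLS regression with R-squared. No multiple-testing correction is
#' applied.
#'
#' @param manual,algo named lists mapping group label to an integer count
#'   vector; group labels must match.
#' @return list with `groups` (data.frame) and `regression`
#'   (list, see [linearRegressionR2()]); `regression` is NULL when the
#'   pooled samples are unsuitable (fewer than 3 pairs or constant x).
#' @export
compareGroups <- function(manual, algo) {
  if (!setequal(names(manual), names(algo)))
    stop("manual and algo group labels differ")
  labs <- names(manual)
  rows <- lapply(labs, function(g) {
    m <- manual[[g]]; a <- algo[[g]]
    if (length(m) == 0L || length(a) == 0L)
      stop(sprintf("group '%s' is empty", g))
    untested <- all(m == 0) || all(a == 0)
    if (untested) {
      U <- NA_real_; p <- NA_real_
    } else {
      mw <- mannWhitneyU(m, a)
      U <- mw$U; p <- mw$p
    }
    data.frame(group = g, n_manual = length(m), n_algo = length(a),
               mean_manual = mean(m), se_manual = standardError(m),
               mean_algo = mean(a), se_algo = standardError(a),
               U = U, p = p, significance = .stars(p),
               untested = untested, stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)
  pooledM <- unlist(manual, use.names = FALSE)
  pooledA <- unlist(algo, use.names = FALSE)
  reg <- NULL
  if (length(pooledM) == length(pooledA) && length(pooledM) >= 3L &&
      stats::sd(pooledM) > 0)
    reg <- linearRegressionR2(pooledM, pooledA)
  list(groups = groups, regression = reg)
}
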