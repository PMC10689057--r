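## Exact resampling tests used by the expression module. Small-n exact
## enumeration here is deliberate: stats::wilcox.test cannot give exact
## p-values with ties, and the replicate numbers in this design are tiny.

#' Exact sign-flip test on a mean
#'
#' Two-sided test of H0: symmetric about 0, statistic = mean(x), null
#' distribution = all 2^n sign assignments. Used for paired per-replicate
#' log-ratios. For n > `max_exact` a one-sample t-test is used instead.
#'
#' @param x Numeric vector (no NAs).
#' @param max_exact Largest n for exact enumeration (default 6).
#' @return Two-sided p-value.
#' @export
signflip_mean_test <- function(x, max_exact = 6L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  if (n > max_exact) return(t.test(x)$p.value)
  obs <- abs(mean(x))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- abs(as.vector(signs %*% x)) / n
  mean(null >= obs - 1e-12)
}

#' Exact two-sample permutation test on a difference of means
#'
#' Two-sided; enumerates all group-label assignments when their number is
#' at most `max_enum`, otherwise samples `n_mc` random assignments.
#'
#' @param x,y Numeric vectors.
#' @param max_enum Enumeration limit on choose(n, nx) (default 10000).
#' @param n_mc Monte-Carlo assignments past the limit.
#' @return Two-sided p-value.
#' @export
perm_meandiff_test <- function(x, y, max_enum = 10000L, n_mc = 2000L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  z <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  if (choose(length(z), nx) <= max_enum) {
    idx <- combn(length(z), nx)
    null <- apply(idx, 2, function(i) abs(mean(z[i]) - mean(z[-i])))
    mean(null >= obs - 1e-12)
  } else {
    null <- replicate(n_mc, {
      i <- sample(length(z), nx)
      abs(mean(z[i]) - mean(z[-i]))
    })
    (1 + sum(null >= obs - 1e-12)) / (n_mc + 1)
  }
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Zeros are dropped; |x| are ranked with average ranks for ties. For
#' n <= `max_exact` the two-sided p-value is exact by enumeration of all
#' sign assignments (valid under ties); beyond that the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x Numeric vector.
#' @param max_exact Largest n for exact enumeration (default 12).
#' @return List with `statistic` (W+, sum of positive ranks), `p`, `n`
#'   (non-zero observations) and `method`.
#' @export
signed_rank_test <- function(x, max_exact = 12L) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0)
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  mu <- sum(r) / 2
  if (n <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null <- as.vector(signs %*% r)
    p <- mean(abs(null - mu) >= abs(W - mu) - 1e-12)
    method <- "exact sign enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  }
  list(statistic = W, p = p, n = n, method = method)
}

#' Mann-Whitney AUC of a recovery score
#'
#' Rank-based AUC: the probability that a randomly chosen positive outranks
#' a randomly chosen negative (ties count 1/2).
#'
#' @param score Numeric score, higher = more confidently positive.
#' @param positive Logical vector of true labels.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]; positive <- as.logical(positive[ok])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) ap_stop("rank_auc: need both classes")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## BH correction over the non-NA entries only
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}
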