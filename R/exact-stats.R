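# Exact nonparametric rank tests valid in the presence of ties, and
# median/IQR summaries. The null distribution is the conditional
# permutation distribution of the mid-rank statistic given the observed
# (possibly tied) values, obtained by full enumeration for small designs
# and by a subset-sum shift (dynamic-programming) recursion otherwise;
# both are exact.

# Exact null distribution of the group-1 rank sum by DP over scaled ranks.
# ranks2: mid-ranks times 2 (integers). Returns counts of subsets of size
# n1 with each achievable (scaled) rank sum.
rankSumShiftCounts <- function(ranks2, n1) {
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, n1 + 1L, smax + 1L)   # f[k+1, s+1] = #subsets size k, sum s
  f[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n1
    for (k in kmax:1) {
      src <- f[k, ]
      nz <- which(src != 0)
      if (!length(nz)) next
      tgt <- nz + r
      keep <- tgt <= smax + 1L
      f[k + 1L, tgt[keep]] <- f[k + 1L, tgt[keep]] + src[nz[keep]]
    }
  }
  f[n1 + 1L, ]
}

twoSidedP <- function(pLow, pHigh, probs = NULL, pObs = NULL,
                      alternative = c("doubled", "minlike")) {
  alternative <- match.arg(alternative)
  if (alternative == "doubled") return(min(1, 2 * min(pLow, pHigh)))
  sum(probs[probs <= pObs * (1 + 1e-9)])
}

#' Exact Mann-Whitney U test (ties allowed)
#'
#' U is computed from mid-ranks; the exact two-sided p-value comes from
#' the permutation distribution of group assignments conditional on the
#' observed values, so it is valid in the presence of ties. Small designs
#' are fully enumerated; larger ones use an equivalent subset-sum shift
#' recursion (also exact). The two-sided p is twice the smaller tail,
#' capped at 1 (the summed-extreme-probabilities alternative is available
#' via `twoSided = "minlike"`).
#'
#' @param x,y numeric samples (both nonempty).
#' @param method `"auto"`, `"enumeration"` or `"shift"`.
#' @param twoSided `"doubled"` (default) or `"minlike"`.
#' @param enumLimit maximum number of assignments to enumerate under
#'   `method = "auto"`.
#' @return a [RankTestResult-class].
#' @examples
#' pValue(exactMannWhitney(c(1, 2), c(3, 4)))   # 1/3
#' @export
exactMannWhitney <- function(x, y, method = c("auto", "enumeration", "shift"),
                             twoSided = c("doubled", "minlike"),
                             enumLimit = 2e5) {
  method <- match.arg(method); twoSided <- match.arg(twoSided)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  v <- c(x, y)
  r <- rank(v)                            # mid-ranks
  wObs <- sum(r[seq_len(n1)])
  uObs <- wObs - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(v) > 0L
  if (method == "auto")
    method <- if (choose(n, n1) <= enumLimit) "enumeration" else "shift"
  r2 <- as.integer(round(2 * r))
  if (method == "enumeration") {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(r2[combs], nrow = n1))
    tot <- ncol(combs)
    w2 <- round(2 * wObs)
    pLow <- sum(sums <= w2) / tot
    pHigh <- sum(sums >= w2) / tot
    tb <- table(sums) / tot
    probs <- as.numeric(tb)
    pObs <- probs[match(as.character(w2), names(tb))]
    lab <- "exact-enumeration"
  } else {
    cnt <- rankSumShiftCounts(r2, n1)
    tot <- sum(cnt)
    s <- which(cnt != 0) - 1L
    p <- cnt[cnt != 0] / tot
    w2 <- round(2 * wObs)
    pLow <- sum(p[s <= w2])
    pHigh <- sum(p[s >= w2])
    probs <- p
    pObs <- p[match(w2, s)]
    lab <- "exact-shift"
  }
  pv <- twoSidedP(pLow, pHigh, probs, pObs, twoSided)
  new("RankTestResult", statistic = uObs, pValue = pv, method = lab,
      n1 = as.integer(n1), n2 = as.integer(n2), ties = ties,
      test = "mann-whitney")
}

# Exact null counts of the positive-part signed-rank statistic by DP.
signedRankShiftCounts <- function(ranks2) {
  smax <- sum(ranks2)
  g <- numeric(smax + 1L); g[1L] <- 1
  for (r in ranks2) {
    nz <- which(g != 0)
    tgt <- nz + r
    g2 <- g
    g2[tgt] <- g2[tgt] + g[nz]
    g <- g2
  }
  g
}

#' Exact Wilcoxon signed-rank test (ties allowed)
#'
#' Zero differences are dropped (conditioning on non-zero differences);
#' W+ is the mid-rank sum of positive differences of `before - after`.
#' The exact p-value enumerates the `2^m` sign assignments conditional on
#' the observed absolute differences (explicitly for small m, by an
#' equivalent shift recursion otherwise), so tied magnitudes are handled
#' exactly. Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param before,after paired numeric samples of equal length.
#' @param twoSided `"doubled"` (default) or `"minlike"`.
#' @param enumLimit maximum `2^m` to enumerate explicitly.
#' @return a [RankTestResult-class].
#' @examples
#' pValue(exactWilcoxonSignedRank(c(2, 3, 4), c(1, 1, 1)))  # 0.25
#' @export
exactWilcoxonSignedRank <- function(before, after,
                                    twoSided = c("doubled", "minlike"),
                                    enumLimit = 2^15) {
  twoSided <- match.arg(twoSided)
  if (length(before) != length(after) || !length(before))
    stop("paired samples must have equal length >= 1")
  d <- before - after
  zero <- d == 0
  if (all(zero)) {
    warning("all differences are zero; p = 1")
    return(new("RankTestResult", statistic = 0, pValue = 1,
               method = "exact-enumeration", n1 = 0L, n2 = 0L,
               ties = TRUE, test = "wilcoxon-signed-rank"))
  }
  d <- d[!zero]
  m <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  r2 <- as.integer(round(2 * r))
  w2 <- round(2 * wObs)
  if (2^m <= enumLimit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    sums <- as.vector(signs %*% r2)
    tot <- length(sums)
    pLow <- sum(sums <= w2) / tot
    pHigh <- sum(sums >= w2) / tot
    tb <- table(sums) / tot
    probs <- as.numeric(tb)
    pObs <- probs[match(as.character(w2), names(tb))]
    lab <- "exact-enumeration"
  } else {
    cnt <- signedRankShiftCounts(r2)
    tot <- sum(cnt)
    s <- which(cnt != 0) - 1L
    p <- cnt[cnt != 0] / tot
    pLow <- sum(p[s <= w2])
    pHigh <- sum(p[s >= w2])
    probs <- p
    pObs <- p[match(w2, s)]
    lab <- "exact-shift"
  }
  pv <- twoSidedP(pLow, pHigh, probs, pObs, twoSided)
  new("RankTestResult", statistic = wObs, pValue = pv, method = lab,
      n1 = as.integer(m), n2 = 0L, ties = ties,
      test = "wilcoxon-signed-rank")
}

#' Median and interquartile range
#'
#' Median with first and third quartiles using the linear-interpolation
#' quantile rule (type 7).
#'
#' @param x nonempty numeric vector.
#' @return named numeric: `median`, `q1`, `q3`.
#' @export
medianIQR <- function(x) {
  if (!length(x)) stop("empty sample")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}
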