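# Nonparametric inference: Mann-Whitney U and Kendall tau-b, implemented
# from first principles with exact small-sample options.

# exact null counts of the rank-sum W for sample sizes n1, n2 without ties:
# number of size-n1 subsets of ranks 1..(n1+n2) with each possible sum.
# Memoized; U = W - n1(n1+1)/2 ranges over 0..n1*n2.
.uCountsExact <- function(n1, n2) {
  key <- sprintf("u_%d_%d", n1, n2)
  if (!is.null(.megnetCache[[key]])) return(.megnetCache[[key]])
  N <- n1 + n2
  smax <- sum((N - n1 + 1L):N)
  cnt <- matrix(0, n1 + 1L, smax + 1L)   # cnt[k+1, s+1]: size k, sum s
  cnt[1L, 1L] <- 1
  for (v in seq_len(N)) {
    for (k in min(n1, v):1L) {
      cnt[k + 1L, (v + 1L):(smax + 1L)] <-
        cnt[k + 1L, (v + 1L):(smax + 1L)] + cnt[k, 1L:(smax + 1L - v)]
    }
  }
  wmin <- n1 * (n1 + 1L) / 2
  counts <- cnt[n1 + 1L, (wmin + 1L):(wmin + n1 * n2 + 1L)]
  .megnetCache[[key]] <- counts          # index u+1 for U = u
  counts
}

# two tail probabilities of an empirical/counted U distribution
.tailsFromCounts <- function(support, weights, u) {
  tot <- sum(weights)
  eps <- 1e-9
  c(ge = sum(weights[support >= u - eps]) / tot,
    le = sum(weights[support <= u + eps]) / tot)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U convention "number of (x, y) pairs with x > y
#' plus half the ties" (so U = W_x - n1(n1+1)/2 with midranks).  The null
#' distribution is exact -- by the subset-sum recursion when there are no
#' ties and n1*n2 <= 400, or by full enumeration of all choose(n1+n2, n1)
#' group labelings when ties are present but the enumeration is small --
#' and otherwise a normal approximation with tie correction and continuity
#' correction.
#'
#' Note on conventions: software differs between reporting U and
#' U' = n1*n2 - U; both describe the same data.  This function always
#' reports U for the first sample \code{x}; \code{\link{runGroupComparison}}
#' reports the larger of the two for its group table.
#'
#' @param x,y numeric samples (non-empty)
#' @param sided \code{"two"} (default) or \code{"one"}
#' @param direction for one-sided tests, the alternative for \code{x}
#'   relative to \code{y}: \code{"greater"} or \code{"less"}
#' @param method \code{"auto"} (default), \code{"exact"} or
#'   \code{"normal"}
#' @return a \linkS4class{StatResult}
#' @examples
#' mannWhitneyU(c(4, 5, 6), c(1, 2, 3))            # U = 9, complete separation
#' mannWhitneyU(c(1, 3), c(2, 4), sided = "two")   # exact enumeration
#' @export
mannWhitneyU <- function(x, y, sided = c("two", "one"),
                         direction = c("greater", "less"),
                         method = c("auto", "exact", "normal")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("non-finite values in samples")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                     # midranks
  W <- sum(r[seq_len(n1)])
  u <- W - n1 * (n1 + 1) / 2
  tiesPresent <- anyDuplicated(c(x, y)) > 0L
  enumSize <- choose(N, n1)

  if (method == "auto") {
    method <- if ((!tiesPresent && n1 * n2 <= 400) ||
                  (tiesPresent && enumSize <= 2e5)) "exact" else "normal"
  } else if (method == "exact" && tiesPresent && enumSize > 2e5) {
    stop("exact method with ties requires choose(n1+n2, n1) <= 2e5")
  }

  if (method == "exact") {
    if (!tiesPresent) {
      counts <- .uCountsExact(n1, n2)
      tails <- .tailsFromCounts(0:(n1 * n2), counts, u)
    } else {
      combs <- combn(N, n1)
      Ws <- colSums(matrix(r[combs], nrow = n1))
      Us <- Ws - n1 * (n1 + 1) / 2
      tails <- .tailsFromCounts(Us, rep.int(1, length(Us)), u)
    }
    methodLabel <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tieTable <- table(r)
    tieCorr <- sum(tieTable^3 - tieTable) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
    if (sigma2 <= 0) stop("degenerate samples: zero variance")
    sigma <- sqrt(sigma2)
    zGe <- (u - 0.5 - mu) / sigma        # continuity-corrected tails
    zLe <- (u + 0.5 - mu) / sigma
    tails <- c(ge = 1 - pnorm(zGe), le = pnorm(zLe))
    methodLabel <- "normal-approx"
  }

  p <- if (sided == "two") {
    min(1, 2 * min(tails))
  } else if (direction == "greater") tails[["ge"]] else tails[["le"]]
  new("StatResult", statistic = u, pValue = min(1, max(0, p)),
      n1 = n1, n2 = n2, sided = sided, method = methodLabel)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 in practice
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep.int(k, nrow(p)), p + (p >= k))
  }))
}

#' Kendall tau-b rank correlation
#'
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - t_x)(n_0 - t_y)}}
#' with \eqn{n_0 = n(n-1)/2} and the standard tie terms in both margins.
#' p-values come from the normal approximation with the tie-corrected
#' variance of C - D, or from exact permutation enumeration (all n!
#' relabelings) for n <= 8 under \code{method = "auto"}.
#'
#' @param x,y equal-length numeric vectors, n >= 3
#' @param sided \code{"two"} (default) or \code{"one"}
#' @param direction for one-sided tests, alternative sign of the
#'   association: \code{"positive"} or \code{"negative"}
#' @param method \code{"auto"}, \code{"exact"} or \code{"normal"}
#' @return a \linkS4class{StatResult} (\code{n2 = 0} marks a correlation)
#' @examples
#' kendallTauB(1:4, c(2, 1, 4, 3))   # tau = 1/3
#' @export
kendallTauB <- function(x, y, sided = c("two", "one"),
                        direction = c("positive", "negative"),
                        method = c("auto", "exact", "normal")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  sgnx <- sign(outer(x, x, "-"))
  sgny <- sign(outer(y, y, "-"))
  ut <- upper.tri(sgnx)
  S <- sum(sgnx[ut] * sgny[ut])          # C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  t1x <- sum(tx * (tx - 1) / 2); t1y <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - t1x) * (n0 - t1y))
  if (denom == 0)
    stop("degenerate input: a margin is completely tied")
  tau <- S / denom

  if (method == "auto") method <- if (n <= 8L) "exact" else "normal"

  if (method == "exact") {
    if (n > 8L) stop("exact permutation method limited to n <= 8")
    perms <- .permutations(n)
    Sperm <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      sp <- sgny[p, p]
      sum(sgnx[ut] * sp[ut])
    }, numeric(1))
    eps <- 1e-9
    p <- if (sided == "two") {
      mean(abs(Sperm) >= abs(S) - eps)
    } else if (direction == "positive") {
      mean(Sperm >= S - eps)
    } else mean(Sperm <= S + eps)
    methodLabel <- "exact"
  } else {
    # tie-corrected variance of S (no continuity correction)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1x <- sum(tx * (tx - 1) * (tx - 2)); v1y <- sum(ty * (ty - 1) * (ty - 2))
    v2x <- sum(tx * (tx - 1)); v2y <- sum(ty * (ty - 1))
    varS <- (n * (n - 1) * (2 * n + 5) - vt - vu) / 18 +
      v1x * v1y / (9 * n * (n - 1) * (n - 2)) +
      v2x * v2y / (2 * n * (n - 1))
    if (varS <= 0) stop("degenerate input: zero variance")
    z <- S / sqrt(varS)
    p <- if (sided == "two") {
      2 * (1 - pnorm(abs(z)))
    } else if (direction == "positive") 1 - pnorm(z) else pnorm(z)
    methodLabel <- "normal-approx"
  }
  new("StatResult", statistic = tau, pValue = min(1, max(0, p)),
      n1 = n, n2 = 0L, sided = sided, method = methodLabel)
}

#' Optional Benjamini-Hochberg adjustment for a result table
#'
#' Adds a \code{p_adj} column to any table with a \code{p} column.  The
#' pipeline deliberately applies no multiple-comparison correction by
#' default (the replicated analysis reports uncorrected exact p-values and
#' interprets patterns); this helper is for users who want FDR control.
#'
#' @param table data.frame containing a \code{p} column
#' @return the table with an appended \code{p_adj} column
#' @export
adjustBH <- function(table) {
  stopifnot(is.data.frame(table), "p" %in% names(table))
  table$p_adj <- stats::p.adjust(table$p, method = "BH")
  table
}
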