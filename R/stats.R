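#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `x` successes in `n_draw` draws without
#' replacement from a population of `n_total` containing `n_success`
#' successes. Computed in log space with [lchoose()] for numerical stability;
#' this is the kernel of the exact test on 2x2 tables.
#'
#' @param x Integer number of successes drawn (vectorised).
#' @param n_total Population size.
#' @param n_success Number of successes in the population.
#' @param n_draw Number of draws.
#' @return Numeric vector of probabilities; 0 outside the support.
#' @examples
#' hypergeom_pmf(7, 16, 9, 7) # 36/11440
#' @export
hypergeom_pmf <- function(x, n_total, n_success, n_draw) {
  stopifnot(length(n_total) == 1, length(n_success) == 1, length(n_draw) == 1)
  if (n_total < 0 || n_success < 0 || n_draw < 0 ||
      n_success > n_total || n_draw > n_total) {
    rlang::abort("require 0 <= n_success, n_draw <= n_total")
  }
  lo <- max(0L, n_draw - (n_total - n_success))
  hi <- min(n_draw, n_success)
  p <- numeric(length(x))
  ok <- x >= lo & x <= hi & x == round(x)
  p[ok] <- exp(
    lchoose(n_success, x[ok]) +
      lchoose(n_total - n_success, n_draw - x[ok]) -
      lchoose(n_total, n_draw)
  )
  p
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass two-sided test: the p-value is the sum of hypergeometric
#' probabilities of every table sharing the observed margins whose probability
#' does not exceed that of the observed table (within a small relative
#' tolerance that absorbs floating-point ties). This is the convention used by
#' base R's `fisher.test` and by most clinical reports.
#'
#' The table layout is rows = groups, columns = feature present/absent:
#' \preformatted{
#'           present  absent
#'   group1     a        b
#'   group2     c        d
#' }
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param tie_tol Relative tolerance for counting a table as "as probable as"
#'   the observed one. Default `1e-7`.
#' @return An object of class `"htest"` with `p.value`, `statistic` (the
#'   hypergeometric probability of the observed table) and `method`.
#' @examples
#' fisher_exact_two_sided(4, 3, 0, 9)$p.value # ~0.019
#' @export
fisher_exact_two_sided <- function(a, b, c, d, tie_tol = 1e-7) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("all four cell counts must be non-negative integers")
  }
  m1 <- a + b # group 1 size
  n_total <- a + b + c + d
  k <- a + c # feature-present column total
  lo <- max(0L, k - (n_total - m1))
  hi <- min(k, m1)
  support <- lo:hi
  probs <- hypergeom_pmf(support, n_total, m1, k)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + tie_tol)])
  structure(
    list(
      statistic = c(prob = p_obs),
      p.value = min(p, 1),
      method = "fisher_exact",
      data.name = sprintf("2x2 table (%d, %d, %d, %d)", a, b, c, d)
    ),
    class = "htest"
  )
}

# midranks of the pooled sample
.midranks <- function(z) rank(z, ties.method = "average")

#' Two-sided Mann-Whitney U test
#'
#' U is computed from midranks of the pooled sample. When the combined sample
#' size is at most `exact_max` and there are no ties, the two-sided p-value is
#' obtained by exact enumeration of all group assignments (p = proportion of
#' assignments whose U is at least as far from its null mean as the observed
#' U). Otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest combined sample size for which the exact
#'   permutation distribution is enumerated (default 20).
#' @return An object of class `"htest"` with `statistic` (U for the `x`
#'   sample), `p.value` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p.value # 1/3 by enumeration
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("both samples must be non-empty")
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- .midranks(pooled)
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && nx + ny <= exact_max) {
    # exact: U depends only on which ranks go to x
    idx <- utils::combn(nx + ny, nx)
    rk <- sort(r)
    u_all <- colSums(matrix(rk[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_x - mu) - 1e-9)
    method <- "mann_whitney (exact)"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_x - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "mann_whitney (normal approximation)"
  }
  structure(
    list(
      statistic = c(U = u_x),
      p.value = p,
      method = method,
      data.name = sprintf("x (n = %d), y (n = %d)", nx, ny)
    ),
    class = "htest"
  )
}
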