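#' Kendall rank correlation (tau-b)
#'
#' Tau-b estimator of Kendall's rank correlation: the probability of
#' concordance minus the probability of discordance between two rankings,
#' normalized with tie corrections so that perfectly concordant (discordant)
#' data score +1 (-1). The fast path is an O(n log n) merge-sort pair count
#' (Knight's algorithm, compiled); [kendall_tau_ref()] is the O(n^2)
#' brute-force reference the fast path must agree with exactly.
#'
#' Kendall's tau is invariant under strictly monotone transforms of either
#' argument, which is what makes it the scale-invariant cell--cell dependence
#' score used throughout this package.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return A single number in `[-1, 1]`. When either vector is constant the
#'   correlation is undefined; 0 is returned with a warning.
#' @seealso [ccor_matrix()] for the pairwise cell matrix.
#' @examples
#' kendall_tau(1:4, c(2, 1, 4, 3))  # 1/3
#' @export
kendall_tau <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  tau <- .kendall_tau_cpp(x, y)
  if (is.na(tau)) {
    warning("Kendall tau undefined for constant input; returning 0")
    return(0)
  }
  tau
}

#' Brute-force Kendall tau-b over all pairs
#'
#' O(n^2) enumeration of concordant, discordant and tied pairs. Kept as the
#' independent reference implementation for the merge-sort estimator.
#'
#' @inheritParams kendall_tau
#' @return tau-b, or 0 with a warning for constant input.
#' @export
kendall_tau_ref <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) {
    dx <- x[i] - x[(i + 1L):n]
    dy <- y[i] - y[(i + 1L):n]
    s <- sign(dx) * sign(dy)
    conc <- conc + sum(s > 0)
    disc <- disc + sum(s < 0)
    tx <- tx + sum(dx == 0 & dy != 0)
    ty <- ty + sum(dy == 0 & dx != 0)
  }
  n0 <- n * (n - 1) / 2
  nboth <- n0 - conc - disc - tx - ty       # tied in both
  denom <- sqrt((n0 - tx - nboth) * (n0 - ty - nboth))
  if (denom == 0) {
    warning("Kendall tau undefined for constant input; returning 0")
    return(0)
  }
  (conc - disc) / denom
}

#' Pseudo-observations (rank transform to the unit interval)
#'
#' Maps a sample to (0,1) by r_i/(n+1) where r_i are average ranks, the
#' standard transform feeding empirical copula estimators. Invariant under
#' strictly increasing transforms of the input.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector in (0, 1).
#' @examples
#' pseudo_observations(c(10, 20, 30))  # 0.25 0.50 0.75
#' @export
pseudo_observations <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two observations")
  if (length(unique(x)) == 1L)
    warning("constant vector: all pseudo-observations are 0.5")
  rank(x, ties.method = "average") / (length(x) + 1)
}
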