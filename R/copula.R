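#' Clayton copula machinery
#'
#' The Clayton copula is the Archimedean copula with generator
#' \eqn{\phi(x) = (x^{-\theta} - 1)/\theta}, \eqn{\theta \in [-1, \infty)
#' \setminus \{0\}}; the \eqn{\theta \to 0} limit is the independence copula.
#' Its Kendall tau has the closed form \eqn{\tau = \theta/(\theta + 2)}, the
#' relation that lets an empirical tau be read as a copula dependence score.
#'
#' @param theta Clayton dependence parameter, `theta >= -1`, `theta != 0`
#'   (pass `theta = 0` to `clayton_cdf()` for the independence limit).
#' @name clayton
NULL

.check_theta <- function(theta, allow_zero = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta))
    stop("theta must be a single number")
  if (theta < -1) stop("theta must be >= -1")
  if (!allow_zero && theta == 0)
    stop("theta = 0 is the independence limit; not valid for the generator")
  invisible(theta)
}

#' @describeIn clayton Generator \eqn{\phi(x) = (x^{-\theta}-1)/\theta};
#'   strictly decreasing on (0, 1] with \eqn{\phi(1) = 0}.
#' @param x value in (0, 1] (vectorized).
#' @export
clayton_generator <- function(x, theta) {
  .check_theta(theta)
  if (any(x <= 0)) stop("generator domain is (0, 1]: x must be > 0")
  (x^(-theta) - 1) / theta
}

#' @describeIn clayton Bivariate CDF
#'   \eqn{C(u,v) = \max(u^{-\theta}+v^{-\theta}-1,\,0)^{-1/\theta}} (the
#'   pseudo-inverse clamp matters for \eqn{\theta < 0}); `theta = 0` returns
#'   the independence copula \eqn{uv}. Satisfies the copula boundary
#'   conditions \eqn{C(u,1)=u}, \eqn{C(u,0)=0} and the Frechet-Hoeffding
#'   bounds.
#' @param u,v values in `[0, 1]` (vectorized, recycled).
#' @export
clayton_cdf <- function(u, v, theta) {
  .check_theta(theta, allow_zero = TRUE)
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1))
    stop("u and v must lie in [0, 1]")
  if (theta == 0) return(u * v)
  # u or v exactly 0: C = 0 (avoid 0^negative = Inf)
  out <- numeric(length(u <- rep_len(u, max(length(u), length(v)))))
  v <- rep_len(v, length(u))
  pos <- u > 0 & v > 0
  s <- u[pos]^(-theta) + v[pos]^(-theta) - 1
  out[pos] <- pmax(s, 0)^(-1 / theta)
  if (theta < 0) out[!pos] <- 0   # clamp already gives 0 for theta > 0
  out
}

#' @describeIn clayton Closed-form Kendall tau of the Clayton copula,
#'   \eqn{\tau = \theta/(\theta+2)} (0 in the independence limit).
#' @export
tau_from_theta <- function(theta) {
  .check_theta(theta, allow_zero = TRUE)
  if (theta <= -2) stop("theta must be > -2")
  if (theta == 0) return(0)
  theta / (theta + 2)
}

#' @describeIn clayton Inverse of `tau_from_theta()`:
#'   \eqn{\theta = 2\tau/(1-\tau)} for \eqn{\tau \in (-1/3, 1)} (tau = 0 maps
#'   to the independence limit, returned as 0).
#' @param tau Kendall tau in (-1/3, 1) (the Clayton-attainable range).
#' @export
theta_from_tau <- function(tau) {
  if (any(tau <= -1/3 | tau >= 1)) {
    tau <- pmin(pmax(tau, -1/3 + 1e-9), 1 - 1e-9)
    warning("tau clipped to the Clayton-attainable range (-1/3, 1)")
  }
  2 * tau / (1 - tau)
}

#' Sample from the bivariate Clayton copula
#'
#' Conditional-inversion sampler: draw \eqn{u, w \sim U(0,1)} and set
#' \eqn{v = ((w^{-\theta/(1+\theta)} - 1) u^{-\theta} + 1)^{-1/\theta}},
#' which inverts the conditional CDF \eqn{C_{2|1}(v \mid u)}. Valid for
#' \eqn{\theta > -1}, \eqn{\theta \ne 0}.
#'
#' @param n number of pairs.
#' @param theta Clayton parameter, `theta > -1`, `theta != 0`.
#' @return n x 2 matrix of (u, v) pairs in (0, 1).
#' @examples
#' set.seed(1)
#' uv <- rclayton(1000, theta = 1)
#' kendall_tau(uv[, 1], uv[, 2])  # near 1/3
#' @export
rclayton <- function(n, theta) {
  .check_theta(theta)
  if (theta <= -1) stop("sampler requires theta > -1")
  u <- runif(n)
  w <- runif(n)
  inner <- (w^(-theta / (1 + theta)) - 1) * u^(-theta) + 1
  v <- pmax(inner, .Machine$double.eps)^(-1 / theta)
  cbind(u = u, v = pmin(pmax(v, .Machine$double.eps), 1 - .Machine$double.eps))
}
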