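#' NB2 probability mass, tail probability and variance functions
#'
#' The NB2 parameterization used throughout this package has mean `u` and
#' dispersion `theta`, with variance `u + u^2 / theta`; smaller `theta` means
#' stronger overdispersion, and the Poisson is recovered as `theta -> Inf`.
#' In particular `P(Y = 0) = (theta / (theta + u))^theta`, which is how the
#' expected fraction of empty sampling units is computed from a fitted model.
#'
#' Evaluation uses log-gamma arithmetic so large counts stay numerically
#' stable.
#'
#' @param y Non-negative integer count(s).
#' @param u Mean, `>= 0`.
#' @param theta Dispersion, `> 0`.
#'
#' @return `nb2_pmf()`: `P(Y = y)`. `nb2_tail()`: `P(Y > y_min)`.
#'   `nb2_variance()` / `nb1_variance()`: the variance under the NB2
#'   (`u + u^2/theta`) and NB1 (`u + u/theta`) formulations.
#' @examples
#' nb2_pmf(0, u = 5, theta = 0.2)   # ~0.52: over half the units empty
#' nb2_tail(50, u = 5, theta = 0.2) # ~0.013: heavy right tail
#' nb2_variance(5, 0.2)             # 130
#' @export
nb2_pmf <- function(y, u, theta) {
  check_nb2_params(u, theta)
  stopifnot(all(y >= 0), all(y == floor(y)))
  out <- numeric(length(y))
  degenerate <- u == 0
  if (length(u) == 1L) {
    if (degenerate) return(as.numeric(y == 0))
    out <- exp(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
                 theta * (log(theta) - log(theta + u)) +
                 y * (log(u) - log(theta + u)))
  } else {
    out <- ifelse(degenerate, as.numeric(y == 0),
                  exp(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
                        theta * (log(theta) - log(theta + u)) +
                        y * (log(pmax(u, .Machine$double.xmin)) - log(theta + u))))
  }
  out
}

#' @param y_min `nb2_tail()` returns the probability of a count strictly
#'   greater than `y_min`.
#' @rdname nb2_pmf
#' @export
nb2_tail <- function(y_min, u, theta) {
  check_nb2_params(u, theta)
  stopifnot(length(y_min) == 1L, y_min >= 0, y_min == floor(y_min))
  if (u == 0) return(0)
  1 - sum(nb2_pmf(0:y_min, u, theta))
}

#' @rdname nb2_pmf
#' @export
nb2_variance <- function(u, theta) {
  check_nb2_params(u, theta)
  u + u^2 / theta
}

#' @rdname nb2_pmf
#' @export
nb1_variance <- function(u, theta) {
  check_nb2_params(u, theta)
  u + u / theta
}

check_nb2_params <- function(u, theta) {
  if (any(!is.finite(u)) || any(u < 0)) {
    abort("NB2 mean u must be finite and >= 0", class = "nbrsf_domain_error")
  }
  if (any(is.na(theta)) || any(theta <= 0)) {
    abort("NB2 dispersion theta must be > 0", class = "nbrsf_domain_error")
  }
  invisible(TRUE)
}

# NB2 log-likelihood at counts y, means mu, dispersion theta
nb2_loglik <- function(y, mu, theta) {
  mu <- pmax(mu, .Machine$double.xmin)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta) + y * log(mu) - (theta + y) * log(theta + mu))
}
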