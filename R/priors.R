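#' Uniform prior bounds on the odds-ratio hyperparameters
#'
#' The per-battle odds ratio `P` is drawn from a gamma distribution whose
#' mean `mu` and standard deviation `sigma` are the inferred hyperparameters.
#' Both receive independent uniform priors, U(0, 5) by default — wide,
#' uninformative bounds covering plausible per-soldier lethality odds.
#'
#' @param mu_low,mu_high Bounds of the uniform prior on `mu`.
#' @param sigma_low,sigma_high Bounds of the uniform prior on `sigma`.
#' @return A validated list of bounds.
#' @export
prior_config <- function(mu_low = 0, mu_high = 5,
                         sigma_low = 0, sigma_high = 5) {
  if (mu_low < 0 || sigma_low < 0 || mu_low >= mu_high ||
      sigma_low >= sigma_high) {
    stop("prior bounds must satisfy 0 <= low < high", call. = FALSE)
  }
  list(mu_low = mu_low, mu_high = mu_high,
       sigma_low = sigma_low, sigma_high = sigma_high)
}

# Boundary draws where the gamma reparameterization degenerates are handled
# below this threshold: mu draws are resampled, sigma draws route to the
# deterministic P = mu branch. Measure-zero handling that cannot affect
# posteriors at practical tolerances.
DEGENERACY_EPS <- 1e-6

#' Gamma shape/scale from mean and standard deviation
#'
#' Moment reparameterization of the gamma distribution:
#' `kappa = (mu/sigma)^2`, `theta = sigma^2/mu`, so that
#' `kappa * theta = mu` and `kappa * theta^2 = sigma^2`.
#'
#' @param mu Mean, positive.
#' @param sigma Standard deviation, non-negative. Values below the
#'   degeneracy threshold (1e-6) mark the draw as deterministic (`P = mu`).
#' @return A list with `kappa`, `theta` and `degenerate` (vectorized).
#' @export
#' @examples
#' gamma_from_moments(2, 1) # kappa 4, theta 0.5
gamma_from_moments <- function(mu, sigma) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  degenerate <- sigma < DEGENERACY_EPS
  kappa <- ifelse(degenerate, NA_real_, (mu / sigma)^2)
  theta <- ifelse(degenerate, NA_real_, sigma^2 / mu)
  list(kappa = kappa, theta = theta, degenerate = degenerate)
}

# Deterministic sub-seed derivation: one root seed, independent named
# streams for each consumer so changing one consumer's draw count does not
# shift another's stream. Plain multiplicative hash kept below 2^31.
abc_substream <- function(seed, name) {
  idx <- match(name, c("hyper", "pdraw", "synth", "model"))
  if (is.na(idx)) stop("unknown substream: ", name, call. = FALSE)
  as.integer((as.double(seed) * 2654435761 + idx * 40503) %% 2147483629)
}

#' Sample hyperparameter draws from the prior
#'
#' Draws `mu ~ U(mu_low, mu_high)` and `sigma ~ U(sigma_low, sigma_high)`
#' and attaches the derived gamma shape/scale. `mu` draws at the degenerate
#' boundary (below 1e-6) are resampled; degenerate `sigma` draws are kept
#' and flagged, yielding deterministic `P = mu`.
#'
#' @param n Number of draws.
#' @param prior [prior_config()].
#' @return data.frame with columns `mu`, `sigma`, `kappa`, `theta`,
#'   `degenerate`.
#' @export
sample_hyperparams <- function(n, prior = prior_config()) {
  mu <- stats::runif(n, prior$mu_low, prior$mu_high)
  bad <- mu < DEGENERACY_EPS
  while (any(bad)) {
    mu[bad] <- stats::runif(sum(bad), prior$mu_low, prior$mu_high)
    bad <- mu < DEGENERACY_EPS
  }
  sigma <- stats::runif(n, prior$sigma_low, prior$sigma_high)
  g <- gamma_from_moments(mu, sigma)
  data.frame(mu = mu, sigma = sigma, kappa = g$kappa, theta = g$theta,
             degenerate = g$degenerate)
}

#' Sample per-battle odds ratios
#'
#' Draws `n` independent odds ratios from one hyperparameter draw:
#' `P ~ Gamma(kappa, theta)`, or `P = mu` exactly when `sigma` is
#' degenerate. One ABC run over a dataset of `n` battles consumes `n` such
#' draws.
#'
#' @param n Number of draws.
#' @param hyper One row of [sample_hyperparams()] output (or any list with
#'   `mu`, `kappa`, `theta`, `degenerate`).
#' @return Numeric vector of positive odds ratios.
#' @export
sample_odds_ratio <- function(n, hyper) {
  if (isTRUE(hyper$degenerate)) {
    return(rep(hyper$mu, n))
  }
  stats::rgamma(n, shape = hyper$kappa, scale = hyper$theta)
}
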