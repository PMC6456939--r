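#' Right-censored geometric distributions and their finite mixtures
#'
#' The basic building block of the package is the geometric distribution on
#' \{0, 1, 2, ...\} (number of failures before the first success, success
#' probability \code{p}) subjected to artificial right censoring at a fixed
#' constant \code{T}: distances larger than \code{T} are recorded only as
#' "greater than \code{T}", with point mass \eqn{(1-p)^{T+1} = P(Y > T)}.
#' An observation therefore carries a value \code{y} and a censoring
#' indicator \code{delta} (1 = observed, 0 = censored), and the
#' log-probability of a single observation is
#' \deqn{\delta\,[\log p + y \log(1-p)] + (1-\delta)(T+1)\log(1-p).}
#'
#' @name censored-geometric
#' @keywords internal
NULL

## ---- parameter containers ----------------------------------------------

#' Parameters of a finite mixture of right-censored geometric distributions
#'
#' @param pi numeric vector of component proportions; must sum to 1.
#' @param p numeric vector of per-component success probabilities in (0,1),
#'   same length as \code{pi}.
#' @param T censoring constant in bp, or \code{NA} for an uncensored model.
#' @return An object of class \code{"mixture_params"} with fields \code{g}
#'   (component count), \code{pi}, \code{p} and \code{T}. Components are
#'   stored in canonical order: \code{p} decreasing, i.e. mean distance
#'   increasing, so that fits are comparable across runs despite EM label
#'   switching.
#' @export
mixture_params <- function(pi, p, T = NA_real_) {
  pi <- as.numeric(pi); p <- as.numeric(p)
  if (length(pi) != length(p)) stop("'pi' and 'p' must have the same length")
  if (length(pi) < 1L) stop("at least one component is required")
  if (any(!is.finite(pi)) || any(pi < 0)) stop("'pi' must be non-negative and finite")
  if (abs(sum(pi) - 1) > 1e-10) stop("component proportions must sum to 1")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("success probabilities must lie strictly in (0, 1)")
  if (!is.na(T) && T < 1) stop("censoring constant 'T' must be >= 1")
  ord <- order(p, decreasing = TRUE)
  structure(list(g = length(p), pi = pi[ord], p = p[ord], T = as.numeric(T)),
            class = "mixture_params")
}

#' Parameters of a mixture of censored-geometric GLMs with a shared slope
#'
#' Each component is a censored geometric whose success probability depends
#' on a covariate \code{x} (typically window GC fraction) through the
#' log-mean link \eqn{\eta_j(x) = \beta_{j0} + \beta_1 x},
#' \eqn{\mu_j = e^{\eta_j}}, \eqn{p_j(x) = 1/(1+\mu_j)}. The slope
#' \eqn{\beta_1} is shared across components because it represents a single
#' genome-wide GC-content effect; the intercepts differ per component.
#'
#' @param pi component proportions (sum to 1).
#' @param beta0 per-component intercepts on the log-mean scale.
#' @param beta1 shared covariate slope.
#' @param T censoring constant in bp, or \code{NA}.
#' @return Object of class \code{"glm_mixture_params"} with fields \code{g},
#'   \code{pi}, \code{beta0}, \code{beta1}, \code{T}. Canonical component
#'   order is \code{beta0} increasing (mean distance increasing, matching
#'   \code{p} decreasing at any fixed covariate value).
#' @export
glm_mixture_params <- function(pi, beta0, beta1, T = NA_real_) {
  pi <- as.numeric(pi); beta0 <- as.numeric(beta0); beta1 <- as.numeric(beta1)
  if (length(pi) != length(beta0)) stop("'pi' and 'beta0' must have the same length")
  if (length(beta1) != 1L || !is.finite(beta1)) stop("'beta1' must be a single finite number")
  if (any(!is.finite(pi)) || any(pi < 0)) stop("'pi' must be non-negative and finite")
  if (abs(sum(pi) - 1) > 1e-10) stop("component proportions must sum to 1")
  if (any(!is.finite(beta0))) stop("'beta0' must be finite")
  if (!is.na(T) && T < 1) stop("censoring constant 'T' must be >= 1")
  ord <- order(beta0)
  structure(list(g = length(pi), pi = pi[ord], beta0 = beta0[ord],
                 beta1 = beta1, T = as.numeric(T)),
            class = "glm_mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Censored-geometric mixture: g = %d, T = %s\n", x$g,
              ifelse(is.na(x$T), "none", format(x$T))))
  print(data.frame(pi = x$pi, p = x$p, mean = (1 - x$p) / x$p))
  invisible(x)
}

#' @export
print.glm_mixture_params <- function(x, ...) {
  cat(sprintf("Censored-geometric GLM mixture: g = %d, beta1 = %.4g, T = %s\n",
              x$g, x$beta1, ifelse(is.na(x$T), "none", format(x$T))))
  print(data.frame(pi = x$pi, beta0 = x$beta0))
  invisible(x)
}

#' Component success probabilities at covariate values
#'
#' @param params a \code{glm_mixture_params} object.
#' @param x numeric covariate vector.
#' @return matrix \code{length(x) x g} of \eqn{p_j(x) = 1/(1+e^{\beta_{j0}+\beta_1 x})}.
#' @export
glm_component_p <- function(params, x) {
  eta <- outer(params$beta1 * x, params$beta0, `+`)
  1 / (1 + exp(eta))
}

## ---- single-component log-likelihood and CDF ---------------------------

#' Log-probability of one right-censored geometric observation
#'
#' @param y non-negative integer distance(s).
#' @param delta censoring indicator(s): 1 observed, 0 censored. For censored
#'   entries \code{y} is ignored; the probability is \eqn{P(Y > T)}.
#' @param p success probability in (0,1).
#' @param T censoring constant (required when any \code{delta == 0}).
#' @return log-probability, vectorized over \code{y}/\code{delta}.
#' @export
loglik_single <- function(y, delta, p, T = NA_real_) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single probability strictly in (0, 1)")
  if (any(delta == 0) && is.na(T)) stop("censored observations require 'T'")
  if (is.na(T)) T <- 0                  # unused: no censored entries
  l1p <- log1p(-p)                      # log(1 - p), stable for small p
  delta * (log(p) + y * l1p) + (1 - delta) * (T + 1) * l1p
}

#' CDF of the (uncensored) geometric distribution
#'
#' \eqn{F(y) = P(Y \le y) = 1 - (1-p)^{y+1}} with support starting at 0;
#' negative \code{y} returns 0. Used by the inverse normal transformation,
#' which by construction is applied only to uncensored distances.
#'
#' @param y integer quantile(s).
#' @param p success probability in (0,1).
#' @return probability, vectorized over \code{y}.
#' @export
cdf_single <- function(y, p) {
  if (any(p <= 0) || any(p >= 1)) stop("'p' must be strictly in (0, 1)")
  ifelse(y < 0, 0, -expm1((floor(y) + 1) * log1p(-p)))
}

## ---- mixture log-likelihood / CDF --------------------------------------

# n x g matrix of per-component log-probabilities for plain mixture params.
component_loglik_matrix <- function(y, delta, params) {
  g <- params$g
  out <- matrix(NA_real_, length(y), g)
  for (j in seq_len(g))
    out[, j] <- loglik_single(y, delta, params$p[j], params$T)
  out
}

# n x g matrix for GLM params at covariate x (recycled scalar x allowed).
component_loglik_matrix_glm <- function(y, delta, x, params) {
  n <- length(y)
  if (length(x) == 1L) x <- rep(x, n)
  eta <- outer(params$beta1 * x, params$beta0, `+`)   # n x g
  ## log p = -log(1+mu), log(1-p) = eta - log(1+mu); mu = exp(eta)
  log1pmu <- log1p(exp(eta))
  big <- eta > 30                                     # avoid overflow; log(1+e^eta) ~ eta
  log1pmu[big] <- eta[big]
  logp <- -log1pmu
  log1mp <- eta - log1pmu
  Tpl1 <- if (is.na(params$T)) 1 else params$T + 1   # unused when all observed
  delta * (logp + y * log1mp) + (1 - delta) * Tpl1 * log1mp
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Log-likelihood of observations under a censored-geometric mixture
#'
#' Computes \eqn{\log \sum_j \pi_j f_j(y)} per observation via log-sum-exp.
#'
#' @param y,delta observation vectors (see \code{\link{loglik_single}}).
#' @param params a \code{\link{mixture_params}} object.
#' @return numeric vector of per-observation log-probabilities.
#' @export
mixture_loglik <- function(y, delta, params) {
  stopifnot(inherits(params, "mixture_params"))
  lm <- component_loglik_matrix(y, delta, params)
  logsumexp_rows(sweep(lm, 2L, log(params$pi), `+`))
}

#' Mixture CDF of the covariate-adjusted model
#'
#' \eqn{F(y; x) = \sum_j \pi_j F_j(y; x)} where \eqn{F_j} is the uncensored
#' geometric CDF with success probability \eqn{p_j(x)}.
#'
#' @param y integer quantile(s).
#' @param x covariate value(s), recycled against \code{y}.
#' @param params a \code{\link{glm_mixture_params}} object.
#' @return probability vector.
#' @export
mixture_cdf_glm <- function(y, x, params) {
  stopifnot(inherits(params, "glm_mixture_params"))
  n <- max(length(y), length(x))
  y <- rep_len(y, n); x <- rep_len(x, n)
  pmat <- glm_component_p(params, x)                 # n x g
  Fmat <- matrix(0, n, params$g)
  pos <- y >= 0
  for (j in seq_len(params$g))
    Fmat[pos, j] <- -expm1((floor(y[pos]) + 1) * log1p(-pmat[pos, j]))
  as.numeric(Fmat %*% params$pi)
}

#' Mixture CDF of the plain (covariate-free) model
#'
#' @param y integer quantile(s).
#' @param params a \code{\link{mixture_params}} object.
#' @return probability vector \eqn{\sum_j \pi_j F_j(y)}.
#' @export
mixture_cdf <- function(y, params) {
  stopifnot(inherits(params, "mixture_params"))
  Fmat <- vapply(seq_len(params$g), function(j) cdf_single(y, params$p[j]),
                 numeric(length(y)))
  as.numeric(matrix(Fmat, ncol = params$g) %*% params$pi)
}

## ---- samplers ----------------------------------------------------------

#' Sample from a censored-geometric mixture
#'
#' Draws component labels from \code{pi}, distances from the geometric with
#' the component's success probability, and applies right censoring at
#' \code{params$T} (if set): draws with \code{y > T} are flagged censored
#' (\code{delta = 0}); their raw value is retained for diagnostics only.
#'
#' @param n number of draws.
#' @param params a \code{\link{mixture_params}} object.
#' @param rng_seed optional integer seed for reproducibility.
#' @return data.frame with columns \code{y}, \code{delta}, \code{component}.
#' @export
sample_mixture <- function(n, params, rng_seed = NULL) {
  stopifnot(inherits(params, "mixture_params"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lab <- sample.int(params$g, n, replace = TRUE, prob = params$pi)
  y <- stats::rgeom(n, prob = params$p[lab])
  delta <- if (is.na(params$T)) rep(1L, n) else as.integer(y <= params$T)
  structure(data.frame(y = y, delta = delta, component = lab), T = params$T)
}

#' Sample from the covariate-adjusted censored-geometric mixture
#'
#' @param n number of draws.
#' @param params a \code{\link{glm_mixture_params}} object.
#' @param x_sampler function of one argument \code{n} returning \code{n}
#'   covariate values; default Uniform[0, 0.25].
#' @param rng_seed optional integer seed.
#' @return data.frame with columns \code{y}, \code{delta}, \code{x},
#'   \code{component}.
#' @export
sample_mixture_glm <- function(n, params,
                               x_sampler = function(n) stats::runif(n, 0, 0.25),
                               rng_seed = NULL) {
  stopifnot(inherits(params, "glm_mixture_params"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x <- x_sampler(n)
  lab <- sample.int(params$g, n, replace = TRUE, prob = params$pi)
  pmat <- glm_component_p(params, x)
  p <- pmat[cbind(seq_len(n), lab)]
  y <- stats::rgeom(n, prob = p)
  delta <- if (is.na(params$T)) rep(1L, n) else as.integer(y <= params$T)
  structure(data.frame(y = y, delta = delta, x = x, component = lab),
            T = params$T)
}

## ---- serialization ------------------------------------------------------

#' Write / read mixture parameters as flat JSON
#'
#' @param params a \code{mixture_params} or \code{glm_mixture_params} object.
#' @param path file path.
#' @return \code{read_params} returns the reconstructed parameter object.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$model <- if (inherits(params, "glm_mixture_params")) "glm_mixture" else "mixture"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  T <- if (is.null(x$T) || is.na(x$T)) NA_real_ else as.numeric(x$T)
  if (identical(x$model, "glm_mixture"))
    glm_mixture_params(x$pi, x$beta0, x$beta1, T)
  else
    mixture_params(x$pi, x$p, T)
}
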