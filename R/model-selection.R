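#' Choosing the number of mixture components
#'
#' The usual chi-square reference distribution for a likelihood-ratio test
#' is invalid when comparing mixtures with different numbers of components
#' (the null lies on the parameter-space boundary), so the p-value is
#' obtained by parametric bootstrap: simulate from the fitted null model,
#' refit both hypotheses on each replicate, and compare the observed LRT
#' score with the bootstrap distribution.
#'
#' @name model-selection
#' @keywords internal
NULL

#' Likelihood-ratio statistic from two fits
#'
#' @param fit0,fit1 \code{mixture_fit} objects for the null (fewer
#'   components) and alternative models on the same data.
#' @return \eqn{2(l_1 - l_0)}; small negative values (possible when the
#'   alternative optimization stalls in a worse local optimum) are floored
#'   at 0 with a warning.
#' @export
lrt_statistic <- function(fit0, fit1) {
  stat <- 2 * (fit1$loglik - fit0$loglik)
  if (stat < 0) {
    warning("negative LRT statistic floored at 0; ",
            "the alternative fit may need more restarts", call. = FALSE)
    stat <- 0
  }
  stat
}

#' Parametric-bootstrap likelihood-ratio test for the component count
#'
#' Tests H0: g = \code{g0} against H1: g = \code{g1} (\code{g0 < g1}).
#' Both models are fitted to the observed data; \code{B} datasets of the
#' same size are then simulated from the fitted null model (matching the
#' censoring constant and, in GLM mode, conditioning on the observed
#' covariate values, which are a fixed property of the genome), both
#' models are refitted on each replicate, and the p-value is
#' \eqn{(1 + \#\{LRT_b \ge LRT_{obs}\})/(B + 1)} — a convention that can
#' never return an exact zero.
#'
#' @param data observations (a \code{distance_series} or list/data.frame
#'   with \code{y}, \code{delta}, optionally \code{x}).
#' @param g0,g1 null and alternative component counts.
#' @param B number of bootstrap replicates (>= 19).
#' @param config a \code{\link{fit_config}} used for every fit; bootstrap
#'   refits are cold-started (fresh initialization per replicate).
#' @param glm if \code{TRUE} fit the covariate-adjusted model.
#' @param T censoring constant override.
#' @return object of class \code{"lrt_result"}: list with \code{g0},
#'   \code{g1}, \code{observed_lrt}, \code{bootstrap_lrts},
#'   \code{p_value}, \code{fit0}, \code{fit1}, \code{n_failed}
#'   (replicates redrawn after a fitting failure).
#' @export
bootstrap_component_test <- function(data, g0, g1, B = 500L,
                                     config = fit_config(), glm = FALSE,
                                     T = NULL) {
  if (g1 <= g0) stop("'g1' must exceed 'g0'")
  if (B < 19L) stop("at least 19 bootstrap replicates are required")
  obs <- as_observation_data(data, T = T)
  n <- length(obs$y)
  ## seed once here; per-fit reseeding would make every replicate identical
  if (!is.null(config$rng_seed)) {
    set.seed(config$rng_seed)
    config$rng_seed <- NULL
  }
  fitter <- if (glm) fit_mixture_glm else fit_mixture
  ## the alternative fit also starts from a split of the null optimum, so
  ## the nested ordering l1 >= l0 is reliable and LRT scores rarely floor
  fit0 <- fitter(obs, g0, config)
  fit1 <- fitter(obs, g1, config, init = split_init(fit0$params, g1))
  ## the raw (unfloored) difference is kept for the bootstrap comparison:
  ## near-zero optimization noise is symmetric between observed and
  ## bootstrap fits, and flooring both sides would create artificial ties
  ## at exactly zero that distort the p-value
  observed_raw <- 2 * (fit1$loglik - fit0$loglik)
  observed <- suppressWarnings(lrt_statistic(fit0, fit1))
  boots <- numeric(B)
  n_failed <- 0L
  b <- 1L; attempts <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 2L * B) stop("too many bootstrap fitting failures")
    sim <- if (glm) {
      d <- sample_mixture_glm(n, fit0$params,
                              x_sampler = function(m) obs$x)  # fixed design
      list(y = d$y, delta = d$delta, x = d$x, T = fit0$params$T)
    } else {
      d <- sample_mixture(n, fit0$params)
      list(y = d$y, delta = d$delta, x = rep(NA_real_, n), T = fit0$params$T)
    }
    res <- try({
      b0 <- fitter(sim, g0, config)
      b1 <- fitter(sim, g1, config, init = split_init(b0$params, g1))
      2 * (b1$loglik - b0$loglik)
    }, silent = TRUE)
    if (inherits(res, "try-error")) { n_failed <- n_failed + 1L; next }
    boots[b] <- res
    b <- b + 1L
  }
  p <- (1 + sum(boots >= observed_raw)) / (B + 1)
  boots <- pmax(boots, 0)
  structure(list(g0 = g0, g1 = g1, observed_lrt = observed,
                 bootstrap_lrts = boots, p_value = p,
                 fit0 = fit0, fit1 = fit1, n_failed = n_failed),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Bootstrap LRT: g = %d vs g = %d\n", x$g0, x$g1))
  cat(sprintf("  observed LRT = %.4f, B = %d, p = %.4g\n",
              x$observed_lrt, length(x$bootstrap_lrts), x$p_value))
  invisible(x)
}
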