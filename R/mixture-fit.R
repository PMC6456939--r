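#' EM estimation for censored-geometric mixtures
#'
#' Maximum-likelihood fitting of the plain mixture (component success
#' probabilities free) and of the covariate-adjusted mixture GLM (shared
#' slope, per-component intercepts) by the EM algorithm. The E-step
#' computes responsibilities; the M-step updates proportions in closed form
#' and, for the GLM, updates the coefficient vector by damped
#' Newton-Raphson on the responsibility-weighted log-likelihood.
#'
#' @name mixture-fit
#' @keywords internal
NULL

#' EM fitting configuration
#'
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the relative change of the observed-
#'   data log-likelihood between EM iterations.
#' @param n_restarts number of jittered re-initializations; the fit with the
#'   best final log-likelihood is returned.
#' @param rng_seed optional seed controlling initialization jitter.
#' @param fixed_beta1 optional value at which the shared covariate slope is
#'   frozen during GLM fitting (pseudo-maximum-likelihood mode, used to
#'   carry a GC effect estimated on a normal sample into the tumor-sample
#'   fit).
#' @param newton_max_iter,newton_tol inner Newton loop control for the GLM
#'   M-step.
#' @return a \code{fit_config} list.
#' @export
fit_config <- function(max_iter = 500L, tol = 1e-8, n_restarts = 5L,
                       rng_seed = NULL, fixed_beta1 = NULL,
                       newton_max_iter = 25L, newton_tol = 1e-10) {
  stopifnot(tol > 0, max_iter >= 1L, n_restarts >= 1L)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), rng_seed = rng_seed,
                 fixed_beta1 = fixed_beta1,
                 newton_max_iter = as.integer(newton_max_iter),
                 newton_tol = newton_tol),
            class = "fit_config")
}

# Coerce distance_series / data.frame / list to a plain list(y, delta, x, T).
as_observation_data <- function(data, T = NULL) {
  if (inherits(data, "distance_series")) {
    out <- list(y = data$y, delta = data$delta, x = data$x, T = attr(data, "T"))
  } else {
    Tdat <- if (!is.null(data$T)) data$T else attr(data, "T")
    out <- list(y = as.numeric(data$y),
                delta = if (is.null(data$delta)) rep(1L, length(data$y)) else as.integer(data$delta),
                x = if (is.null(data$x)) rep(NA_real_, length(data$y)) else as.numeric(data$x),
                T = if (is.null(Tdat)) NA_real_ else as.numeric(Tdat))
  }
  if (!is.null(T)) out$T <- as.numeric(T)
  if (any(out$delta == 0) && is.na(out$T))
    stop("data contain censored observations but no censoring constant 'T'")
  out
}

## ---- E-step -------------------------------------------------------------

#' E-step: posterior component responsibilities
#'
#' \eqn{\tau_{ij} = \pi_j f_j(y_i; x_i) / \sum_h \pi_h f_h(y_i; x_i)},
#' computed in log space.
#'
#' @param data a \code{distance_series}, or a list/data.frame with \code{y},
#'   \code{delta} and (for GLM parameters) \code{x}; the censoring constant
#'   is taken from the parameters.
#' @param params \code{mixture_params} or \code{glm_mixture_params}.
#' @return list with \code{tau} (n x g matrix, rows summing to 1) and
#'   \code{loglik} (observed-data log-likelihood).
#' @export
e_step <- function(data, params) {
  obs <- as_observation_data(data, T = params$T)
  lm <- if (inherits(params, "glm_mixture_params"))
    component_loglik_matrix_glm(obs$y, obs$delta, obs$x, params)
  else component_loglik_matrix(obs$y, obs$delta, params)
  lm <- sweep(lm, 2L, log(params$pi), `+`)
  lse <- logsumexp_rows(lm)
  list(tau = exp(lm - lse), loglik = sum(lse))
}

## ---- M-step pieces ------------------------------------------------------

#' M-step update of the component proportions
#'
#' @param tau n x g responsibility matrix.
#' @return \eqn{\pi_j = \sum_i \tau_{ij} / n}.
#' @export
m_step_proportions <- function(tau) {
  colMeans(tau)
}

#' M-step update of the success probabilities (plain mixture)
#'
#' Closed-form maximizer of the responsibility-weighted complete-data
#' log-likelihood:
#' \deqn{\hat p_j = \frac{\sum_i \tau_{ij}\delta_i}
#'   {\sum_i \tau_{ij}[\delta_i(1+y_i) + (1-\delta_i)(T+1)]}.}
#'
#' @param data observations (see \code{\link{e_step}}).
#' @param tau responsibility matrix.
#' @param T censoring constant (NA if no censored entries).
#' @return vector of updated success probabilities, clamped to
#'   \code{[1e-12, 1 - 1e-12]}.
#' @export
m_step_p_plain <- function(data, tau, T = NA_real_) {
  obs <- as_observation_data(data, T = T)
  num <- colSums(tau * obs$delta)
  if (any(num <= 0))
    stop("component collapse: a component has zero uncensored weight; ",
         "reduce the number of components")
  w <- obs$delta * (1 + obs$y) + (1 - obs$delta) * (obs$T + 1)
  if (is.na(obs$T)) w <- 1 + obs$y        # fully observed
  den <- colSums(tau * w)
  pmin(pmax(num / den, 1e-12), 1 - 1e-12)
}

## ---- GLM M-step: score, information, Newton ----------------------------

# Per-observation building blocks shared by score/information/objective.
# a_i = delta*y + (1-delta)(T+1); b_i = a_i + delta. The component log
# density in the log-mean link eta is  a*eta - b*log(1+exp(eta)), whose
# derivative in eta is a - b*(1-p) and second derivative -b*p*(1-p).
glm_ab <- function(obs) {
  Tpl1 <- if (is.na(obs$T)) 0 else obs$T + 1   # unused when all delta == 1
  a <- obs$delta * obs$y + (1 - obs$delta) * Tpl1
  list(a = a, b = a + obs$delta)
}

#' Score of the weighted GLM-mixture objective
#'
#' Gradient of \eqn{Q(\beta) = \sum_{ij} \tau_{ij} \log f_j(y_i; x_i)}
#' with respect to \eqn{\beta = (\beta_{10},...,\beta_{g0},\beta_1)}.
#' Exposed for verification against numerical differentiation.
#'
#' @param data observations with covariate \code{x}.
#' @param tau responsibility matrix (n x g).
#' @param beta0 intercept vector, \code{beta1} slope scalar.
#' @param T censoring constant.
#' @return numeric vector of length g + 1.
#' @export
glm_mixture_score <- function(data, tau, beta0, beta1, T = NA_real_) {
  obs <- as_observation_data(data, T = T)
  ab <- glm_ab(obs)
  eta <- outer(beta1 * obs$x, beta0, `+`)
  q <- 1 / (1 + exp(-eta))                 # 1 - p = mu/(1+mu)
  s <- tau * (ab$a - ab$b * q)             # d/d eta, weighted
  c(colSums(s), sum(rowSums(s) * obs$x))
}

#' Weighted GLM-mixture objective
#'
#' \eqn{Q(\beta) = \sum_{ij} \tau_{ij} \log f_j(y_i; x_i)}, the quantity the
#' Newton M-step maximizes.
#' @inheritParams glm_mixture_score
#' @return scalar objective value.
#' @export
glm_mixture_objective <- function(data, tau, beta0, beta1, T = NA_real_) {
  obs <- as_observation_data(data, T = T)
  params <- structure(list(g = length(beta0), pi = rep(1 / length(beta0), length(beta0)),
                           beta0 = beta0, beta1 = beta1, T = obs$T),
                      class = "glm_mixture_params")
  lm <- component_loglik_matrix_glm(obs$y, obs$delta, obs$x, params)
  sum(tau * lm)
}

#' One damped Newton-Raphson step for the GLM-mixture coefficients
#'
#' Solves the weighted normal equations
#' \eqn{\beta_{new} = \beta + (X^T W X)^{-1} X^T s} where the stacked design
#' has one row per (observation, component) with an intercept indicator and
#' the covariate, \eqn{W = \tau b p (1-p)} and \eqn{s = \tau(a - b(1-p))}.
#' The Hessian of the censored-geometric objective in the log-mean link is
#' always negative semi-definite, so the step is ascent; step halving is
#' applied until the objective does not decrease. When \code{fixed_beta1}
#' is supplied the slope coordinate is frozen and only intercepts move.
#'
#' @inheritParams glm_mixture_score
#' @param fixed_beta1 optional frozen slope value.
#' @return list with updated \code{beta0}, \code{beta1}, the achieved
#'   \code{objective} and the step-halving count \code{halvings}.
#' @export
newton_raphson_beta <- function(data, tau, beta0, beta1, T = NA_real_,
                                fixed_beta1 = NULL) {
  obs <- as_observation_data(data, T = T)
  if (all(is.na(obs$x))) stop("GLM update requires a covariate column 'x'")
  if (!is.null(fixed_beta1)) beta1 <- fixed_beta1
  g <- length(beta0)
  ab <- glm_ab(obs)
  eta <- outer(beta1 * obs$x, beta0, `+`)
  q <- 1 / (1 + exp(-eta))                       # 1 - p
  smat <- tau * (ab$a - ab$b * q)                # per-cell score in eta
  wmat <- tau * (ab$b * q * (1 - q))             # per-cell curvature weight
  grad <- c(colSums(smat), sum(rowSums(smat) * obs$x))
  ## information matrix: diag intercept block, covariate cross terms
  info <- matrix(0, g + 1L, g + 1L)
  diag(info)[seq_len(g)] <- colSums(wmat)
  cross <- colSums(wmat * obs$x)
  info[g + 1L, seq_len(g)] <- cross
  info[seq_len(g), g + 1L] <- cross
  info[g + 1L, g + 1L] <- sum(rowSums(wmat) * obs$x^2)
  free <- if (is.null(fixed_beta1)) seq_len(g + 1L) else seq_len(g)
  step <- rep(0, g + 1L)
  sol <- tryCatch(solve(info[free, free, drop = FALSE], grad[free]),
                  error = function(e)
                    stop("singular information matrix in the GLM M-step; ",
                         "consider fewer components or rescaling the covariate"))
  step[free] <- sol
  f0 <- glm_mixture_objective(obs, tau, beta0, beta1, obs$T)
  lambda <- 1; halvings <- 0L
  repeat {
    cand <- c(beta0, beta1) + lambda * step
    f1 <- glm_mixture_objective(obs, tau, cand[seq_len(g)], cand[g + 1L], obs$T)
    if (is.finite(f1) && f1 >= f0 - 1e-12 * (abs(f0) + 1)) break
    lambda <- lambda / 2; halvings <- halvings + 1L
    if (halvings > 30L) { cand <- c(beta0, beta1); f1 <- f0; break }
  }
  list(beta0 = cand[seq_len(g)], beta1 = cand[g + 1L],
       objective = f1, halvings = halvings)
}

## ---- initialization -----------------------------------------------------

# Quantile-split initialization: order log(1+y), cut into g groups, use the
# per-group geometric MLE. Jittered multiplicatively across restarts.
init_plain <- function(obs, g, jitter = 0) {
  ly <- log1p(obs$y)
  qs <- stats::quantile(ly, probs = seq(0, 1, length.out = g + 1L))
  grp <- cut(ly, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  if (length(unique(grp)) < g) grp <- as.integer(cut(rank(ly, ties.method = "first"),
                                                     breaks = g, labels = FALSE))
  p <- vapply(seq_len(g), function(j) {
    yy <- obs$y[grp == j]
    if (length(yy) == 0L) return(stats::runif(1, 0.01, 0.5))
    1 / (1 + mean(yy))
  }, numeric(1))
  if (jitter > 0) p <- p * exp(stats::rnorm(g, 0, jitter))
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  pi <- tabulate(grp, g) / length(obs$y)
  pi <- pmax(pi, 1e-3); pi <- pi / sum(pi)
  list(pi = pi, p = sort(p, decreasing = TRUE))
}

## ---- plain mixture EM ---------------------------------------------------

#' Fit a censored-geometric mixture by EM
#'
#' Alternates the responsibility E-step with closed-form M-step updates of
#' the proportions and success probabilities, from several jittered
#' quantile-split initializations; the restart with the highest final
#' log-likelihood is returned with components in canonical order
#' (decreasing \code{p}).
#'
#' @param data a \code{distance_series} or list/data.frame with \code{y},
#'   \code{delta}; censoring constant taken from the series attribute or
#'   the \code{T} argument.
#' @param g number of mixture components.
#' @param config a \code{\link{fit_config}}.
#' @param T censoring constant override.
#' @param init optional extra initialization, a list with \code{pi} and
#'   \code{p} (e.g. a split-component start derived from a smaller fit,
#'   which makes nested log-likelihood orderings reliable); tried in
#'   addition to the quantile-split restarts.
#' @return object of class \code{"mixture_fit"}: list with \code{params}
#'   (a \code{\link{mixture_params}}), \code{tau}, \code{loglik},
#'   \code{loglik_trace}, \code{converged}, \code{n_iter}.
#' @export
fit_mixture <- function(data, g, config = fit_config(), T = NULL,
                        init = NULL) {
  obs <- as_observation_data(data, T = T)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (g == 1L && all(obs$delta == 1)) {
    ## closed-form MLE, no EM needed
    p <- min(max(1 / (1 + mean(obs$y)), 1e-12), 1 - 1e-12)
    params <- mixture_params(1, p, if (is.na(obs$T)) NA_real_ else obs$T)
    es <- e_step(obs, params)
    return(structure(list(params = params, tau = es$tau, loglik = es$loglik,
                          loglik_trace = es$loglik, converged = TRUE, n_iter = 1L),
                     class = "mixture_fit"))
  }
  best <- NULL
  starts <- lapply(seq_len(config$n_restarts), function(r)
    init_plain(obs, g, jitter = if (r == 1L) 0 else 0.4))
  if (!is.null(init)) starts <- c(list(init), starts)
  for (ini in starts) {
    fit <- try(em_plain(obs, ini$pi, ini$p, config), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed: ",
                          "data may be degenerate for g = ", g)
  best
}

# Initialization for a (g0+k)-component fit from a fitted g0 model: split
# the largest-proportion component into two, nudging p apart to break the
# symmetric fixed point. Keeps the start's likelihood within O(eps^2) of
# the smaller model's optimum, so EM lands at or above it.
split_init <- function(params, g_target) {
  pi <- params$pi
  if (inherits(params, "glm_mixture_params")) {
    beta0 <- params$beta0
    while (length(pi) < g_target) {
      j <- which.max(pi)
      pi <- c(pi[-j], pi[j] / 2, pi[j] / 2)
      beta0 <- c(beta0[-j], beta0[j] - 0.1, beta0[j] + 0.1)
    }
    list(pi = pi, beta0 = beta0, beta1 = params$beta1)
  } else {
    p <- params$p
    while (length(pi) < g_target) {
      j <- which.max(pi)
      pi <- c(pi[-j], pi[j] / 2, pi[j] / 2)
      p <- c(p[-j], min(p[j] * 1.1, 1 - 1e-12), p[j] / 1.1)
    }
    list(pi = pi, p = p)
  }
}

# Compiled EM core (src/em_plain.cpp); the reference R implementation
# em_plain_r below is retained and the two are cross-checked in the tests.
em_plain <- function(obs, pi, p, config) {
  n <- length(obs$y)
  Tval <- if (is.na(obs$T)) NA_real_ else obs$T
  res <- .em_plain_cpp(obs$y, obs$delta, Tval, pi, p,
                       config$max_iter, config$tol)
  ord <- order(res$p, decreasing = TRUE)
  params <- mixture_params(res$pi[ord] / sum(res$pi), res$p[ord], Tval)
  if (any(params$pi < 10 / n))
    warning("component proportion below 10/n: possible component collapse",
            call. = FALSE)
  es <- e_step(obs, params)   # responsibilities at the final parameters
  structure(list(params = params, tau = es$tau, loglik = es$loglik,
                 loglik_trace = res$trace,
                 converged = res$converged, n_iter = res$n_iter),
            class = "mixture_fit")
}

em_plain_r <- function(obs, pi, p, config) {
  n <- length(obs$y)
  Tval <- if (is.na(obs$T)) NA_real_ else obs$T
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    params <- structure(list(g = length(p), pi = pi, p = p, T = Tval),
                        class = "mixture_params")
    es <- e_step(obs, params)
    trace[it] <- es$loglik
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < config$tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    pi <- m_step_proportions(es$tau)
    pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
    p <- m_step_p_plain(obs, es$tau, Tval)
  }
  if (any(pi < 10 / n))
    warning("component proportion below 10/n: possible component collapse",
            call. = FALSE)
  ord <- order(p, decreasing = TRUE)
  params <- mixture_params(pi[ord] / sum(pi), p[ord], Tval)
  es <- e_step(obs, params)
  structure(list(params = params, tau = es$tau, loglik = es$loglik,
                 loglik_trace = trace, converged = converged, n_iter = it),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik = %.4f, %d EM iterations (%sconverged)\n",
              if (inherits(x$params, "glm_mixture_params")) "GLM mixture" else "Mixture",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT "))
  print(x$params)
  invisible(x)
}

## ---- GLM mixture EM -----------------------------------------------------

#' Fit the covariate-adjusted censored-geometric mixture by EM
#'
#' As \code{\link{fit_mixture}}, but each component's success probability
#' depends on the covariate through the shared-slope log-mean link. The
#' M-step runs the damped Newton update of
#' \code{\link{newton_raphson_beta}} to convergence. With
#' \code{config$fixed_beta1} set, the slope is held at that value
#' throughout (pseudo-maximum-likelihood estimation: the GC effect is a
#' property of the reference genome, so it can be estimated once on a
#' normal sample and frozen when fitting the matched tumor sample).
#'
#' @inheritParams fit_mixture
#' @param init optional extra initialization: list with \code{pi},
#'   \code{beta0}, \code{beta1}.
#' @return object of class \code{"mixture_fit"} whose \code{params} is a
#'   \code{\link{glm_mixture_params}}.
#' @export
fit_mixture_glm <- function(data, g, config = fit_config(), T = NULL,
                            init = NULL) {
  obs <- as_observation_data(data, T = T)
  if (all(is.na(obs$x))) stop("GLM fitting requires a covariate column 'x'")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  xbar <- mean(obs$x)
  best <- NULL
  starts <- lapply(seq_len(config$n_restarts), function(r) {
    ini <- init_plain(obs, g, jitter = if (r == 1L) 0 else 0.4)
    beta1 <- if (!is.null(config$fixed_beta1)) config$fixed_beta1 else 0
    ## convert group means to intercepts at the covariate mean
    list(pi = ini$pi, beta0 = log((1 - ini$p) / ini$p) - beta1 * xbar,
         beta1 = beta1)
  })
  if (!is.null(init)) starts <- c(list(init), starts)
  for (ini in starts) {
    fit <- try(em_glm(obs, ini$pi, ini$beta0, ini$beta1, config),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed: ",
                          "data may be degenerate for g = ", g)
  best
}

em_glm <- function(obs, pi, beta0, beta1, config) {
  n <- length(obs$y)
  Tval <- if (is.na(obs$T)) NA_real_ else obs$T
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    params <- structure(list(g = length(beta0), pi = pi, beta0 = beta0,
                             beta1 = beta1, T = Tval),
                        class = "glm_mixture_params")
    es <- e_step(obs, params)
    trace[it] <- es$loglik
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < config$tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    pi <- m_step_proportions(es$tau)
    pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
    ## inner Newton loop to (approximate) stationarity of Q(beta)
    obj_old <- -Inf
    for (k in seq_len(config$newton_max_iter)) {
      upd <- newton_raphson_beta(obs, es$tau, beta0, beta1, Tval,
                                 fixed_beta1 = config$fixed_beta1)
      beta0 <- upd$beta0; beta1 <- upd$beta1
      if (is.finite(obj_old) &&
          abs(upd$objective - obj_old) < config$newton_tol * (abs(obj_old) + 1))
        break
      obj_old <- upd$objective
    }
  }
  ord <- order(beta0)
  params <- glm_mixture_params(pi[ord] / sum(pi), beta0[ord], beta1, Tval)
  es <- e_step(obs, params)
  structure(list(params = params, tau = es$tau, loglik = es$loglik,
                 loglik_trace = trace, converged = converged, n_iter = it),
            class = "mixture_fit")
}
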