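# EM machinery: E-step, M-step updates, Newton-Raphson, full fits.

test_that("E-step responsibilities follow the posterior formula", {
  # single component: all responsibilities are one
  d <- sample_mixture(50, mixture_params(1, 0.1), rng_seed = 2)
  es <- e_step(d, mixture_params(1, 0.1))
  expect_equal(es$tau, matrix(1, 50, 1))

  # two identical components: responsibilities equal the proportions
  twin <- mixture_params(c(0.3, 0.7), c(0.1, 0.1 + 1e-15))
  es <- e_step(list(y = c(0, 5, 40), delta = c(1, 1, 1)), twin)
  for (i in 1:3) expect_equal(es$tau[i, ], twin$pi, tolerance = 1e-9)

  # a value typical of the diffuse component, far in the tail of the tight
  # one, is assigned to the diffuse component
  mp <- mixture_params(c(0.5, 0.5), c(0.5, 0.001))
  es <- e_step(list(y = 2000, delta = 1), mp)
  expect_gt(es$tau[1, 2], 1 - 1e-6)

  # rows always sum to one, and loglik matches mixture_loglik
  set.seed(31)
  d <- sample_mixture(500, scenario1_plain(T = 1000), rng_seed = 31)
  es <- e_step(d, scenario1_plain(T = 1000))
  expect_equal(rowSums(es$tau), rep(1, 500), tolerance = 1e-10)
  expect_equal(es$loglik,
               sum(mixture_loglik(d$y, d$delta, scenario1_plain(T = 1000))))
})

test_that("proportion M-step is the responsibility column mean", {
  expect_equal(m_step_proportions(matrix(1, 10, 1)), 1)
  expect_equal(m_step_proportions(matrix(0.5, 8, 2)), c(0.5, 0.5))
  set.seed(4)
  tau <- matrix(runif(60), 20); tau <- tau / rowSums(tau)
  expect_equal(m_step_proportions(tau), apply(tau, 2, mean))
  expect_equal(sum(m_step_proportions(tau)), 1)
})

test_that("p M-step maximizes the weighted censored-geometric likelihood", {
  # g = 1, no censoring: textbook geometric MLE
  y <- c(0, 2, 5, 9, 1)
  p <- m_step_p_plain(list(y = y, delta = rep(1, 5)), matrix(1, 5, 1))
  expect_equal(p, 1 / (1 + mean(y)))

  # all censored: no uncensored weight, rejected as degenerate
  expect_error(
    m_step_p_plain(list(y = rep(99, 4), delta = rep(0, 4), T = 10),
                   matrix(1, 4, 1), T = 10),
    "collapse")

  # oracle: matches 1-D numerical maximization under random weights
  set.seed(12)
  d <- sample_mixture(80, mixture_params(c(0.5, 0.5), c(0.3, 0.01), T = 100),
                      rng_seed = 12)
  tau <- matrix(runif(160), 80); tau <- tau / rowSums(tau)
  phat <- m_step_p_plain(d, tau, T = 100)
  for (j in 1:2) {
    obj <- function(p) sum(tau[, j] * loglik_single(d$y, d$delta, p, T = 100))
    opt <- optimize(obj, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-10)
    expect_equal(phat[j], opt$maximum, tolerance = 1e-6)
    # stationarity: derivative of the weighted objective is zero
    h <- 1e-7
    expect_lt(abs(obj(phat[j] + h) - obj(phat[j] - h)) / (2 * h), 1e-2)
  }
})

test_that("analytic GLM score matches central finite differences", {
  set.seed(55)
  d <- sample_mixture_glm(150, scenario1_glm(T = 570), rng_seed = 55)
  tau <- matrix(runif(450), 150); tau <- tau / rowSums(tau)
  for (rep in 1:5) {
    beta0 <- rnorm(3, 3, 2); beta1 <- rnorm(1, 0, 1)
    sc <- glm_mixture_score(d, tau, beta0, beta1, T = 570)
    h <- 1e-5
    num <- vapply(1:4, function(k) {
      bp <- c(beta0, beta1); bm <- bp
      bp[k] <- bp[k] + h; bm[k] <- bm[k] - h
      (glm_mixture_objective(d, tau, bp[1:3], bp[4], T = 570) -
         glm_mixture_objective(d, tau, bm[1:3], bm[4], T = 570)) / (2 * h)
    }, numeric(1))
    expect_equal(sc, num, tolerance = 1e-6)
  }
})

test_that("Newton step is ascent, honours fixed slope, solves g=1 exactly", {
  set.seed(77)
  d <- sample_mixture_glm(300, scenario1_glm(T = 570), rng_seed = 77)
  tau <- matrix(runif(900), 300); tau <- tau / rowSums(tau)
  beta0 <- c(5, 3, 1); beta1 <- 0.5
  f0 <- glm_mixture_objective(d, tau, beta0, beta1, T = 570)
  upd <- newton_raphson_beta(d, tau, beta0, beta1, T = 570)
  expect_gte(upd$objective, f0 - 1e-9)

  fixed <- newton_raphson_beta(d, tau, beta0, beta1, T = 570, fixed_beta1 = 0.5)
  expect_equal(fixed$beta1, 0.5)

  # g = 1, slope fixed at 0, no censoring: fixed point at beta0 = log(ybar)
  y <- rgeom(2000, 1 / (1 + exp(2.5)))
  dat <- list(y = y, delta = rep(1, 2000), x = runif(2000))
  b <- 0
  for (i in 1:50)
    b <- newton_raphson_beta(dat, matrix(1, 2000, 1), b, 0, fixed_beta1 = 0)$beta0
  expect_equal(b, log(mean(y)), tolerance = 1e-8)
})

test_that("plain EM recovers well-separated parameters and is monotone", {
  d <- sample_mixture(5000, scenario1_plain(), rng_seed = 99)
  fit <- fit_mixture(d, 3, fit_config(n_restarts = 2, rng_seed = 1))
  expect_true(all(abs(fit$params$pi - c(0.2, 0.5, 0.3)) < 0.05))
  expect_equal(fit$params$p, c(0.2, 0.02, 0.002), tolerance = 0.25)
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))

  # g = 1 equals the closed-form MLE
  f1 <- fit_mixture(d, 1)
  expect_equal(f1$params$p, 1 / (1 + mean(d$y)))
  # nesting: more components never fit worse
  f2 <- fit_mixture(d, 2, fit_config(n_restarts = 2, rng_seed = 2))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_gte(fit$loglik, f2$loglik - 1e-6)
})

test_that("compiled EM core agrees with the reference R implementation", {
  for (Tval in c(NA_real_, 300)) {
    d <- sample_mixture(400, scenario1_plain(T = Tval), rng_seed = 140)
    obs <- list(y = d$y, delta = d$delta, x = rep(NA_real_, 400), T = Tval)
    ini <- cnvdist:::init_plain(obs, 3)
    cfg <- fit_config(n_restarts = 1, tol = 1e-9)
    fc <- cnvdist:::em_plain(obs, ini$pi, ini$p, cfg)
    fr <- cnvdist:::em_plain_r(obs, ini$pi, ini$p, cfg)
    expect_equal(fc$loglik, fr$loglik, tolerance = 1e-8)
    expect_equal(fc$params$p, fr$params$p, tolerance = 1e-6)
    expect_equal(fc$params$pi, fr$params$pi, tolerance = 1e-6)
  }
})

test_that("plain EM handles censored data", {
  d <- sample_mixture(4000, scenario1_plain(T = 1000), rng_seed = 17)
  expect_gt(sum(d$delta == 0), 0)
  fit <- fit_mixture(d, 3, fit_config(n_restarts = 2, rng_seed = 3))
  expect_equal(fit$params$p, c(0.2, 0.02, 0.002), tolerance = 0.3)
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))
})

test_that("GLM EM recovers the shared slope and intercepts", {
  d <- sample_mixture_glm(10000, scenario1_glm(T = 570), rng_seed = 21)
  fit <- fit_mixture_glm(d, 3, fit_config(n_restarts = 1, rng_seed = 4))
  expect_true(fit$converged)
  expect_equal(fit$params$beta0, c(1.1, 3.6, 6.0), tolerance = 0.2)
  expect_equal(fit$params$beta1, 2.0, tolerance = 0.5)
  expect_true(all(abs(fit$params$pi - c(0.2, 0.5, 0.3)) < 0.05))
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))

  # pseudo-ML: slope frozen at the supplied value throughout
  fixed <- fit_mixture_glm(d, 3, fit_config(n_restarts = 1, rng_seed = 4,
                                            fixed_beta1 = 2.0))
  expect_equal(fixed$params$beta1, 2.0)
  expect_equal(fixed$params$beta0, c(1.1, 3.6, 6.0), tolerance = 0.2)
})

test_that("constant covariate reduces the GLM fit to the plain mixture", {
  set.seed(61)
  mp <- mixture_params(c(0.4, 0.6), c(0.1, 0.01))
  d <- sample_mixture(3000, mp, rng_seed = 61)
  dglm <- list(y = d$y, delta = d$delta, x = rep(0.5, 3000))
  fp <- fit_mixture(d, 2, fit_config(n_restarts = 1, rng_seed = 5))
  # a constant covariate is collinear with the intercepts; fix the slope
  fg <- fit_mixture_glm(dglm, 2, fit_config(n_restarts = 1, rng_seed = 5,
                                            fixed_beta1 = 0))
  expect_equal(fg$loglik, fp$loglik, tolerance = 1e-6)
  p_implied <- 1 / (1 + exp(fg$params$beta0))
  expect_equal(sort(p_implied, decreasing = TRUE), fp$params$p,
               tolerance = 1e-3)
})
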