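# Distribution primitives: censored-geometric pmf/CDF, mixtures, samplers.

test_that("single-observation log-likelihood matches the censored geometric", {
  expect_equal(loglik_single(0, 1, 0.5), log(0.5))
  expect_equal(loglik_single(0, 0, 0.5, T = 1), log(0.25))
  # observed branch equals dgeom
  expect_equal(loglik_single(7, 1, 0.13), dgeom(7, 0.13, log = TRUE))
  expect_error(loglik_single(1, 1, 1.2), "p")
  expect_error(loglik_single(1, 0, 0.5), "T")
})

test_that("total mass is one over {0..T} plus the censored state", {
  for (case in list(c(p = 0.3, T = 7), c(p = 0.002, T = 5000),
                    c(p = 0.97, T = 3))) {
    total <- sum(exp(loglik_single(0:case[["T"]], 1, case[["p"]], case[["T"]]))) +
      exp(loglik_single(0, 0, case[["p"]], case[["T"]]))
    expect_equal(total, 1, tolerance = 1e-10)
  }
  mp <- mixture_params(c(0.3, 0.7), c(0.1, 0.4), T = 10)
  total <- sum(exp(mixture_loglik(0:10, 1, mp))) + exp(mixture_loglik(0, 0, mp))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("geometric CDF is consistent with the pmf", {
  expect_equal(cdf_single(0, 0.5), 0.5)
  expect_equal(cdf_single(5000, 0.01), 1, tolerance = 1e-10)
  expect_equal(cdf_single(-1, 0.3), 0)
  y <- 1:50
  expect_equal(cdf_single(y, 0.2) - cdf_single(y - 1, 0.2),
               0.2 * 0.8^y)
})

test_that("mixture log-likelihood degenerates correctly", {
  y <- c(0, 3, 50); delta <- c(1, 1, 1)
  g1 <- mixture_params(1, 0.07)
  expect_equal(mixture_loglik(y, delta, g1), loglik_single(y, delta, 0.07))
  # two identical components behave as one
  twin <- mixture_params(c(0.5, 0.5), c(0.07, 0.07 + 1e-15))
  expect_equal(mixture_loglik(y, delta, twin), loglik_single(y, delta, 0.07),
               tolerance = 1e-12)
})

test_that("canonical component order is p decreasing", {
  mp <- mixture_params(c(0.2, 0.5, 0.3), c(0.02, 0.2, 0.002))
  expect_equal(mp$p, c(0.2, 0.02, 0.002))
  expect_equal(mp$pi, c(0.5, 0.2, 0.3))
  gp <- glm_mixture_params(c(0.2, 0.8), c(5, 2), 1.5)
  expect_equal(gp$beta0, c(2, 5))
  expect_equal(gp$pi, c(0.8, 0.2))
})

test_that("GLM mixture CDF reduces, bounds and increases as it should", {
  # g = 1, slope 0: equals the single geometric CDF with p = 1/(1+e^b0)
  gp1 <- glm_mixture_params(1, 1.2, 0)
  p <- 1 / (1 + exp(1.2))
  y <- 0:60
  expect_equal(mixture_cdf_glm(y, 0.7, gp1), cdf_single(y, p))
  expect_equal(mixture_cdf_glm(-1, 0.5, gp1), 0)

  # strictly increasing in y at fixed x for an application-style model
  gp <- application_glm()
  Fv <- mixture_cdf_glm(0:100, 0.45, gp)
  expect_true(all(diff(Fv) > 0))

  # oracle: CDF equals the brute-force pmf partial sums
  pj <- glm_component_p(gp, 0.45)[1, ]
  pmf <- colSums(gp$pi * sapply(0:200, function(k) pj * (1 - pj)^k))
  expect_equal(mixture_cdf_glm(0:200, 0.45, gp), cumsum(pmf), tolerance = 1e-12)
})

test_that("mixture sampler matches its own distribution", {
  mp <- mixture_params(c(0.3, 0.5, 0.2), c(0.2, 0.02, 0.002), T = 1000)
  d <- sample_mixture(10000, mp, rng_seed = 5)
  # component frequencies within 3 binomial SE
  freq <- tabulate(d$component, 3) / nrow(d)
  se <- sqrt(mp$pi * (1 - mp$pi) / nrow(d))
  expect_true(all(abs(freq - mp$pi) < 3 * se))
  # uncensored mean of the tightest component near (1-p)/p
  y1 <- d$y[d$component == 1 & d$delta == 1]
  expect_equal(mean(y1), (1 - 0.2) / 0.2, tolerance = 0.1)
  # censor flag honours T
  expect_equal(d$delta, as.integer(d$y <= 1000))
  # reproducible under seed
  d2 <- sample_mixture(10000, mp, rng_seed = 5)
  expect_identical(d, d2)
})

test_that("sampled histogram matches the pmf in total variation", {
  mp <- mixture_params(c(0.6, 0.4), c(0.3, 0.05))
  d <- sample_mixture(1e5, mp, rng_seed = 8)
  ymax <- 400
  emp <- tabulate(pmin(d$y, ymax) + 1L, ymax + 1L) / nrow(d)
  pmf <- 0.6 * dgeom(0:ymax, 0.3) + 0.4 * dgeom(0:ymax, 0.05)
  pmf[ymax + 1] <- pmf[ymax + 1] + (1 - sum(pmf))   # lump the tail
  expect_lt(0.5 * sum(abs(emp - pmf)), 0.01)
})

test_that("GLM sampler reduces to the plain sampler at slope zero", {
  gp <- glm_mixture_params(c(0.5, 0.5), c(4, 1.5), 0)
  d <- sample_mixture_glm(20000, gp, rng_seed = 13)
  p_implied <- 1 / (1 + exp(gp$beta0))   # canonical order
  for (j in 1:2) {
    yj <- d$y[d$component == j]
    expect_equal(mean(yj), (1 - p_implied[j]) / p_implied[j], tolerance = 0.1)
  }
})

test_that("parameters survive a JSON round trip", {
  path <- tempfile(fileext = ".json")
  mp <- mixture_params(c(0.25, 0.75), c(0.4, 0.001), T = 5000)
  write_params(mp, path)
  expect_equal(read_params(path), mp)
  gp <- glm_mixture_params(c(0.3, 0.7), c(5.5, 2.2), -4.4)
  write_params(gp, path)
  expect_equal(read_params(gp_path <- path) , gp)
})
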