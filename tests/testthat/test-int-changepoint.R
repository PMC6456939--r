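# Inverse normal transformation, binning, recursive combination.

test_that("model-CDF transform maps median mass to zero and censored to the sentinel", {
  gp <- application_glm(T = 5000)
  # find y with F(y; x) closest to 0.5 -> z near 0
  x <- 0.45
  Fv <- mixture_cdf_glm(0:5000, x, gp)
  y_med <- which.min(abs(Fv - 0.5)) - 1L
  d <- apply_censoring(make_series(c(y_med, 12, 7000), x = rep(x, 3)), 5000)
  z <- int_transform(d, gp)
  expect_equal(z$z[1], qnorm(Fv[y_med + 1L]))
  expect_lt(abs(z$z[1]), 0.05)
  expect_identical(z$z[3], 10)          # censored entry: exactly the sentinel
  expect_true(z$censored[3])

  # strictly increasing in y at fixed x
  d2 <- apply_censoring(make_series(0:200, x = rep(x, 201)), 5000)
  z2 <- int_transform(d2, gp)
  expect_true(all(diff(z2$z) > 0))

  # sentinel must dominate every finite z
  expect_error(int_transform(d2, gp, sentinel = -5), "sentinel")
})

test_that("rank-based transform is a labelled alternative", {
  d <- make_series(sample(0:1000, 101))
  z <- int_transform(d, rank_based = TRUE)
  expect_equal(sort(z$z), qnorm((1:101 - 3/8) / (101 + 1/4)), tolerance = 1e-12)
})

test_that("probability integral transform yields approximately N(0,1) z-values", {
  gp <- application_glm(T = 5000)
  # GC window chosen so censoring stays near 1%: the finite z are truncated
  # at the censor threshold, so the KS distance floors at the censored mass
  d <- sample_mixture_glm(1e5, gp,
                          x_sampler = function(n) runif(n, 0.45, 0.60),
                          rng_seed = 71)
  ds <- make_series(d$y, delta = d$delta, x = d$x, T = 5000)
  z <- int_transform(ds, gp)
  zf <- z$z[!z$censored]
  D <- suppressWarnings(ks.test(zf, pnorm))$statistic
  expect_lt(D, 0.02)
  expect_true(all(is.finite(zf)))
})

test_that("binning tiles the covered range with half-open windows", {
  # uniform anchors over 150 kb -> 3 bins of 50 kb
  zs <- structure(list(anchor_positions = seq(0, 149999, by = 1000),
                       z = rnorm(150), censored = rep(FALSE, 150)),
                  chromosome = "sim", sentinel = 10, class = "z_series")
  b <- bin_z(zs, 50000)
  expect_length(b$values, 3)
  expect_equal(b$start, c(0, 50000, 100000))
  # conservation: every value lands in exactly one bin
  expect_equal(sum(lengths(b$values)) + sum(b$n_censored), 150)
  # boundary membership: position 50000 goes to the second bin
  zs2 <- structure(list(anchor_positions = c(49999, 50000),
                        z = c(1, 2), censored = c(FALSE, FALSE)),
                   chromosome = "sim", sentinel = 10, class = "z_series")
  b2 <- bin_z(zs2, 50000)
  expect_equal(lengths(b2$values), c(1L, 1L))
  # censored sentinels counted but excluded from values
  zs3 <- structure(list(anchor_positions = c(10, 20, 30),
                        z = c(0.5, 10, -0.2), censored = c(FALSE, TRUE, FALSE)),
                   chromosome = "sim", sentinel = 10, class = "z_series")
  b3 <- bin_z(zs3, 50000)
  expect_equal(b3$n_censored, 1L)
  expect_equal(sort(b3$values[[1]]), c(-0.2, 0.5))
})

test_that("the per-comparison level follows the Bonferroni formula", {
  expect_equal(alpha_c(2), 0.05)
  expect_equal(alpha_c(767), 0.05 / 293761)
  expect_equal(alpha_c(772), 0.05 / 297606)
  expect_error(alpha_c(1), "m")
})

test_that("recursive combination merges null data and finds a strong step", {
  set.seed(5)
  # all bins from one normal distribution: a single block
  null_bins <- lapply(1:20, function(i) rnorm(25))
  seg <- recursive_combination(null_bins, alpha = alpha_c(20))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_bins, 20L)

  # -3 SD step at the midpoint: exactly one boundary at the true split
  step_bins <- c(lapply(1:10, function(i) rnorm(25, 0)),
                 lapply(1:10, function(i) rnorm(25, -3)))
  seg2 <- recursive_combination(step_bins, alpha = alpha_c(20))
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$end_bin[1], 11L)
  expect_equal(seg2$mean_z, c(0, -3), tolerance = 0.3)

  # single bin: one block, no tests
  seg3 <- recursive_combination(list(rnorm(10)))
  expect_equal(nrow(seg3), 1L)

  expect_error(recursive_combination(list()), "no bins")
})

test_that("final segmentation never contains a mergeable adjacent pair", {
  set.seed(9)
  for (rep in 1:5) {
    bins <- lapply(1:30, function(i) rnorm(15, mean = sample(c(0, 2), 1)))
    alpha <- alpha_c(30)
    seg <- recursive_combination(bins, alpha = alpha)
    if (nrow(seg) >= 2L) {
      # recompute block values and check each adjacent pair separates
      blocks <- lapply(seq_len(nrow(seg)), function(i)
        unlist(bins[seg$start_bin[i]:(seg$end_bin[i] - 1L)]))
      for (i in seq_len(nrow(seg) - 1L)) {
        p <- t.test(blocks[[i]], blocks[[i + 1L]], var.equal = TRUE)$p.value
        expect_lt(p, alpha)
      }
    }
    # blocks partition the bin range
    expect_equal(seg$start_bin[1], 1L)
    expect_equal(seg$end_bin[nrow(seg)], 31L)
    if (nrow(seg) >= 2L)
      expect_equal(seg$start_bin[-1], seg$end_bin[-nrow(seg)])
  }
})

test_that("segmentation is mirror-symmetric under bin reversal", {
  set.seed(13)
  bins <- c(lapply(1:8, function(i) rnorm(20, 0)),
            lapply(1:12, function(i) rnorm(20, 1.5)))
  seg_f <- recursive_combination(bins, alpha = 1e-4)
  seg_r <- recursive_combination(rev(lapply(bins, rev)), alpha = 1e-4)
  m <- 20L
  expect_equal(nrow(seg_f), nrow(seg_r))
  expect_equal(rev(m + 2L - seg_f$end_bin), seg_r$start_bin)
  expect_equal(rev(seg_f$mean_z), seg_r$mean_z)
})

test_that("qq_check samples regions, excludes sentinels, reproduces under seed", {
  set.seed(3)
  n <- 2000
  zs <- structure(list(anchor_positions = sort(runif(n, 0, 1e6)),
                       z = rnorm(n), censored = rep(FALSE, n)),
                  chromosome = "sim", sentinel = 10, class = "z_series")
  zs$censored[1:50] <- TRUE
  zs$z[1:50] <- 10
  qq <- qq_check(zs, region_length = 1e5, n_regions = 5, rng_seed = 2)
  expect_gt(length(qq), 0)
  for (q in qq) {
    expect_true(all(q$sample < 10))
    expect_equal(nrow(q), length(q$theoretical))
    # near-normal input stays near the diagonal in the bulk
    mid <- abs(q$theoretical) < 2
    expect_lt(max(abs(q$sample[mid] - q$theoretical[mid])), 1)
  }
  qq2 <- qq_check(zs, region_length = 1e5, n_regions = 5, rng_seed = 2)
  expect_identical(qq, qq2)
})
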