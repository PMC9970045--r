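# Wasserstein distances, the subset-size sweep, the power-law fit and the
# Pareto optimum.

test_that("wasserstein1 has the closed forms and metric properties", {
  edges <- seq(0, 8, length.out = 9)
  h1 <- hist_from_counts(c(3L, 1L, 4L, 1L, 5L, 9L, 2L, 6L), edges)
  expect_equal(wasserstein1(h1, h1), 0)
  # point mass at bin 2 vs bin 5, unit bin width: distance 3
  pa <- hist_from_counts(c(0L, 10L, 0L, 0L, 0L, 0L, 0L, 0L), edges)
  pb <- hist_from_counts(c(0L, 0L, 0L, 0L, 10L, 0L, 0L, 0L), edges)
  expect_equal(wasserstein1(pa, pb), 3)
  # metric on random instances: symmetry and triangle inequality
  withr::with_seed(8, {
    hs <- replicate(12, hist_from_counts(rpois(8, 4) + c(1L, rep(0L, 7)),
                                         edges), simplify = FALSE)
    for (k in 1:40) {
      ijk <- sample(12, 3)
      dij <- wasserstein1(hs[[ijk[1]]], hs[[ijk[2]]])
      dji <- wasserstein1(hs[[ijk[2]]], hs[[ijk[1]]])
      expect_identical(dij, dji)
      dik <- wasserstein1(hs[[ijk[1]]], hs[[ijk[3]]])
      dkj <- wasserstein1(hs[[ijk[3]]], hs[[ijk[2]]])
      expect_lte(dij, dik + dkj + 1e-12)
    }
  })
  z <- h1
  z$counts <- rep(0, 8)
  expect_error(wasserstein1(h1, z), "zero-mass")
})

test_that("wasserstein1 equals the optimal-transport cost", {
  edges <- seq(0, 4, length.out = 9)
  withr::with_seed(123, {
    for (k in 1:50) {
      ca <- rpois(8, 3) + c(1L, rep(0L, 7))
      cb <- rpois(8, 3) + c(0L, rep(0L, 6), 1L)
      ha <- hist_from_counts(ca, edges)
      hb <- hist_from_counts(cb, edges)
      expect_equal(wasserstein1(ha, hb),
                   nw_transport_cost(ha$raw_counts, hb$raw_counts, edges),
                   tolerance = 1e-9)
    }
  })
})

test_that("pair pools are symmetric with brute-force-verified means", {
  edges <- seq(0, 2, length.out = 5)
  withr::with_seed(4, {
    hs <- replicate(6, hist_from_counts(rpois(4, 5) + 1L, edges),
                    simplify = FALSE)
  })
  pool <- build_pair_pool(list(H = hs), ids = letters[1:6])
  d <- pool$dist$H
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # brute-force double loop
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    if (i != j) brute[i, j] <- wasserstein1(hs[[i]], hs[[j]])
  expect_equal(unname(d), brute)
  expect_equal(mean(d[upper.tri(d)]), mean(brute[upper.tri(brute)]))
  # two images: a single distinct off-diagonal value
  p2 <- build_pair_pool(list(H = hs[1:2]))
  expect_length(unique(p2$dist$H[upper.tri(p2$dist$H)]), 1L)
  # identical tiles give an all-zero pool
  p0 <- build_pair_pool(list(H = hs[c(1, 1, 1)]))
  expect_true(all(p0$dist$H == 0))
})

test_that("subset sweep obeys law-of-large-numbers and CLT scaling", {
  edges <- seq(0, 2, length.out = 9)
  withr::with_seed(10, {
    hs <- replicate(30, hist_from_counts(rpois(8, 4) + 1L, edges),
                    simplify = FALSE)
  })
  pool <- build_pair_pool(list(H = hs))
  sw <- subset_sweep(pool, s_max = 64L, n_perms = 1000L, seed = 3)
  sds <- sw$stains$H$sd_per_size
  expect_true(all(sds >= 0))
  expect_equal(dim(sw$stains$H$mean_per_perm), c(1000L, 64L))
  # determinism
  sw2 <- subset_sweep(pool, s_max = 64L, n_perms = 1000L, seed = 3)
  expect_identical(sw$stains, sw2$stains)
  # CLT: sd(n) * sqrt(n) constant within 15% over a dyadic ladder
  scaled <- sds[c(4, 16, 64)] * sqrt(c(4, 16, 64))
  expect_lt(diff(range(scaled)) / mean(scaled), 0.15)
  # law of large numbers: permutation means at n = 64 concentrate on the
  # pool mean within 3 pool standard errors
  dvec <- pool$dist$H[upper.tri(pool$dist$H)]
  mu <- mean(dvec)
  se64 <- sd(dvec) / sqrt(64)
  expect_lt(abs(mean(sw$stains$H$mean_per_perm[, 64]) - mu), 3 * se64)
  # degenerate pool: all pairwise distances equal -> zero SD everywhere
  pool0 <- build_pair_pool(list(H = hs[c(1, 2, 1, 2)]))
  d0 <- pool0$dist$H
  expect_length(unique(round(d0[upper.tri(d0)][d0[upper.tri(d0)] > 0], 12)),
                1L)
})

test_that("power-law fit recovers exact and noisy decay parameters", {
  n <- 1:100
  f <- fit_power_law(n, 4 * n^(-0.5))
  expect_equal(f$a_const, 4, tolerance = 1e-10)
  expect_equal(f$slope, -0.5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_warning(f0 <- fit_power_law(1:5, c(1, 0.7, 0, 0.5, 0.4)),
                 "excluded")
  expect_error(suppressWarnings(fit_power_law(1:3, c(1, 0, 0))), ">= 3")
})

test_that("pareto optima match summation and inversion oracles", {
  # constant curve: cumulative rule crosses 80% at k = 160 of 200
  pc <- pareto_optimal_size(rep(2, 200))
  expect_equal(pc$optimal_size, 160L)
  y <- (1:200)^(-0.5)
  p <- pareto_optimal_size(y, convention = "cumulative_80")
  # direct-summation oracle
  k_oracle <- which(cumsum(y) >= 0.8 * sum(y))[1]
  expect_equal(p$optimal_size, k_oracle)
  pr <- pareto_optimal_size(y, convention = "reduction_80")
  # closed-form inversion of n^(-1/2) <= 1 - 0.8 (1 - 200^(-1/2))
  thresh <- 1 - 0.8 * (1 - 200^(-0.5))
  expect_equal(pr$optimal_size, ceiling(thresh^(-2)))
  expect_equal(unname(p$optima["reduction_80"]), pr$optimal_size)
  # monotone non-decreasing in the fraction
  ks <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(fr)
    pareto_optimal_size(y, fraction = fr)$optimal_size, numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(pareto_optimal_size(c(1, -1)), "negative")
})

test_that("stain-curve correlation has the textbook closed forms", {
  y <- (1:50)^(-0.5)
  expect_equal(compare_stain_curves(y, y)$r, 1, tolerance = 1e-12)
  expect_equal(compare_stain_curves(y, -(y - mean(y)))$r, -1,
               tolerance = 1e-12)
  # formula oracle on noisy curves
  withr::with_seed(2, {
    a <- y + rnorm(50, sd = 0.01)
    b <- y + rnorm(50, sd = 0.01)
  })
  got <- compare_stain_curves(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(48 / (1 - r_direct^2))
  expect_equal(got$p_value, 2 * pt(abs(tstat), 48, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(compare_stain_curves(rep(1, 10), y[1:10]), "zero-variance")
})
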