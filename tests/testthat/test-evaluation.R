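# Levene's test, the convergence experiments and L* heatmaps.

test_that("levene_test matches the textbook formula and edge cases", {
  a <- c(1, 2, 3, 4)
  b <- c(10, 20, 30, 40)
  got <- levene_test(a, b, center = "mean")
  want <- levene_oracle(a, b, mean)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  # identical groups: W = 0, p = 1
  same <- levene_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # zero deviation in both groups
  z <- levene_test(c(2, 2, 2), c(5, 5))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(levene_test(1, c(1, 2)), ">= 2")
})

test_that("levene_test agrees with car::leveneTest on random instances", {
  skip_if_not_installed("car")
  withr::with_seed(77, {
    for (k in 1:100) {
      a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(5:30, 1), mean = 1, sd = runif(1, 0.5, 3))
      for (ctr in c("mean", "median")) {
        got <- levene_test(a, b, center = ctr)
        ref <- car::leveneTest(c(a, b),
                               factor(rep(1:2, c(length(a), length(b)))),
                               center = ctr)
        expect_equal(got$statistic, ref[1, "F value"], tolerance = 1e-10)
        expect_equal(got$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
      }
    }
  })
})

test_that("convergence experiment produces coherent per-size records", {
  co <- small_cohort()
  images <- cohort_images(co)
  rep <- convergence_experiment(images, subset_sizes = c(1L, 5L, 20L),
                                n_perms = 3L, seed = 2)
  # schema: one images x perms matrix per size
  expect_equal(names(rep$labic), c("1", "5", "20"))
  for (m in rep$labic) expect_equal(dim(m), c(20L, 3L))
  expect_equal(sum(vapply(rep$labic, ncol, integer(1))), 3L * 3L)
  expect_true(all(unlist(rep$labic) >= 0 & unlist(rep$labic) <= 100))
  # at full cohort size every permutation uses the same subset
  expect_equal(rep$range_per_size[["20"]], 0, tolerance = 1e-12)
  expect_equal(rep$labic[["20"]][, 1], rep$labic[["20"]][, 2])
  # single-image references vary across permutations
  expect_gt(rep$range_per_size[["1"]], 0)
  # the convergence signal: per-permutation SD spread shrinks as the
  # reference subset grows
  expect_lt(rep$range_per_size[["20"]], rep$range_per_size[["1"]])
  # Levene rows cover adjacent size pairs with valid p-values
  expect_equal(rep$levene_vs_next$size_a, c(1L, 5L))
  expect_true(all(rep$levene_vs_next$p_value >= 0 &
                    rep$levene_vs_next$p_value <= 1))
  expect_length(rep$failed, 0)
})

test_that("roi experiment reduces to the whole-tile experiment", {
  co <- small_cohort()[1:6]
  images <- cohort_images(co)
  full <- lapply(images, function(im)
    list(all = matrix(TRUE, nrow(im), ncol(im))))
  got <- roi_convergence_experiment(images, full,
                                    subset_sizes = c(1L, 4L),
                                    n_perms = 2L, seed = 9)
  plain <- convergence_experiment(images, subset_sizes = c(1L, 4L),
                                  n_perms = 2L, seed = 9)
  expect_named(got, "all")
  # whole-tile region mask intersects to the tissue mask: identical L*
  expect_equal(got$all$labic, plain$labic, tolerance = 1e-9)
})

test_that("roi experiment separates strata and skips absent regions", {
  # two-strata tiles: rows 1-16 lightly stained, rows 17-32 heavily
  w <- he_stain_matrix()
  images <- lapply(1:6, function(k) {
    h_lo <- sample_concentrations(16 * 32, c(2, 2), c(0.15, 0.10),
                                  seed = 100 + k)
    h_hi <- sample_concentrations(16 * 32, c(2, 2), c(0.8, 0.6),
                                  seed = 200 + k)
    h <- matrix(0, 2, 32 * 32)
    top <- as.vector(outer(1:16, 0:31 * 32, `+`))
    h[, top] <- h_lo
    h[, setdiff(1:(32 * 32), top)] <- h_hi
    render_tile(w, h, c(32L, 32L))
  })
  top_mask <- rbind(matrix(TRUE, 16, 32), matrix(FALSE, 16, 32))
  masks <- lapply(1:6, function(k) {
    m <- list(light = top_mask, dark = !top_mask)
    if (k == 6) m$dark <- NULL  # region absent from one image
    m
  })
  got <- roi_convergence_experiment(images, masks, subset_sizes = 2L,
                                    n_perms = 2L, seed = 1)
  expect_named(got, c("light", "dark"))
  light <- colMeans(got$light$labic[["2"]], na.rm = TRUE)
  dark <- colMeans(got$dark$labic[["2"]], na.rm = TRUE)
  # lightly stained stratum is brighter in L*
  expect_true(all(light > dark))
  # absent region: that image's cells are missing, and the skip is logged
  expect_true(all(is.na(got$dark$labic[["2"]][6, ])))
  expect_true(any(grepl("absent", got$dark$failed)))
})

test_that("labic heatmaps mirror the L* channel", {
  flat <- array(119, c(4, 4, 3))
  hm <- labic_heatmap(flat)
  expect_true(hm$constant)
  expect_equal(diff(range(hm$map)), 0)
  expect_true(all(hm$gray == 0))
  # white/black checkerboard: bimodal {0, 100}
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- 255
  img[2, 2, ] <- 255
  hm2 <- labic_heatmap(img)
  expect_equal(sort(unique(round(as.vector(hm2$map), 6))), c(0, 100))
  expect_equal(hm2$gray, hm2$map / 100, tolerance = 1e-9)
  # map equals the L* channel of the full conversion
  el <- small_cohort()[[4]]
  expect_equal(labic_heatmap(el$image)$map, rgb_to_lab(el$image)[, , 1])
})

test_that("convergence reports round-trip through JSON losslessly", {
  co <- small_cohort()[1:8]
  images <- cohort_images(co)
  rep <- convergence_experiment(images, subset_sizes = c(1L, 4L),
                                n_perms = 2L, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$subset_sizes, rep$subset_sizes)
  for (i in seq_along(rep$labic))
    expect_equal(unname(back$labic[[i]]), unname(rep$labic[[i]]),
                 tolerance = 0)
  expect_equal(unname(back$range_per_size), unname(rep$range_per_size),
               tolerance = 0)
  expect_equal(back$levene_vs_next$p_value, rep$levene_vs_next$p_value,
               tolerance = 0)
})
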