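# Subset-size convergence analysis: pairwise 1-D Wasserstein distances
# between per-image density histograms, a Monte Carlo sweep of subset sizes,
# the power-law fit of the standard-deviation decay (law of large numbers:
# SD of a mean of n i.i.d. pair distances decays as n^(-1/2)), and Pareto
# 80/20 selection of the optimal reference-cohort size.

#' 1-D Wasserstein distance between two histograms
#'
#' First Wasserstein (earth mover's) distance between the unit-mass
#' renormalized distributions: on the line it equals the integrated absolute
#' CDF difference, here `sum_k |CDF_A(k) - CDF_B(k)| * bin_width`. The
#' probability mass is taken from the raw bin occupancies when the
#' histogram carries them (the min-max scaling to C zeroes the
#' least-occupied bin and is a representation, not a distribution);
#' aggregate histograms use their scaled counts.
#'
#' @param hist_a,hist_b `density_histogram`s on identical edges, each with
#'   nonzero total mass.
#' @return Nonnegative distance in density units.
#' @export
wasserstein1 <- function(hist_a, hist_b) {
  check_hist_compatible(list(hist_a, hist_b))
  if (sum(hist_a$counts) <= 0 || sum(hist_b$counts) <= 0)
    stop_stainref("data", "zero-mass histogram")
  width <- hist_a$edges[2] - hist_a$edges[1]
  sum(abs(cumsum(hist_mass(hist_a)) - cumsum(hist_mass(hist_b)))) * width
}

#' All pairwise Wasserstein distances of a cohort
#'
#' Computes, once per stain, the symmetric matrix of 1-D Wasserstein
#' distances between every unordered image pair. The pool is the empirical
#' distribution of the random pair distance D whose expectation the
#' subset-sweep means converge to.
#'
#' @param hists named list per stain (`H`, `E`) of per-image
#'   `density_histogram`s on shared edges.
#' @param ids image identifiers (default names of the first stain's list).
#' @return A list of class `pair_pool`: `image_ids`, `dist` (named list of
#'   symmetric zero-diagonal matrices).
#' @export
build_pair_pool <- function(hists, ids = NULL) {
  n <- length(hists[[1]])
  if (n < 2L) stop_stainref("schema", "need >= 2 images")
  if (is.null(ids)) ids <- names(hists[[1]]) %||% sprintf("img%04d", seq_len(n))
  dist <- lapply(hists, function(per_image) {
    check_hist_compatible(per_image)
    width <- per_image[[1]]$edges[2] - per_image[[1]]$edges[1]
    cdfs <- vapply(seq_along(per_image), function(i) {
      h <- per_image[[i]]
      if (sum(h$counts) <= 0)
        stop_stainref("data", "zero-mass histogram for image %s", ids[i])
      cumsum(hist_mass(h))
    }, numeric(length(per_image[[1]]$counts)))
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      d[i, rest] <- colSums(abs(cdfs[, rest, drop = FALSE] - cdfs[, i])) * width
      d[rest, i] <- d[i, rest]
    }
    d
  })
  structure(list(image_ids = ids, dist = dist), class = "pair_pool")
}

#' Monte Carlo sweep of reference-subset sizes
#'
#' For each subset size n in `1..s_max` and each of `n_perms` permutations,
#' draws n image pairs uniformly at random with replacement (pairs are
#' unordered pairs of distinct images; images may recur across pairs) and
#' records the mean of their pooled Wasserstein distances. The per-size
#' standard deviation of those permutation means is the quantity whose
#' decay is fitted by [fit_power_law()].
#'
#' @param pool a [build_pair_pool()] result.
#' @param s_max largest subset size (number of pairs).
#' @param n_perms permutations per size (>= 2).
#' @param seed integer seed; the sweep is deterministic given the seed.
#' @return A list of class `subset_sweep` with, per stain: `mean_per_perm`
#'   (`n_perms` x `s_max` matrix of permutation means) and `sd_per_size`
#'   (length `s_max`, sample SD with the n-1 denominator). Plus `sizes`,
#'   `n_perms`, `seed`.
#' @export
subset_sweep <- function(pool, s_max = 200L, n_perms = 1000L, seed = 1L) {
  stopifnot(inherits(pool, "pair_pool"))
  if (s_max < 1L || n_perms < 2L)
    stop_stainref("schema", "s_max >= 1 and n_perms >= 2 required")
  sizes <- seq_len(s_max)
  per_stain <- withr::with_seed(seed, lapply(pool$dist, function(d) {
    dv <- d[upper.tri(d)]
    means <- matrix(NA_real_, n_perms, s_max)
    for (n in sizes) {
      draws <- matrix(dv[sample.int(length(dv), n * n_perms, replace = TRUE)],
                      n, n_perms)
      means[, n] <- colMeans(draws)
    }
    list(mean_per_perm = means, sd_per_size = apply(means, 2, sd))
  }))
  structure(list(stains = per_stain, sizes = sizes, n_perms = n_perms,
                 seed = seed), class = "subset_sweep")
}

#' Fit a power law to the SD-decay curve
#'
#' Ordinary least squares of `ln(SD)` on `ln(size)`. The model is
#' `SD(n) = A * n^slope`; under the central limit theorem the SD of a mean
#' of n i.i.d. pair distances is `sigma / sqrt(n)`, so the expected slope
#' is -1/2 and `A` estimates the pool SD.
#'
#' @param sizes subset sizes.
#' @param sds per-size standard deviations; zero entries are excluded with
#'   a warning, and at least 3 positive points must remain.
#' @return A list of class `power_law_fit`: `a_const` (A, exp of the
#'   intercept), `slope` (log-log slope, expected -0.5), `r_squared`.
#' @export
fit_power_law <- function(sizes, sds) {
  keep <- sds > 0
  if (any(!keep))
    warning(sprintf("%d zero-SD sizes excluded from power-law fit",
                    sum(!keep)))
  if (sum(keep) < 3L)
    stop_stainref("data", "need >= 3 sizes with positive SD")
  fit <- lm(log(sds[keep]) ~ log(sizes[keep]))
  y <- log(sds[keep])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(a_const = unname(exp(coef(fit)[1])),
                 slope = unname(coef(fit)[2]),
                 r_squared = r2),
            class = "power_law_fit")
}

#' Pareto 80/20 optimal subset size
#'
#' Two conventions are computed; `optimal_size` is taken from the requested
#' one:
#' \describe{
#'   \item{`cumulative_80`}{Pareto-chart rule (the spreadsheet-style
#'     cumulative analysis): the smallest k whose cumulative SD mass reaches
#'     `fraction` of the total, `sum_{n<=k} SD(n) >= fraction * sum_n SD(n)`.}
#'   \item{`reduction_80`}{the smallest k at which the SD has dropped by
#'     `fraction` of the maximum reduction observed at the largest size:
#'     `SD(k) <= SD(1) - fraction * (SD(1) - SD(s_max))`.}
#' }
#'
#' @param sds per-size SDs ordered by size (noise-induced non-monotonicity
#'   is permitted; negative values are an error).
#' @param fraction Pareto fraction in (0, 1), default 0.8.
#' @param convention `"cumulative_80"` (default) or `"reduction_80"`.
#' @param sizes subset sizes (default `seq_along(sds)`).
#' @return A list of class `pareto_result`: `optimal_size`, `convention`,
#'   `optima` (both conventions), `cumulative_curve`.
#' @export
pareto_optimal_size <- function(sds, fraction = 0.8,
                                convention = c("cumulative_80",
                                               "reduction_80"),
                                sizes = seq_along(sds)) {
  convention <- match.arg(convention)
  if (any(sds < 0)) stop_stainref("data", "negative SDs")
  if (fraction <= 0 || fraction >= 1)
    stop_stainref("schema", "fraction must be in (0, 1)")
  cum <- cumsum(sds) / sum(sds)
  k_cum <- sizes[which(cum >= fraction - 1e-12)[1]]
  target <- sds[1] - fraction * (sds[1] - sds[length(sds)])
  hit <- which(sds <= target + 1e-12)
  k_red <- if (length(hit)) sizes[hit[1]] else sizes[length(sizes)]
  structure(list(
    optimal_size = if (convention == "cumulative_80") k_cum else k_red,
    convention = convention,
    optima = c(cumulative_80 = k_cum, reduction_80 = k_red),
    cumulative_curve = cum, fraction = fraction
  ), class = "pareto_result")
}

#' Pearson correlation between the two stain SD curves
#'
#' Product-moment correlation with the two-tailed p-value from the
#' t-distribution on `length - 2` degrees of freedom, quantifying the
#' similarity of the Hematoxylin and Eosin decay curves.
#'
#' @param sds_h,sds_e equal-length (>= 3) SD curves.
#' @return A list with `r` and `p_value`.
#' @export
compare_stain_curves <- function(sds_h, sds_e) {
  if (length(sds_h) != length(sds_e) || length(sds_h) < 3L)
    stop_stainref("schema", "curves must have equal length >= 3")
  if (var(sds_h) == 0 || var(sds_e) == 0)
    stop_stainref("data", "zero-variance curve")
  ct <- cor.test(sds_h, sds_e, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
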