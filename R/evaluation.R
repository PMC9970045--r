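# Quantitative convergence experiments: repeated reference subsets per
# size, cohort SD of per-image mean L*, Levene's tests between adjacent
# sizes, and qualitative L* heatmaps.

#' Levene's test for equality of variances (two groups)
#'
#' Levene's W statistic on absolute deviations from the group center
#' (arithmetic mean as in Levene 1960, or median for the Brown-Forsythe
#' variant), with the p-value from the F distribution on (1, N - 2)
#' degrees of freedom. When both groups have zero within-group deviation
#' the statistic is 0 and p = 1.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return A list with `statistic`, `p_value`, `df` (c(1, N - 2)).
#' @export
levene_test <- function(group_a, group_b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_stainref("schema", "each group needs >= 2 values")
  cfun <- if (center == "mean") mean else stats::median
  z <- list(abs(group_a - cfun(group_a)), abs(group_b - cfun(group_b)))
  n <- lengths(z)
  nn <- sum(n)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(n * zbar_i) / nn
  between <- sum(n * (zbar_i - zbar)^2)
  within <- sum(vapply(seq_along(z),
                       function(i) sum((z[[i]] - zbar_i[i])^2), numeric(1)))
  if (within == 0) {
    if (between == 0) return(list(statistic = 0, p_value = 1,
                                  df = c(1, nn - 2)))
    return(list(statistic = Inf, p_value = 0, df = c(1, nn - 2)))
  }
  w <- (nn - 2) / 1 * between / within
  list(statistic = w, p_value = pf(w, 1, nn - 2, lower.tail = FALSE),
       df = c(1, nn - 2))
}

# Precompute everything per image that the permutation loop reuses:
# OD, tissue mask, stain fit, and per-stain source histograms on edges
# shared across the cohort. The stored concentrations are the debiased
# (unpenalized) projection onto the fitted dictionary, matching what
# normalize_image() reconstructs with.
prepare_cohort <- function(images, ids = NULL, beta = 0.15, lambda = 0.1,
                           c_const = 1, m_max = 1024L, seed = 1L, i0 = 255) {
  n <- length(images)
  if (is.null(ids)) ids <- names(images) %||% sprintf("img%04d", seq_len(n))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  fits <- vector("list", n)
  for (k in seq_len(n)) {
    od <- rgb_to_od(images[[k]], i0 = i0)
    mask <- tissue_mask(od, beta = beta)
    fits[[k]] <- fit_stain_model(od, mask, lambda = lambda, seed = seeds[k])
    h_proj <- project_concentrations(od, mask, fits[[k]]$w, lambda = 0)
    fits[[k]]$h <- h_proj
    fits[[k]]$index <- attr(h_proj, "index")
  }
  dens <- list(H = lapply(fits, function(f) f$h["H", ]),
               E = lapply(fits, function(f) f$h["E", ]))
  spec <- cohort_bin_spec(dens, m_max = m_max)
  hists <- lapply(c(H = "H", E = "E"), function(s)
    stats::setNames(lapply(dens[[s]], build_density_histogram,
                           edges = spec[[s]]$edges, c_const = c_const,
                           stain = s), ids))
  structure(list(ids = ids, fits = stats::setNames(fits, ids),
                 hists = hists, bin_spec = spec, beta = beta,
                 lambda = lambda, c_const = c_const, i0 = i0, seed = seed),
            class = "prepared_cohort")
}

# Mean L* of one image normalized against a reference, computed on tissue
# pixels only (background is white and excluded by the mask by definition).
norm_mean_lab <- function(fit, ref, i0 = 255, sub_mask = NULL) {
  h <- matched_concentrations(fit, ref)
  if (!is.null(sub_mask)) {
    keep <- sub_mask[fit$index]
    if (!any(keep)) return(NA_real_)
    h <- h[, keep, drop = FALSE]
  }
  od_new <- pmin(ref$w_op %*% h, 50)
  rgb <- t(pmin(round(i0 * exp(-od_new)), 255)) / 255
  mean(convertColor(rgb, from = "sRGB", to = "Lab")[, 1])
}

#' Normalization convergence experiment over reference subset sizes
#'
#' For each subset size and permutation, a random reference subset (drawn
#' without replacement) is aggregated into a reference, the whole cohort is
#' normalized against it, and the per-image mean L* plus the cohort SD are
#' recorded. Levene's test is applied between the pooled per-image mean-L*
#' values of adjacent sizes; the per-size range is the max - min of
#' per-permutation cohort SDs. Decreasing ranges as the subset grows
#' indicate convergence of the normalized cohort.
#'
#' @param images list of RGB arrays (a synthetic cohort's `image` fields or
#'   images loaded from a manifest).
#' @param subset_sizes integer sizes, each `<= length(images)`.
#' @param n_perms permutations per size (>= 2).
#' @param seed integer master seed.
#' @param ids image identifiers.
#' @param beta,lambda,c_const,m_max,i0 pipeline parameters (see
#'   [fit_stain_model()], [build_density_histogram()], [cohort_bin_spec()]).
#' @param center Levene centering, `"mean"` or `"median"`.
#' @param prepared optionally, a precomputed `prepare_cohort()` result.
#' @return A list of class `convergence_report`: `subset_sizes`, `labic`
#'   (per size: images x perms matrix of mean L*), `sd_per_perm` (per size:
#'   per-permutation cohort SDs), `range_per_size`, `levene_vs_next`
#'   (data frame: size_a, size_b, statistic, p_value), `failed` (per-image
#'   failure log), `seed`.
#' @export
convergence_experiment <- function(images, subset_sizes = c(1L, 10L, 100L),
                                   n_perms = 8L, seed = 1L, ids = NULL,
                                   beta = 0.15, lambda = 0.1, c_const = 1,
                                   m_max = 1024L, i0 = 255,
                                   center = "mean", prepared = NULL) {
  if (n_perms < 2L) stop_stainref("schema", "n_perms must be >= 2")
  if (is.null(prepared))
    prepared <- prepare_cohort(images, ids = ids, beta = beta,
                               lambda = lambda, c_const = c_const,
                               m_max = m_max, seed = seed, i0 = i0)
  n <- length(prepared$ids)
  if (any(subset_sizes > n))
    stop_stainref("schema", "subset sizes exceed cohort size %d", n)
  labic <- vector("list", length(subset_sizes))
  names(labic) <- as.character(subset_sizes)
  failed <- character(0)
  withr::with_seed(seed + 1L, {
    for (si in seq_along(subset_sizes)) {
      s <- subset_sizes[si]
      m <- matrix(NA_real_, n, n_perms,
                  dimnames = list(prepared$ids, NULL))
      for (p in seq_len(n_perms)) {
        sel <- sample.int(n, s)
        ref <- build_reference(prepared$fits[sel],
                               lapply(prepared$hists,
                                      function(hh) hh[sel]),
                               subset_ids = prepared$ids[sel])
        for (k in seq_len(n)) {
          val <- tryCatch(norm_mean_lab(prepared$fits[[k]], ref,
                                        i0 = prepared$i0),
                          error = function(e) {
                            failed <<- c(failed,
                                         sprintf("%s@size%d/perm%d: %s",
                                                 prepared$ids[k], s, p,
                                                 conditionMessage(e)))
                            NA_real_
                          })
          m[k, p] <- val
        }
      }
      labic[[si]] <- m
    }
  })
  sd_per_perm <- lapply(labic, function(m) apply(m, 2, sd, na.rm = TRUE))
  range_per_size <- vapply(sd_per_perm, function(v) max(v) - min(v),
                           numeric(1))
  lev <- NULL
  if (length(subset_sizes) > 1L) {
    lev <- do.call(rbind, lapply(seq_len(length(subset_sizes) - 1L),
                                 function(i) {
      lt <- levene_test(as.vector(labic[[i]]), as.vector(labic[[i + 1]]),
                        center = center)
      data.frame(size_a = subset_sizes[i], size_b = subset_sizes[i + 1],
                 statistic = lt$statistic, p_value = lt$p_value)
    }))
  }
  structure(list(subset_sizes = subset_sizes, labic = labic,
                 sd_per_perm = sd_per_perm, range_per_size = range_per_size,
                 levene_vs_next = lev, failed = failed, seed = seed),
            class = "convergence_report")
}

#' Region-wise normalization convergence experiment
#'
#' Identical protocol to [convergence_experiment()], with the mean L*
#' computed within each annotated region (intersected with the tissue
#' mask). Regions absent from an image, or empty after masking, are skipped
#' and logged.
#'
#' @inheritParams convergence_experiment
#' @param masks list parallel to `images`; element k is a named list of
#'   logical region masks for image k.
#' @return Named list (one `convergence_report` per region label).
#' @export
roi_convergence_experiment <- function(images, masks,
                                       subset_sizes = c(1L, 10L, 100L),
                                       n_perms = 8L, seed = 1L, ids = NULL,
                                       ...) {
  prepared <- prepare_cohort(images, ids = ids, seed = seed, ...)
  labels <- unique(unlist(lapply(masks, names)))
  out <- lapply(labels, function(lab) {
    n <- length(prepared$ids)
    labic <- vector("list", length(subset_sizes))
    names(labic) <- as.character(subset_sizes)
    skipped <- character(0)
    withr::with_seed(seed + 1L, {
      for (si in seq_along(subset_sizes)) {
        s <- subset_sizes[si]
        m <- matrix(NA_real_, n, n_perms,
                    dimnames = list(prepared$ids, NULL))
        for (p in seq_len(n_perms)) {
          sel <- sample.int(n, s)
          ref <- build_reference(prepared$fits[sel],
                                 lapply(prepared$hists,
                                        function(hh) hh[sel]),
                                 subset_ids = prepared$ids[sel])
          for (k in seq_len(n)) {
            rm_k <- masks[[k]][[lab]]
            if (is.null(rm_k)) {
              skipped <- c(skipped, sprintf("%s: region %s absent",
                                            prepared$ids[k], lab))
              next
            }
            m[k, p] <- norm_mean_lab(prepared$fits[[k]], ref,
                                     i0 = prepared$i0, sub_mask = rm_k)
          }
        }
        labic[[si]] <- m
      }
    })
    sd_per_perm <- lapply(labic, function(mm)
      apply(mm, 2, sd, na.rm = TRUE))
    structure(list(subset_sizes = subset_sizes, labic = labic,
                   sd_per_perm = sd_per_perm,
                   range_per_size = vapply(sd_per_perm,
                                           function(v) max(v) - min(v),
                                           numeric(1)),
                   levene_vs_next = NULL, failed = unique(skipped),
                   seed = seed),
              class = "convergence_report")
  })
  stats::setNames(out, labels)
}

#' Per-pixel CIELAB intensity heatmap
#'
#' @param img rows x cols x 3 RGB array in \[0, 255\].
#' @return A list of class `labic_heatmap`: `map` (matrix of L* values in
#'   \[0, 100\]) and `gray` (min-max scaled to \[0, 1\] for 8-bit grayscale
#'   export; a constant map yields all zeros and `constant = TRUE`).
#' @export
labic_heatmap <- function(img) {
  lab <- rgb_to_lab(img)
  l <- lab[, , 1]
  rng <- range(l)
  constant <- rng[1] == rng[2]
  gray <- if (constant) matrix(0, nrow(l), ncol(l))
          else (l - rng[1]) / (rng[2] - rng[1])
  structure(list(map = l, gray = gray, constant = constant),
            class = "labic_heatmap")
}
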