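# Normalization against an aggregate reference: per-stain CDF matching of
# concentrations to H_op, reconstruction with W_op, and CIELAB intensity
# extraction.

# Probability mass per bin. Distribution comparisons use the raw bin
# occupancies where provenance is available: the min-max scaling to C
# zeroes the least-occupied bin, which would misrepresent an occupied bin
# as massless. Aggregate (mean-of-scaled) histograms carry no raw counts
# and use their scaled counts, the only definition an aggregate has.
hist_mass <- function(h) {
  cnt <- if (!is.null(h$mass)) h$mass
         else if (!is.null(h$raw_counts)) h$raw_counts
         else h$counts
  cnt / sum(cnt)
}

# Piecewise-linear CDF of a histogram at its bin edges (unit mass).
hist_cdf <- function(h) {
  c(0, cumsum(hist_mass(h)))
}

#' Match densities to a reference histogram by CDF transfer
#'
#' Classical histogram matching `x -> Q_ref(F_src(x))` with both the source
#' CDF `F` and the reference quantile function `Q` piecewise-linear over the
#' shared bin edges of the unit-mass renormalized histograms (raw bin
#' occupancies where available, see [wasserstein1()]). The mapping is
#' non-decreasing, so the rank order of the inputs is preserved (ties
#' allowed); inputs outside the edge range are clamped.
#'
#' @param densities nonnegative numeric vector of source densities.
#' @param source_hist,ref_hist `density_histogram`s on identical edges.
#' @return Matched densities, nonnegative, within the reference support.
#'   A degenerate reference (all mass in one bin) maps every input to that
#'   bin's center, with a warning.
#' @export
match_histogram <- function(densities, source_hist, ref_hist) {
  check_hist_compatible(list(source_hist, ref_hist))
  edges <- source_hist$edges
  p_ref <- hist_mass(ref_hist)
  occupied <- which(p_ref > 0)
  if (length(occupied) == 1L) {
    warning("degenerate reference histogram: single occupied bin")
    return(rep((edges[occupied] + edges[occupied + 1]) / 2,
               length(densities)))
  }
  f_src <- hist_cdf(source_hist)
  q <- approx(edges, f_src, xout = pmin(pmax(densities, edges[1]),
                                        edges[length(edges)]),
              rule = 2)$y
  # Quantile function: exact inverse of the piecewise-linear reference CDF.
  # Each occupied bin k maps [F(e_k), F(e_{k+1})] back onto [e_k, e_{k+1}]
  # linearly; empty bins are jumps of Q (mass never lands where the
  # reference has none), so the occupied bin is located explicitly instead
  # of interpolating across CDF plateaus.
  f_right <- cumsum(p_ref)
  pos <- findInterval(q, f_right[occupied], left.open = TRUE) + 1L
  pos <- pmin(pos, length(occupied))
  k <- occupied[pos]
  width <- edges[2] - edges[1]
  f_left <- f_right[k] - p_ref[k]
  edges[k] + pmin(pmax((q - f_left) / p_ref[k], 0), 1) * width
}

#' Normalize an image against an aggregate reference
#'
#' The population-reference form of structure-preserving color
#' normalization: the image is taken to optical density, background is
#' masked out, the per-image stain model is fitted (or a precomputed fit is
#' reused), each stain's concentrations are histogram-matched to the
#' reference `H_op`, and the tissue is reconstructed as
#' `OD' = W_op %*% H_matched` and returned to RGB. Background pixels pass
#' through unchanged, so the tissue-mask geometry of input and output is
#' identical.
#'
#' @param img rows x cols x 3 RGB array in \[0, 255\].
#' @param ref an [build_reference()] `aggregate_reference`.
#' @param beta tissue-mask OD threshold (default 0.15).
#' @param lambda sparsity weight for the stain fit (default 0.1).
#' @param seed seed for the stain fit.
#' @param fit optional precomputed `stain_fit` for `img`, skipping
#'   re-estimation.
#' @param i0 white-point intensity (default 255).
#' @return rows x cols x 3 normalized RGB array. An all-background image is
#'   returned unchanged with a warning.
#' @export
normalize_image <- function(img, ref, beta = 0.15, lambda = 0.1, seed = 1L,
                            fit = NULL, i0 = 255) {
  stopifnot(inherits(ref, "aggregate_reference"))
  od <- rgb_to_od(img, i0 = i0)
  mask <- tissue_mask(od, beta = beta)
  if (attr(mask, "empty")) {
    warning("image contains no tissue; returned unchanged")
    return(img)
  }
  if (is.null(fit))
    fit <- fit_stain_model(od, mask, lambda = lambda, seed = seed)
  # Debiased coding: the dictionary is learned with the L1 penalty, but the
  # densities that are histogram-matched and reconstructed come from the
  # unpenalized nonnegative projection, avoiding the ~lambda/2 systematic
  # shrinkage (dimming) a penalized code would carry into the output.
  h_proj <- project_concentrations(od, mask, fit$w, lambda = 0)
  fit$h <- h_proj
  fit$index <- attr(h_proj, "index")
  h_matched <- matched_concentrations(fit, ref)
  od_new <- pmin(ref$w_op %*% h_matched, 50)
  rgb_new <- round(i0 * exp(-od_new))
  rgb_new[rgb_new > 255] <- 255
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[fit$index] <- rgb_new[ch, ]
    out[, , ch] <- plane
  }
  out
}

# Histogram-match both stain rows of a fit against a reference.
matched_concentrations <- function(fit, ref) {
  h <- fit$h
  for (s in c("H", "E")) {
    src <- build_density_histogram(h[s, ], ref$h_op[[s]]$edges,
                                   c_const = ref$c_const, stain = s)
    h[s, ] <- match_histogram(h[s, ], src, ref$h_op[[s]])
  }
  h
}

#' Convert an 8-bit sRGB image to CIELAB
#'
#' Standard sRGB -> CIE XYZ (D65) -> CIELAB conversion; `L*` lies in
#' \[0, 100\].
#'
#' @param img rows x cols x 3 RGB array in \[0, 255\].
#' @return rows x cols x 3 array of (L*, a*, b*).
#' @export
rgb_to_lab <- function(img) {
  d <- dim(img)
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3])) / 255
  lab <- convertColor(rgb, from = "sRGB", to = "Lab")
  array(lab, c(d[1], d[2], 3))
}

#' Mean CIELAB intensity (L*) over tissue
#'
#' The per-image summary used to quantify normalization convergence: the
#' mean of the L* channel over mask-retained pixels.
#'
#' @param img rows x cols x 3 RGB array in \[0, 255\].
#' @param mask logical matrix; must retain at least one pixel.
#' @return Mean L* (scalar in \[0, 100\]).
#' @export
extract_labic <- function(img, mask) {
  if (!any(mask)) stop_stainref("data", "empty mask")
  idx <- which(mask)
  rgb <- cbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx]) / 255
  mean(convertColor(rgb, from = "sRGB", to = "Lab")[, 1])
}
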