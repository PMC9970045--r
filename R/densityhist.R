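# Per-stain concentration density histograms: Knuth-optimal power-of-2
# binning shared across a cohort, bin-wise min-max scaling to a constant C,
# and aggregation of histograms and stain matrices into the population
# normalization reference (W_op, H_op).

#' Knuth's Bayesian optimal number of histogram bins
#'
#' Maximizes the Knuth log-posterior over the number of equal-width bins M
#' spanning \[min(x), max(x)\]:
#' `F(M) = N ln M + lnGamma(M/2) - M lnGamma(1/2) - lnGamma(N + M/2) +
#'  sum_k lnGamma(n_k + 1/2)`
#' with `n_k` the occupancy of bin k. The rule depends only on bin
#' occupancies, so it is invariant under affine transforms of the data.
#'
#' @param samples numeric vector with at least 2 distinct values.
#' @param m_max largest bin count searched (default 1024). If the argmax
#'   lands on `m_max` the result carries attribute `truncated = TRUE`.
#' @return Integer bin count (attributes: `truncated`, `logp` the attained
#'   log-posterior).
#' @references Knuth, K.H. (2019) Optimal data-based binning for histograms
#'   and histogram-based probability density models. Digital Signal
#'   Processing 95.
#' @export
knuth_bins <- function(samples, m_max = 1024L) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L || x[1] == x[n])
    stop_stainref("data", "degenerate range: need >= 2 distinct values")
  lg_half <- lgamma(0.5)
  best_m <- 1L
  best_f <- -Inf
  for (m in seq_len(m_max)) {
    edges <- x[1] + (x[n] - x[1]) * seq_len(m) / m
    # counts per bin from the sorted sample: #{x <= edge} differences
    cum <- findInterval(edges, x)
    cnt <- diff(c(0L, cum))
    f <- n * log(m) + lgamma(m / 2) - m * lg_half - lgamma(n + m / 2) +
      sum(lgamma(cnt + 0.5))
    if (f > best_f) {
      best_f <- f
      best_m <- m
    }
  }
  structure(best_m, truncated = best_m == m_max, logp = best_f)
}

#' Shared histogram bin specification for a cohort
#'
#' For each stain, the bin count is the largest per-image Knuth-optimal
#' count, rounded up to the next power of 2; the range is anchored at 0 and
#' extends to the largest density observed in the cohort, so all images of
#' the cohort share identical uniform bin edges.
#'
#' @param densities named list (per stain, e.g. `H`, `E`) of lists of
#'   per-image density vectors.
#' @param m_max passed to [knuth_bins()].
#' @return Named list per stain: `edges` (length n_bins + 1), `n_bins`.
#' @export
cohort_bin_spec <- function(densities, m_max = 1024L) {
  lapply(densities, function(per_image) {
    ks <- vapply(seq_along(per_image), function(i) {
      tryCatch(as.integer(knuth_bins(per_image[[i]], m_max = m_max)),
               stainref_error = function(e) {
                 stop_stainref("data", "image %s: %s",
                               names(per_image)[i] %||% i, conditionMessage(e))
               })
    }, integer(1))
    n_bins <- next_pow2(max(ks))
    top <- max(vapply(per_image, max, numeric(1)))
    list(edges = seq(0, top, length.out = n_bins + 1), n_bins = n_bins,
         knuth = ks)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a scaled per-stain density histogram
#'
#' Bins the densities on shared uniform edges (values at or above the top
#' edge fall in the last bin), then applies bin-wise min-max scaling to the
#' constant `C`: `scaled_k = (n_k - min_k) / (max_k - min_k) * C`, so the
#' emptiest bin maps to 0 and the fullest to `C`.
#'
#' @param densities nonnegative numeric vector.
#' @param edges uniform, strictly increasing bin edges.
#' @param c_const the scaling constant C (> 0, default 1).
#' @param stain stain label, `"H"` or `"E"`.
#' @return A list of class `density_histogram`: `edges`, `counts` (scaled),
#'   `raw_counts`, `c_const`, `stain`, `n_pixels_raw`.
#' @export
build_density_histogram <- function(densities, edges, c_const = 1,
                                    stain = "H") {
  if (c_const <= 0) stop_stainref("schema", "c_const must be positive")
  widths <- diff(edges)
  if (any(widths <= 0) || diff(range(widths)) > 1e-9 * widths[1])
    stop_stainref("schema", "edges must be uniform and increasing")
  x <- pmin(pmax(densities, edges[1]), edges[length(edges)])
  idx <- findInterval(x, edges, all.inside = TRUE)
  raw <- tabulate(idx, nbins = length(edges) - 1L)
  if (max(raw) == min(raw))
    stop_stainref("data", "degenerate histogram: all bin counts equal")
  scaled <- (raw - min(raw)) / (max(raw) - min(raw)) * c_const
  structure(list(edges = edges, counts = scaled, raw_counts = raw,
                 c_const = c_const, stain = stain,
                 n_pixels_raw = length(densities)),
            class = "density_histogram")
}

# shared-edge compatibility check
check_hist_compatible <- function(hists) {
  e1 <- hists[[1]]$edges
  for (h in hists[-1]) {
    if (length(h$edges) != length(e1) || any(abs(h$edges - e1) > 1e-9))
      stop_stainref("schema", "histograms do not share bin edges")
    if (!identical(h$stain, hists[[1]]$stain))
      stop_stainref("schema", "histograms mix stains")
    if (h$c_const != hists[[1]]$c_const)
      stop_stainref("schema", "histograms mix scaling constants")
  }
  invisible(TRUE)
}

#' Aggregate density histograms into a reference histogram
#'
#' Bin-wise arithmetic mean over the subset:
#' `H_op = (1 / S_n) * sum_k H_k`. All inputs must share edges, stain and
#' scaling constant.
#'
#' @param hists list of [build_density_histogram()] results.
#' @return A `density_histogram` whose counts are the bin-wise mean of the
#'   scaled member counts; `n_pixels_raw` is the summed provenance. The
#'   aggregate additionally carries `mass`, the bin-wise mean of the
#'   members' unit-mass occupancy distributions, which downstream CDF
#'   operations (matching, Wasserstein) use as the aggregate's probability
#'   content — the min-max scaling is a representation, not a distribution.
#' @export
aggregate_histograms <- function(hists) {
  if (length(hists) < 1L) stop_stainref("schema", "need >= 1 histogram")
  check_hist_compatible(hists)
  nb <- length(hists[[1]]$counts)
  counts <- rowMeans(vapply(hists, `[[`, numeric(nb), "counts"))
  mass <- rowMeans(vapply(hists, hist_mass, numeric(nb)))
  structure(list(edges = hists[[1]]$edges, counts = counts,
                 raw_counts = NULL, mass = mass,
                 c_const = hists[[1]]$c_const,
                 stain = hists[[1]]$stain,
                 n_pixels_raw = sum(vapply(hists, `[[`, numeric(1),
                                           "n_pixels_raw"))),
            class = "density_histogram")
}

#' Aggregate stain matrices into a reference stain matrix
#'
#' Entry-wise arithmetic mean `W_op = (1 / S_n) * sum_k W_k` over
#' Hematoxylin-first ordered matrices, followed by re-normalization of each
#' column to unit length (the mean of unit vectors is not unit; the
#' deconvolution model requires unit columns).
#'
#' @param mats list of 3x2 stain matrices, each already canonically ordered.
#' @return A 3x2 unit-column stain matrix, columns `H`, `E`.
#' @export
aggregate_stain_matrices <- function(mats) {
  if (length(mats) < 1L) stop_stainref("schema", "need >= 1 stain matrix")
  for (w in mats) {
    w_ord <- order_stains(w)
    if (any(abs(w_ord - w) > 1e-12))
      stop_stainref("schema",
                    "stain matrices must be canonically ordered (H first)")
  }
  m <- Reduce(`+`, mats) / length(mats)
  out <- unit_cols(m)
  colnames(out) <- c("H", "E")
  out
}

#' Build an aggregate normalization reference from a cohort subset
#'
#' Combines the subset's per-image stain matrices and per-stain scaled
#' density histograms into the population normalization standard
#' `(W_op, H_op)`.
#'
#' @param fits list of `stain_fit` objects (or bare 3x2 stain matrices) for
#'   the subset images.
#' @param hists named list per stain (`H`, `E`) of per-image
#'   `density_histogram`s for the same subset, on shared edges.
#' @param subset_ids character identifiers of the subset images.
#' @return A list of class `aggregate_reference`: `w_op`, `h_op` (list with
#'   `H` and `E` histograms), `edges`, `c_const`, `subset_ids`, `s_n`.
#' @export
build_reference <- function(fits, hists, subset_ids = NULL) {
  mats <- lapply(fits, function(f) if (inherits(f, "stain_fit")) f$w else f)
  w_op <- aggregate_stain_matrices(mats)
  h_op <- lapply(hists, aggregate_histograms)
  structure(list(w_op = w_op, h_op = h_op,
                 edges = lapply(h_op, `[[`, "edges"),
                 c_const = h_op[[1]]$c_const,
                 subset_ids = subset_ids, s_n = length(mats)),
            class = "aggregate_reference")
}
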