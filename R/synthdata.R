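# Synthetic H&E tile generator: a Beer-Lambert forward model with known
# ground-truth stain matrices and gamma-distributed concentrations, used to
# emulate inter-slide staining variability (stain-vector jitter plus a
# per-image multiplicative "lab effect" on concentrations).

#' Canonical H&E stain matrix
#'
#' The widely used reference optical-density directions for Hematoxylin
#' (0.65, 0.70, 0.29) and Eosin (0.07, 0.99, 0.11), unit-normalized and
#' Hematoxylin-first.
#'
#' @return 3x2 matrix with unit-norm columns named `H` and `E`.
#' @export
he_stain_matrix <- function() {
  w <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  unit_cols(w)
}

#' Perturb stain vectors by a bounded random rotation
#'
#' Each column of `base` is rotated by an angle drawn uniformly from
#' \[0, `jitter_deg`\] degrees about a random axis, then clamped to the
#' nonnegative octant and re-normalized. Clamping is the Euclidean
#' projection onto the nonnegative cone containing the base vector, so the
#' angular distance to the base column never exceeds the drawn angle.
#'
#' @param base 3x2 stain matrix with nonnegative unit-norm columns.
#' @param jitter_deg maximum angular perturbation per column, degrees (>= 0).
#' @param seed integer seed; output is deterministic given the seed.
#' @return A 3x2 stain matrix; equals `base` exactly when `jitter_deg = 0`.
#' @export
make_stain_matrix <- function(base, jitter_deg, seed = 1L) {
  if (jitter_deg < 0) stop_stainref("schema", "jitter_deg must be >= 0")
  if (jitter_deg == 0) return(base)
  withr::with_seed(seed, {
    out <- base
    for (j in seq_len(ncol(base))) {
      cvec <- base[, j]
      theta <- runif(1, 0, jitter_deg) * pi / 180
      # random unit vector orthogonal to cvec
      repeat {
        z <- rnorm(3)
        u <- z - sum(z * cvec) * cvec
        nu <- sqrt(sum(u^2))
        if (nu > 1e-8) break
      }
      u <- u / nu
      v <- cos(theta) * cvec + sin(theta) * u
      v <- pmax(v, 0)
      out[, j] <- v / sqrt(sum(v^2))
    }
    out
  })
}

#' Draw per-pixel stain concentrations from a gamma law
#'
#' Row `s` of the result is `rgamma(n, shape_s, scale_s) * lab_factor`,
#' modeling the per-image multiplicative staining-intensity ("lab effect")
#' shift on top of the cohort-level concentration distribution.
#'
#' @param n_pixels number of pixels (>= 1).
#' @param shapes,scales length-2 positive numerics (Hematoxylin, Eosin).
#' @param lab_factor nonnegative per-image multiplier (0 yields a zero map).
#' @param seed integer seed.
#' @return 2 x `n_pixels` nonnegative matrix with rows `H`, `E`.
#' @export
sample_concentrations <- function(n_pixels, shapes, scales, lab_factor = 1,
                                  seed = 1L) {
  if (n_pixels < 1) stop_stainref("schema", "n_pixels must be >= 1")
  if (any(shapes <= 0) || any(scales <= 0))
    stop_stainref("schema", "gamma shapes and scales must be positive")
  if (lab_factor < 0) stop_stainref("schema", "lab_factor must be >= 0")
  withr::with_seed(seed, {
    h <- rbind(H = rgamma(n_pixels, shape = shapes[1], scale = scales[1]),
               E = rgamma(n_pixels, shape = shapes[2], scale = scales[2]))
    h * lab_factor
  })
}

#' Render an RGB tile from stain matrix and concentrations
#'
#' Beer-Lambert forward model: `I_c = i0 * exp(-(W H)_c)`, quantized to
#' 8-bit. Optical densities are clamped at `od_ceiling` before
#' exponentiation so the transform remains invertible at 8-bit precision;
#' zero-density pixels render as pure white (`i0`).
#'
#' @param w 3x2 stain matrix.
#' @param h 2 x N concentration map, N = rows * cols, pixels in column-major
#'   order.
#' @param tile_size integer `(rows, cols)`.
#' @param i0 white-point intensity (default 255).
#' @param od_ceiling maximum optical density (default 3.0, the 8-bit floor
#'   of one count).
#' @return rows x cols x 3 integer array in \[0, 255\].
#' @export
render_tile <- function(w, h, tile_size, i0 = 255, od_ceiling = 3) {
  n <- prod(tile_size)
  if (ncol(h) != n)
    stop_stainref("schema", "h has %d pixels but tile_size implies %d",
                  ncol(h), n)
  od <- pmin(w %*% h, od_ceiling)
  img <- array(0, c(tile_size[1], tile_size[2], 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(round(i0 * exp(-od[ch, ])), tile_size[1])
  img
}

#' Specification of a synthetic H&E cohort
#'
#' Bundles the generator parameters with validation. Defaults describe the
#' study conditions used throughout the package's experiments: 200 tiles of
#' 64 x 64 pixels, stain-vector jitter up to 5 degrees, per-image lab-effect
#' factors uniform in \[0.7, 1.3\], gamma(2, 0.40) Hematoxylin and
#' gamma(2, 0.30) Eosin concentrations, and 20% background.
#'
#' @param n_images number of tiles (>= 1).
#' @param tile_size integer `(rows, cols)`.
#' @param base_stain_matrix 3x2 unit-norm nonnegative stain matrix.
#' @param stain_angle_jitter_deg max per-image angular perturbation, degrees.
#' @param shapes,scales per-stain gamma parameters (Hematoxylin, Eosin).
#' @param lab_factor_range length-2 range of the per-image multiplicative
#'   concentration factor.
#' @param background_fraction fraction of pixels rendered as pure white
#'   background, in \[0, 1).
#' @param i0 white-point intensity.
#' @param od_ceiling optical-density clamp used when rendering.
#' @param seed master seed for the cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_images = 200L, tile_size = c(64L, 64L),
                        base_stain_matrix = he_stain_matrix(),
                        stain_angle_jitter_deg = 5,
                        shapes = c(H = 2, E = 2),
                        scales = c(H = 0.40, E = 0.30),
                        lab_factor_range = c(0.7, 1.3),
                        background_fraction = 0.2,
                        i0 = 255, od_ceiling = 3, seed = 1L) {
  if (n_images < 1) stop_stainref("schema", "n_images must be >= 1")
  if (background_fraction < 0 || background_fraction >= 1)
    stop_stainref("schema", "background_fraction must be in [0, 1)")
  if (any(base_stain_matrix < 0))
    stop_stainref("schema", "base stain matrix must be nonnegative")
  if (any(abs(colSums(base_stain_matrix^2) - 1) > 1e-6))
    stop_stainref("schema", "base stain matrix columns must be unit-norm")
  structure(list(
    n_images = as.integer(n_images), tile_size = as.integer(tile_size),
    base_stain_matrix = base_stain_matrix,
    stain_angle_jitter_deg = stain_angle_jitter_deg,
    shapes = shapes, scales = scales,
    lab_factor_range = lab_factor_range,
    background_fraction = background_fraction,
    i0 = i0, od_ceiling = od_ceiling, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic H&E cohort with ground truth
#'
#' Renders `spec$n_images` tiles. Each image gets its own jittered stain
#' matrix and lab-effect factor; a contiguous block of
#' `background_fraction * rows * cols` pixels is left unstained (pure
#' white). Ground truth is retained for testing stain recovery and
#' histogram fidelity. Byte-identical across runs given the same spec.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort`; element `i` is a list with
#'   `id`, `image` (rows x cols x 3), `w_true`, `h_true` (2 x N, zeros at
#'   background pixels), `lab_factor`, `tissue` (logical ground-truth
#'   tissue indicator, column-major), and `seed`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_px <- prod(spec$tile_size)
  n_bg <- round(spec$background_fraction * n_px)
  draws <- withr::with_seed(spec$seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, 2L * spec$n_images),
    labf = runif(spec$n_images, spec$lab_factor_range[1],
                 spec$lab_factor_range[2])
  ))
  out <- vector("list", spec$n_images)
  for (k in seq_len(spec$n_images)) {
    w_k <- make_stain_matrix(spec$base_stain_matrix,
                             spec$stain_angle_jitter_deg,
                             seed = draws$seeds[2 * k - 1])
    h_tissue <- sample_concentrations(n_px - n_bg, spec$shapes, spec$scales,
                                      lab_factor = draws$labf[k],
                                      seed = draws$seeds[2 * k])
    h_full <- matrix(0, 2, n_px, dimnames = list(c("H", "E"), NULL))
    tissue <- c(rep(FALSE, n_bg), rep(TRUE, n_px - n_bg))
    h_full[, tissue] <- h_tissue
    img <- render_tile(w_k, h_full, spec$tile_size,
                       i0 = spec$i0, od_ceiling = spec$od_ceiling)
    out[[k]] <- list(id = sprintf("img%04d", k), image = img, w_true = w_k,
                     h_true = h_full, lab_factor = draws$labf[k],
                     tissue = tissue, seed = draws$seeds[2 * k])
  }
  structure(out, class = "synthetic_cohort", spec = spec)
}
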