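# End-to-end orchestration: stain separation -> shared-bin histograms ->
# pair pool -> subset-size sweep -> power-law fit + Pareto optimum ->
# aggregate reference at the optimal size -> cohort normalization ->
# convergence evaluation. Every JSON artifact is stamped with the config
# hash, the stage seed and the package version.

#' Assemble a validated run configuration
#'
#' @param manifest path to the cohort manifest CSV.
#' @param out_dir output directory for artifacts.
#' @param beta tissue-mask OD threshold.
#' @param sparsity_lambda L1 weight of the stain model.
#' @param c_const histogram scaling constant C.
#' @param i0 white-point intensity.
#' @param od_ceiling OD clamp for rendering/reconstruction.
#' @param m_max Knuth bin-search cap.
#' @param s_max largest sweep subset size.
#' @param n_perms sweep permutations per size.
#' @param pareto_fraction Pareto fraction (default 0.8).
#' @param pareto_convention `"cumulative_80"` or `"reduction_80"`.
#' @param subset_sizes evaluation subset sizes.
#' @param eval_perms evaluation permutations per size.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, out_dir, beta = 0.15,
                       sparsity_lambda = 0.1, c_const = 1, i0 = 255,
                       od_ceiling = 3, m_max = 1024L, s_max = 50L,
                       n_perms = 200L, pareto_fraction = 0.8,
                       pareto_convention = "cumulative_80",
                       subset_sizes = c(1L, 5L, 10L), eval_perms = 4L,
                       seed = 1L) {
  stopifnot(beta > 0, sparsity_lambda >= 0, c_const > 0, i0 > 0,
            s_max >= 1, n_perms >= 2, pareto_fraction > 0,
            pareto_fraction < 1)
  cfg <- list(manifest = manifest, out_dir = out_dir, beta = beta,
              sparsity_lambda = sparsity_lambda, c_const = c_const,
              i0 = i0, od_ceiling = od_ceiling, m_max = as.integer(m_max),
              s_max = as.integer(s_max), n_perms = as.integer(n_perms),
              pareto_fraction = pareto_fraction,
              pareto_convention = pareto_convention,
              subset_sizes = as.integer(subset_sizes),
              eval_perms = as.integer(eval_perms), seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stamp <- function(cfg, stage_seed) {
  list(config_hash = config_hash(cfg), seed = stage_seed,
       version = as.character(utils::packageVersion("stainref")))
}

write_artifact <- function(x, cfg, stage_seed, path) {
  jsonlite::write_json(c(list(meta = stamp(cfg, stage_seed)), x), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full normalization workflow
#'
#' Executes, in order: per-image stain separation; shared-bin density
#' histograms; pairwise Wasserstein pool; subset-size sweep; power-law fit
#' and Pareto optimum per stain; aggregate reference at the optimal size
#' (capped at the cohort size); cohort normalization (PNGs written to
#' `out_dir/normalized`); and the convergence evaluation. A stage failure
#' halts the run with the failing stage named; artifacts of completed
#' stages are retained.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the key results (`pareto`, `fits`,
#'   `report`, artifact paths).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- withr::with_seed(cfg$seed,
                            sample.int(.Machine$integer.max - 1L, 5L))
  run_stage <- function(name, expr) {
    message(sprintf("[stainref] stage %s ...", name))
    tryCatch(expr, error = function(e) {
      message(sprintf("[stainref] stage %s FAILED: %s", name,
                      conditionMessage(e)))
      stop_stainref("data", "stage %s failed: %s", name,
                    conditionMessage(e))
    })
  }

  images <- run_stage("load", load_cohort_images(cfg$manifest))
  message(sprintf("[stainref]   %d images", length(images)))

  prepared <- run_stage("separate",
    prepare_cohort(images, beta = cfg$beta, lambda = cfg$sparsity_lambda,
                   c_const = cfg$c_const, m_max = cfg$m_max,
                   seed = seeds[1], i0 = cfg$i0))
  write_artifact(list(
    stain_matrices = lapply(prepared$fits, `[[`, "w"),
    bin_spec = lapply(prepared$bin_spec, function(b)
      list(n_bins = b$n_bins, top_edge = max(b$edges)))
  ), cfg, seeds[1], file.path(cfg$out_dir, "separation.json"))

  pool <- run_stage("pool", build_pair_pool(prepared$hists, prepared$ids))

  s_max <- min(cfg$s_max, length(pool$dist$H[upper.tri(pool$dist$H)]))
  sweep <- run_stage("sweep",
    subset_sweep(pool, s_max = s_max, n_perms = cfg$n_perms,
                 seed = seeds[2]))
  fits_pl <- lapply(sweep$stains, function(s)
    fit_power_law(sweep$sizes, s$sd_per_size))
  sweep_tbl <- data.frame(
    size = sweep$sizes,
    sd_H = sweep$stains$H$sd_per_size,
    sd_E = sweep$stains$E$sd_per_size)
  write.csv(sweep_tbl, file.path(cfg$out_dir, "sweep.csv"),
            row.names = FALSE)
  curves <- compare_stain_curves(sweep_tbl$sd_H, sweep_tbl$sd_E)
  write_artifact(list(power_law = lapply(fits_pl, unclass),
                      stain_curve_pearson = curves),
                 cfg, seeds[2], file.path(cfg$out_dir, "sweep.json"))

  pareto <- run_stage("pareto", lapply(sweep$stains, function(s)
    pareto_optimal_size(s$sd_per_size, fraction = cfg$pareto_fraction,
                        convention = cfg$pareto_convention,
                        sizes = sweep$sizes)))
  write_artifact(list(pareto = lapply(pareto, function(p)
    list(optimal_size = p$optimal_size, convention = p$convention,
         optima = as.list(p$optima)))),
    cfg, seeds[2], file.path(cfg$out_dir, "pareto.json"))

  n_img <- length(prepared$ids)
  s_opt <- min(max(vapply(pareto, `[[`, numeric(1), "optimal_size")), n_img)
  ref <- run_stage("reference", {
    sel <- withr::with_seed(seeds[3], sample.int(n_img, s_opt))
    build_reference(prepared$fits[sel],
                    lapply(prepared$hists, function(hh) hh[sel]),
                    subset_ids = prepared$ids[sel])
  })
  write_artifact(list(w_op = ref$w_op,
                      h_op = lapply(ref$h_op, unclass),
                      subset_ids = ref$subset_ids, s_n = ref$s_n),
                 cfg, seeds[3], file.path(cfg$out_dir, "reference.json"))

  norm_dir <- file.path(cfg$out_dir, "normalized")
  run_stage("normalize", {
    dir.create(norm_dir, showWarnings = FALSE)
    for (k in seq_len(n_img)) {
      out <- normalize_image(images[[k]], ref, beta = cfg$beta,
                             lambda = cfg$sparsity_lambda,
                             fit = prepared$fits[[k]], i0 = cfg$i0)
      write_image(out, file.path(norm_dir,
                                 paste0(prepared$ids[k], ".png")))
    }
    message(sprintf("[stainref]   %d images normalized", n_img))
  })

  report <- run_stage("evaluate",
    convergence_experiment(images, subset_sizes = cfg$subset_sizes,
                           n_perms = cfg$eval_perms, seed = seeds[4],
                           prepared = prepared))
  write_report(report, file.path(cfg$out_dir, "report.json"))
  eval_tbl <- do.call(rbind, lapply(seq_along(report$subset_sizes),
                                    function(i) data.frame(
    size = report$subset_sizes[i],
    permutation = seq_along(report$sd_per_perm[[i]]),
    cohort_sd = unname(report$sd_per_perm[[i]]),
    range = unname(report$range_per_size[i]))))
  write.csv(eval_tbl, file.path(cfg$out_dir, "report.csv"),
            row.names = FALSE)

  invisible(list(pareto = pareto, power_law = fits_pl, curves = curves,
                 reference = ref, report = report, out_dir = cfg$out_dir))
}
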