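#' Experiment configuration
#'
#' Describes the full simulation workflow: rasterize (or load) a
#' phantom, simulate a densely sampled sinogram, decimate it to each
#' requested view count, optionally add relative Gaussian noise, run
#' each reconstruction method, and score the results against the ground
#' truth.
#'
#' @param phantom a [phantom_spec()] (default [default_phantom_spec()])
#'   or an [image_grid()].
#' @param full_views number of views in the densely sampled scan from
#'   which sparse sets are decimated (default 360 over 180 degrees).
#' @param n_detectors detector bins per view (default: image side).
#' @param detector_spacing detector pitch (default: pixel size).
#' @param view_counts view counts to sweep (default `seq(20, 120, 10)`).
#' @param methods subset of `c("fbp", "art", "sart", "tv", "cs")`
#'   (`"cs"` is the joint TV + wavelet method).
#' @param noise_level relative sinogram noise `||e||/||y||` (default 0).
#' @param seed experiment seed; per-stage noise seeds are derived from it.
#' @param fbp_filter ramp filter kind for FBP.
#' @param art,sart [algebraic_config()]s for the algebraic methods.
#' @param tv_lambda TV weight for the TV-only method.
#' @param cs [cs_config()] for the joint method.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = default_phantom_spec(),
                              full_views = 360, n_detectors = NULL,
                              detector_spacing = NULL,
                              view_counts = seq(20, 120, by = 10),
                              methods = c("fbp", "art", "sart", "tv", "cs"),
                              noise_level = 0, seed = 1L,
                              fbp_filter = "ram-lak",
                              art = algebraic_config(n_iterations = 30),
                              sart = algebraic_config(n_iterations = 150),
                              tv_lambda = 5e-4,
                              cs = cs_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(view_counts > full_views))
    stop("view_counts may not exceed full_views")
  structure(list(phantom = phantom, full_views = full_views,
                 n_detectors = n_detectors,
                 detector_spacing = detector_spacing,
                 view_counts = view_counts, methods = methods,
                 noise_level = noise_level, seed = as.integer(seed),
                 fbp_filter = fbp_filter, art = art, sart = sart,
                 tv_lambda = tv_lambda, cs = cs),
            class = "experiment_config")
}

reconstruct_method <- function(method, A, y, cfg) {
  switch(method,
    fbp = recon_result(
      fbp_reconstruct(y, A$side_px, A$pixel_size,
                      build_ramp_filter(cfg$fbp_filter,
                                        2L * y$geometry$n_detectors - 1L,
                                        y$geometry$detector_spacing)),
      numeric(0), "fbp", 0L, TRUE),
    art = art_reconstruct(A, y, cfg$art),
    sart = sart_reconstruct(A, y, cfg$sart),
    tv = tv_reconstruct(A, y, lambda = cfg$tv_lambda,
                        max_iterations = cfg$cs$max_iterations),
    cs = nlcg_reconstruct(A, y, cfg$cs),
    stop("unknown method: ", method))
}

#' Run a sparse-view reconstruction experiment
#'
#' Executes the pipeline described by an [experiment_config()] for every
#' (method, view count) pair and returns one metrics row per pair.  When
#' `outdir` is given, reconstructions (CSV images), the metrics table
#' (`metrics.csv`) and solver traces (`traces.csv`) are written there.
#' Runs are deterministic for a fixed config and seed.
#'
#' @param cfg an [experiment_config()].
#' @param outdir optional output directory (created if missing).
#' @param verbose print per-stage progress.
#' @return Invisibly, a data frame with columns `method`, `views`,
#'   `rrmse`, `si`, `ssim`.
#' @export
run_experiment <- function(cfg, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  truth <- if (inherits(cfg$phantom, "image_grid")) cfg$phantom
           else generate_phantom(cfg$phantom)
  n_det <- if (is.null(cfg$n_detectors)) truth$side_px else cfg$n_detectors
  d_sp <- if (is.null(cfg$detector_spacing)) truth$pixel_size
          else cfg$detector_spacing
  geom_full <- uniform_geometry(cfg$full_views, n_det, d_sp)
  if (verbose) message("simulating ", cfg$full_views, "-view sinogram")
  sino_full <- simulate_sinogram(truth, geom_full)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  rows <- list()
  traces <- list()
  for (nv in cfg$view_counts) {
    y <- decimate_views(sino_full, nv)
    if (cfg$noise_level > 0)
      y <- add_noise(y, cfg$noise_level, seed = cfg$seed + nv)
    A <- build_system_matrix(truth, y$geometry)
    for (method in cfg$methods) {
      if (verbose) message(method, " @ ", nv, " views")
      rec <- reconstruct_method(method, A, y, cfg)
      met <- evaluate_recon(rec$image, truth)
      rows[[length(rows) + 1]] <-
        data.frame(method = method, views = nv,
                   rrmse = met[["rrmse"]], si = met[["si"]],
                   ssim = met[["ssim"]])
      if (length(rec$trace))
        traces[[length(traces) + 1]] <-
          data.frame(method = method, views = nv,
                     iteration = seq_along(rec$trace) - 1,
                     value = rec$trace)
      if (!is.null(outdir))
        write_image(rec$image,
                    file.path(outdir, sprintf("recon_%s_%03d.csv", method, nv)))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(outdir)) {
    utils::write.csv(res, file.path(outdir, "metrics.csv"), row.names = FALSE)
    if (length(traces))
      utils::write.csv(do.call(rbind, traces),
                       file.path(outdir, "traces.csv"), row.names = FALSE)
  }
  invisible(res)
}
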