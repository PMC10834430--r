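#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config file accepted by
#' [run_pipeline()].  Unknown keys are rejected on load.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    population = list(n_shapes = 8, base_resolution = 1.5,
                      condyle_width_sd = 1.0, condyle_separation_sd = 1.8),
    degradation = list(spacing = 0.5, jitter_sd = 0.3, n_holes = 3,
                       hole_radius = 2, flip_prob = 0.02),
    ssm = list(n_points = 400, variance_fraction = 0.95,
               template_vertices = 1800, refine_iter = 40, refine_d = 2,
               fit = list(clamp_sigma = 3.0, lam_b = 1.0, tol = 1e-3,
                          max_iter = 50)),
    extrusion = list(enabled = TRUE, n_layers = 5, max_distance = 2.0,
                     element_size = 2.0, cartilage_thickness = 2.0),
    spm = list(alpha = 0.05)
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Values merge over [default_config()]; unknown keys raise an error.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, upd, prefix = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", prefix, nm)
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], upd[[nm]],
                                paste0(prefix, nm, "."))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  merge_cfg(cfg, user)
}

config_hash <- function(config) {
  # order-stable serialization -> simple polynomial hash (provenance tag)
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a shape population, builds the statistical shape model from all
#' but the last shape, degrades the held-out shape into a coarse
#' segmentation mask, adjusts it by fitting the model to the raw
#' marching-cubes surface, evaluates both surfaces against the ground
#' truth, and (optionally) extrudes a layered cartilage hex mesh on the
#' adjusted bone.  Deterministic given `config`.
#'
#' @param config a configuration list from [read_config()] (or a YAML path).
#' @return List with `adjusted_mesh`, `raw_mesh`, `metrics_adjusted`,
#'   `metrics_raw`, `model`, `hex` (or `NULL`), and `log` (stage timings,
#'   seeds, residuals, config hash).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  log <- list(config_hash = config_hash(config), seed = config$seed,
              stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    res
  }

  pop <- stage("synth_population", {
    pc <- config$population
    synth_population(PopulationSpec(
      n_shapes = pc$n_shapes,
      modes = list(condyle_width = c(12, pc$condyle_width_sd),
                   condyle_separation = c(26, pc$condyle_separation_sd)),
      base_resolution = pc$base_resolution, seed = config$seed))
  })
  n <- length(pop$meshes)
  train <- pop$meshes[seq_len(n - 1L)]
  gt <- pop$meshes[[n]]

  model <- stage("build_ssm", suppressWarnings(
    build_shape_model(train,
                      template_vertices = config$ssm$template_vertices,
                      n_points = config$ssm$n_points, seed = config$seed,
                      refine_iter = config$ssm$refine_iter,
                      refine_d = config$ssm$refine_d,
                      variance_fraction = config$ssm$variance_fraction)))

  mask <- stage("synth_degrade", {
    dc <- config$degradation
    synth_degrade(gt, DegradationSpec(spacing = dc$spacing,
                                      jitter_sd = dc$jitter_sd,
                                      n_holes = dc$n_holes,
                                      hole_radius = dc$hole_radius,
                                      flip_prob = dc$flip_prob,
                                      seed = config$seed + 1))
  })
  raw <- stage("mask_to_surface", mask_to_surface(mask))
  fit <- stage("ssm_fit", {
    fc <- config$ssm$fit
    ssm_fit(model, raw, clamp_sigma = fc$clamp_sigma, lam_b = fc$lam_b,
            tol = fc$tol, max_iter = fc$max_iter, seed = config$seed)
  })
  log$fit_residual_rms <- fit$residual_rms

  grid <- grid_from_mask(mask)
  metrics_raw <- stage("metrics_raw",
                       evaluate_segmentation(raw, gt, grid = grid))
  metrics_adj <- stage("metrics_adjusted",
                       evaluate_segmentation(fit$fitted_mesh, gt, grid = grid))

  hex <- NULL
  if (isTRUE(config$extrusion$enabled)) {
    hex <- stage("extrusion", {
      ec <- config$extrusion
      bone <- fit$fitted_mesh
      # synthetic articular target over the distal condylar region
      probe <- bone$vertices[which.min(bone$vertices[, 3]), , drop = FALSE]
      sel <- which(mesh_closest(
        (bone$vertices[bone$faces[, 1], ] + bone$vertices[bone$faces[, 2], ] +
           bone$vertices[bone$faces[, 3], ]) / 3,
        TriMesh(rbind(probe, probe + c(0, 0, 1e-3), probe + c(0, 1e-3, 0)),
                matrix(1:3, 1)))$dist < 12)
      art <- synth_cartilage_surface(bone, sel,
                                     thickness_profile = ec$cartilage_thickness)
      patch <- select_contact_patch(bone, art, max_distance = ec$max_distance +
                                      ec$cartilage_thickness)
      qp <- quad_patch(bone, patch, element_size = ec$element_size)
      extrude_cartilage(qp, art, n_layers = ec$n_layers)
    })
    log$hex_quality <- unclass(hex_quality(hex))
  }

  log$total_seconds <- round(proc.time()[3] - t_all, 2)
  out <- list(adjusted_mesh = fit$fitted_mesh, raw_mesh = raw,
              metrics_adjusted = metrics_adj, metrics_raw = metrics_raw,
              model = model, fit = fit, hex = hex, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mesh(fit$fitted_mesh, file.path(config$out_dir, "adjusted.ply"))
    write_mesh(raw, file.path(config$out_dir, "raw.ply"))
    save_ssm(model, file.path(config$out_dir, "model.json"))
    write_metrics_csv(metrics_adj,
                      file.path(config$out_dir, "metrics_adjusted.csv"))
    write_metrics_csv(metrics_raw, file.path(config$out_dir, "metrics_raw.csv"))
    if (!is.null(hex)) write_inp(hex, file.path(config$out_dir, "cartilage.inp"))
    jsonlite::write_json(log, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
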