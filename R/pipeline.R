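# End-to-end orchestration: simulate -> flow -> atlas -> associate, driven by
# one YAML config, with a machine-readable run report and per-stage outputs.
# Stages communicate only through files in the output directory, so deleting
# a downstream output and re-running that stage alone reproduces it.

#' Default pipeline configuration
#'
#' The full configuration tree with every default filled in: study size,
#' planted shape-mode structure, flow-phantom geometry and preprocessing
#' settings, ROI and diastolic-window parameters, atlas truncation fraction,
#' and the association settings. Defaults mirror the conventional study
#' setup: VENC 150 cm/s, 2.4 mm isotropic voxels, a +-2-frame diastolic
#' window, and a 90 percent variance truncation.
#'
#' @param output_dir run output directory.
#' @param seed integer root seed.
#' @return A nested list of class \code{"PipelineConfig"}.
#' @export
defaultPipelineConfig <- function(output_dir = file.path(tempdir(), "vortexatlas_run"),
                                  seed = 1) {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    n_subjects = 60L,
    stages = list(simulate = TRUE, flow = TRUE, atlas = TRUE, associate = TRUE),
    shape = list(points_per_surface = 120L, ring_size = 24L,
                 mode_variances = c(400, 144, 49, 25),
                 noise_sd = 0.1, pose_jitter_deg = 5, pose_jitter_mm = 5),
    association_betas = c(0, 0, 0.6, 0),
    covariate_betas = NULL,   # M x 4 matrix; NULL = small default effects
    score_noise_sd = 0.5,
    flow = list(grid_shape = c(24L, 24L, 24L), spacing_mm = 2.4,
                n_frames = 10L, frame_duration_ms = 38.8,
                diastole_frames = 4:9, venc_cms = 150,
                noise_sd_cms = 3, gamma0_cm2s = 100, gamma_scale = 0.25,
                core_radius_cm = 1.2, support_radius_cm = 2.0,
                envelope = "smooth", background_offset = c(2, 0.05),
                background_order = 1L, denoise = "gaussian",
                denoise_sd_voxels = 1),
    roi = list(radius_mm = 12, region = "RV_cavity"),
    window = list(half_width = 2L),
    atlas = list(variance_fraction = 0.90),
    alpha = 0.05,
    covariates = c("sex", "height", "weight", "age")
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Reads the file and overlays it on [defaultPipelineConfig()], so a config
#' only needs the fields it changes.
#'
#' @param path YAML file.
#' @return A \code{"PipelineConfig"} list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) .stopf("cannot parse config %s: %s",
                                              path, conditionMessage(e)))
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge2(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge2(unclass(defaultPipelineConfig()), user)
  structure(cfg, class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Checks every invariant the pipeline relies on and reports each violation
#' with a path into the config. An empty report means the config is valid.
#'
#' @param config a \code{"PipelineConfig"} (or a YAML path).
#' @return data.frame with columns \code{field} and \code{message}
#'   (zero rows when valid).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  v <- list()
  bad <- function(field, message) v[[length(v) + 1]] <<- data.frame(field = field, message = message)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(config$seed) || config$seed != round(config$seed))
    bad("seed", "must be a single integer")
  if (!num1(config$n_subjects) || config$n_subjects < 4)
    bad("n_subjects", "must be an integer >= 4")
  fr <- config$atlas$variance_fraction
  if (!num1(fr) || fr <= 0 || fr > 1)
    bad("atlas.variance_fraction", "must lie in (0, 1]")
  if (!num1(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    bad("alpha", "must lie in (0, 1)")
  if (!num1(config$shape$points_per_surface) || config$shape$points_per_surface < 50)
    bad("shape.points_per_surface", "must be >= 50")
  mv <- config$shape$mode_variances
  if (!is.numeric(mv) || any(mv <= 0) || is.unsorted(rev(mv)))
    bad("shape.mode_variances", "must be positive and non-increasing")
  if (length(config$association_betas) != length(mv))
    bad("association_betas", "must have one entry per shape mode variance")
  fl <- config$flow
  if (!is.numeric(fl$grid_shape) || length(fl$grid_shape) != 3 || any(fl$grid_shape < 8))
    bad("flow.grid_shape", "must be 3 dimensions, each >= 8")
  if (!num1(fl$spacing_mm) || fl$spacing_mm <= 0)
    bad("flow.spacing_mm", "must be positive")
  if (!num1(fl$venc_cms) || fl$venc_cms <= 0)
    bad("flow.venc_cms", "must be positive")
  if (any(fl$diastole_frames < 1) || any(fl$diastole_frames > fl$n_frames))
    bad("flow.diastole_frames", "must lie within 1..n_frames")
  if (!fl$denoise %in% c("none", "gaussian"))
    bad("flow.denoise", "must be 'none' or 'gaussian'")
  if (!num1(config$roi$radius_mm) || config$roi$radius_mm <= 0)
    bad("roi.radius_mm", "must be positive")
  if (!num1(config$window$half_width) || config$window$half_width < 0)
    bad("window.half_width", "must be a non-negative integer")
  missingCov <- setdiff(config$covariates, c("sex", "height", "weight", "age"))
  if (length(missingCov))
    bad("covariates", paste("unknown covariate(s):", paste(missingCov, collapse = ", ")))
  for (nm in c("roi_file", "plane_file")) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
      bad(nm, sprintf("file does not exist: %s", config[[nm]]))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(), message = character())
}

# Small default covariate effect matrix (M x 4): mild size effects on the
# first two modes, nothing elsewhere.
.defaultCovariateBetas <- function(M) {
  cb <- matrix(0, M, 4, dimnames = list(NULL, c("sex", "height", "weight", "age")))
  if (M >= 1) cb[1, c("height", "weight")] <- c(0.20, 0.10)
  if (M >= 2) cb[2, c("sex", "age")] <- c(0.20, -0.10)
  cb
}

.writeCsv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

# --- stages -----------------------------------------------------------------

.stageSimulate <- function(config, dir) {
  template <- generateTemplateShape(config$shape$points_per_surface,
                                    config$shape$ring_size)
  M <- length(config$shape$mode_variances)
  covBetas <- config$covariate_betas %||% .defaultCovariateBetas(M)
  truth <- makeGroundTruth(config$n_subjects, M,
                           association_betas = config$association_betas,
                           covariate_betas = covBetas)
  cv <- generateSubjectCovariates(config$n_subjects, truth,
                                  noise_sd = config$score_noise_sd,
                                  seed = subSeed(config$seed, 11))
  spec <- populationSpec(template, config$n_subjects,
                         mode_variances = config$shape$mode_variances,
                         noise_sd = config$shape$noise_sd,
                         pose_jitter_deg = config$shape$pose_jitter_deg,
                         pose_jitter_mm = config$shape$pose_jitter_mm,
                         seed = subSeed(config$seed, 12))
  pop <- generateShapePopulation(spec, truth = cv$truth)
  .writeCsv(cv$covariates, file.path(dir, "covariates.csv"))
  saveRDS(list(truth = pop$truth, mode_displacements = spec$mode_displacements,
               template = template),
          file.path(dir, "simulate_state.rds"))
  saveRDS(pop$shapes, file.path(dir, "shapes.rds"))
  list(outputs = c("covariates.csv", "simulate_state.rds", "shapes.rds"),
       params = config$shape)
}

.stageFlow <- function(config, dir) {
  cov <- utils::read.csv(file.path(dir, "covariates.csv"))
  fl <- config$flow
  central <- config$window$central_frame %||%
    fl$diastole_frames[ceiling(length(fl$diastole_frames) / 2)]
  dims <- as.integer(fl$grid_shape)
  ctr <- .gridCenter(dims, rep(fl$spacing_mm, 3))
  roi <- sphericalROI(ctr, config$roi$radius_mm, config$roi$region)
  rows <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    gamma_i <- fl$gamma0_cm2s * max(0.2, 1 + fl$gamma_scale * cov$predictor_std[i])
    spec <- flowPhantomSpec("lamb_oseen", dims, fl$spacing_mm, fl$n_frames,
                            fl$frame_duration_ms, fl$diastole_frames,
                            params = list(gamma = gamma_i, r_c = fl$core_radius_cm,
                                          support_radius = fl$support_radius_cm),
                            noise_sd = fl$noise_sd_cms, venc = fl$venc_cms,
                            seed = subSeed(config$seed, 1000 + i),
                            envelope = fl$envelope)
    field <- generateFlowPhantom(spec)
    # phase offset + aliasing, then the preprocessing chain undoes both
    off <- fl$background_offset
    if (!is.null(off) && any(off != 0)) {
      co <- .coordArrays(dims, rep(fl$spacing_mm, 3))
      plane <- off[1] + off[2] * co$x
      vals <- field@values
      for (t in seq_len(dim(vals)[5])) vals[, , , 1, t] <- vals[, , , 1, t] + plane
      field <- initialize(field, values = vals)
    }
    field <- wrapVelocity(field)
    field <- unwrapVelocity(field)
    co <- .coordArrays(dims, rep(fl$spacing_mm, 3))
    rho_cm <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2) / 10
    staticMask <- rho_cm > fl$support_radius_cm * 1.1
    field <- correctBackgroundPhase(field, staticMask, fl$background_order)
    if (fl$denoise == "gaussian")
      field <- denoiseVelocity(field, "gaussian", sd = fl$denoise_sd_voxels)
    curls <- lapply(fl$diastole_frames, function(t) computeCurlField(field, t))
    summ <- summarizeRoiVorticity(curls, roi)
    win <- windowedDiastolicAverage(summ, central, config$window$half_width,
                                    diastole_frames = fl$diastole_frames)
    rows[[i]] <- data.frame(id = cov$id[i], region = roi$region,
                            windowed_mean = win$windowed_mean,
                            windowed_max = win$windowed_max,
                            indexed_value = indexVorticity(win$windowed_mean, cov$bsa[i]),
                            frames_used = paste(win$frames_used, collapse = ";"))
  }
  .writeCsv(do.call(rbind, rows), file.path(dir, "vorticity.csv"))
  list(outputs = "vorticity.csv",
       params = c(fl, list(central_frame = central, roi = unclass(roi))))
}

.stageAtlas <- function(config, dir) {
  shapes <- readRDS(file.path(dir, "shapes.rds"))
  gpa <- generalizedProcrustesAlign(shapes)
  atlas <- buildShapeAtlas(gpa$shapes)
  K <- selectModeCount(atlas, config$atlas$variance_fraction)
  nModesRetained(atlas) <- K
  saveShapeAtlas(atlas, file.path(dir, "atlas.rds"))
  cov <- utils::read.csv(file.path(dir, "covariates.csv"))
  scores <- t(vapply(gpa$shapes, function(s) projectToAtlas(s, atlas, align = FALSE),
                     numeric(K)))
  df <- data.frame(id = cov$id, scores)
  names(df)[-1] <- paste0("mode", seq_len(K))
  .writeCsv(df, file.path(dir, "scores.csv"))
  list(outputs = c("atlas.rds", "scores.csv"),
       params = list(variance_fraction = config$atlas$variance_fraction, K = K,
                     gpa_iterations = gpa$iterations))
}

.stageAssociate <- function(config, dir) {
  cov <- utils::read.csv(file.path(dir, "covariates.csv"))
  sc <- utils::read.csv(file.path(dir, "scores.csv"))
  atlas <- readShapeAtlas(file.path(dir, "atlas.rds"))
  scores <- as.matrix(sc[, -1, drop = FALSE])
  vortPath <- file.path(dir, "vorticity.csv")
  if (file.exists(vortPath)) {
    vo <- utils::read.csv(vortPath)
    predictor <- vo$indexed_value[match(sc$id, vo$id)]
    predName <- "vorticity_indexed"
  } else {
    predictor <- cov$predictor_std[match(sc$id, cov$id)]
    predName <- "predictor_std"
  }
  assoc <- univariateModeAssociations(scores, predictor, alpha = config$alpha)
  tab <- assoc$table
  tab$family_size <- assoc$family_size
  .writeCsv(tab, file.path(dir, "associations.csv"))
  mm <- fitMorphometricMode(scores, predictor,
                            cov[match(sc$id, cov$id), c("sex", "height", "weight", "age")],
                            atlas, predictor_name = predName)
  reg <- data.frame(mode = seq_along(mm@betaPerMode), beta = mm@betaPerMode,
                    se = mm@betaSE, ci_lower = mm@betaCI[, 1],
                    ci_upper = mm@betaCI[, 2])
  .writeCsv(reg, file.path(dir, "regression.csv"))
  saveRDS(mm, file.path(dir, "morphometric.rds"))
  list(outputs = c("associations.csv", "regression.csv", "morphometric.rds"),
       params = list(alpha = config$alpha, predictor = predName,
                     covariates = config$covariates))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order (simulate, flow, atlas, associate),
#' writing each stage's outputs into the config's output directory plus a
#' machine-readable \code{report.json} (stage inputs, outputs, parameter
#' echo, seed, wall time). Numeric stage outputs (the CSV files) are
#' bit-reproducible for a fixed config and seed; the report's wall-clock
#' times are the only run-dependent field. A failing stage aborts with the
#' stage named and leaves a \code{FAILED_<stage>} marker beside any partial
#' outputs.
#'
#' @param config a \code{"PipelineConfig"} list or a YAML path.
#' @param stages optional character vector to run a subset (outputs of
#'   earlier stages must already exist in the output directory).
#' @return The run report, invisibly (list, also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  viol <- validateConfig(config)
  if (nrow(viol))
    .stopf("invalid config:\n%s",
           paste(sprintf("  %s: %s", viol$field, viol$message), collapse = "\n"))
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "flow", "atlas", "associate")
  enabled <- all_stages[vapply(all_stages, function(s) isTRUE(config$stages[[s]]), logical(1))]
  if (!is.null(stages)) enabled <- intersect(enabled, stages)
  runners <- list(simulate = .stageSimulate, flow = .stageFlow,
                  atlas = .stageAtlas, associate = .stageAssociate)
  report <- list(seed = config$seed, output_dir = dir, stages = list())
  for (s in enabled) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(runners[[s]](config, dir), error = function(e) e)
    if (inherits(res, "error")) {
      file.create(file.path(dir, paste0("FAILED_", s)))
      .stopf("pipeline stage '%s' failed: %s", s, conditionMessage(res))
    }
    report$stages[[s]] <- list(stage = s, outputs = res$outputs,
                               params = res$params, seed = config$seed,
                               wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
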