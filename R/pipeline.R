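#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run on one phantom (or
#' study): phantom generation, AIF selection ROI, the trained correction
#' network, deconvolution regularization and lesion thresholds.
#'
#' @param phantom A [phantom_config()].
#' @param seed Integer seed for the run.
#' @param model Optional trained [build_cnn()] model (required for the
#'   CNN-AIF branch).
#' @param lesion A [lesion_config()].
#' @param reg A [reg_config()].
#' @param scale CBF unit conversion (see [compute_cbf()]).
#' @param output_dir Optional directory for NIfTI/CSV/JSON outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(), seed = 1L,
                            model = NULL, lesion = lesion_config(),
                            reg = reg_config(), scale = 6000,
                            output_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(lesion, "lesion_config"),
            inherits(reg, "reg_config"))
  structure(list(phantom = phantom, seed = as.integer(seed), model = model,
                 lesion = lesion, reg = reg, scale = scale,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Default AIF search region for a phantom study
#'
#' The phantom's arterial block dilated in-plane by `margin` voxels,
#' clipped to the brain mask — a stand-in for the operator-drawn region
#' around the middle cerebral artery on patient data.
#'
#' @param study A [ctp_study()] with an artery mask.
#' @param margin In-plane dilation radius in voxels (default 2).
#' @return A 3D logical array.
#' @export
artery_roi <- function(study, margin = 2L) {
  m <- study$artery_mask
  if (is.null(m)) stop("study has no artery mask; supply an ROI", call. = FALSE)
  dims <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  out <- array(FALSE, dims)
  for (dx in -margin:margin) for (dy in -margin:margin) {
    xs <- pmin(pmax(idx[, 1] + dx, 1L), dims[1])
    ys <- pmin(pmax(idx[, 2] + dy, 1L), dims[2])
    out[cbind(xs, ys, idx[, 3])] <- TRUE
  }
  out & study$brain_mask
}

#' Run the perfusion pipeline on a phantom
#'
#' Generates the phantom, selects the measured AIF by recursive clustering,
#' optionally replaces it with the CNN-corrected gamma-shaped AIF, and
#' computes perfusion maps and thresholded lesion volumes.
#'
#' @param config A [pipeline_config()].
#' @param mode `"with_cnn_aif"` (requires `config$model`) or
#'   `"without_cnn_aif"`.
#' @param phantom Optional pre-generated phantom (list with `study`,
#'   `truth`) to reuse across modes; generated from `config` when `NULL`.
#' @return A list with `mode`, `truth`, `aif_candidates`, `aif_used`
#'   ([conc_curve()]), `maps`, `lesions`, `volumes_mL` (data.frame) and the
#'   true lesion volumes `true_core_mL`, `true_penumbra_mL`.
#' @export
run_pipeline <- function(config, mode = c("with_cnn_aif", "without_cnn_aif"),
                         phantom = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  mode <- match.arg(mode)
  if (mode == "with_cnn_aif" &&
      (is.null(config$model) || !isTRUE(config$model$trained)))
    stop("mode 'with_cnn_aif' needs a trained model in `config$model`; ",
         "train one with make_curve_bank() + build_cnn() + train_cnn()",
         call. = FALSE)
  if (is.null(phantom)) phantom <- generate_phantom(config$phantom, config$seed)
  study <- phantom$study
  cands <- select_aifs(study, artery_roi(study), seed = config$seed)
  aif_raw <- cands[[1]]$curve
  aif <- if (mode == "with_cnn_aif") predict_aif(config$model, aif_raw) else aif_raw
  maps <- compute_maps(study, aif, config$reg, config$scale)
  les <- segment_lesions(maps, study, config$lesion)
  voxel_mL <- prod(study$spacing) / 1000
  out <- list(mode = mode, truth = phantom$truth,
              aif_candidates = cands, aif_used = aif,
              maps = maps, lesions = les, volumes_mL = les$volumes_mL,
              true_core_mL = sum(phantom$truth$core_mask_true) * voxel_mL,
              true_penumbra_mL = sum(phantom$truth$penumbra_mask_true) * voxel_mL)
  if (!is.null(config$output_dir))
    write_pipeline_outputs(out, study, config, mode)
  out
}

#' Run both AIF branches on the same phantom
#'
#' Convenience wrapper generating one phantom and running [run_pipeline()]
#' with and without the CNN AIF, for paired comparison.
#'
#' @param config A [pipeline_config()] with a trained model.
#' @return A list with elements `with_cnn_aif` and `without_cnn_aif`.
#' @export
compare_aif_modes <- function(config) {
  phantom <- generate_phantom(config$phantom, config$seed)
  list(with_cnn_aif = run_pipeline(config, "with_cnn_aif", phantom),
       without_cnn_aif = run_pipeline(config, "without_cnn_aif", phantom))
}

# small polynomial rolling hash of the deparsed config, for sidecar provenance
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_pipeline_outputs <- function(result, study, config, mode) {
  dir <- file.path(config$output_dir, mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti_map(result$maps$cbf, study, file.path(dir, "cbf.nii.gz"))
  write_nifti_map(result$maps$tmax, study, file.path(dir, "tmax.nii.gz"))
  write_nifti_mask(result$lesions$core_mask, study, file.path(dir, "core_mask.nii.gz"))
  write_nifti_mask(result$lesions$penumbra_mask, study,
                   file.path(dir, "penumbra_mask.nii.gz"))
  vol <- result$volumes_mL
  vol$volume_mL <- round(vol$volume_mL, 1)
  utils::write.csv(vol, file.path(dir, "volumes.csv"), row.names = FALSE)
  write_curve_csv(result$aif_used, file.path(dir, "aif_used.csv"))
  sidecar <- list(mode = mode, seed = config$seed,
                  config_hash = config_hash(config[c("phantom", "lesion", "reg", "scale")]),
                  reg_method = config$reg$method,
                  scale = config$scale,
                  reference_cbf = result$lesions$reference_cbf,
                  aif_provenance = if (mode == "with_cnn_aif") "cnn" else "clustered")
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a 4D study or 3D map as NIfTI with a JSON sidecar
#'
#' @param study A [ctp_study()].
#' @param path Output `.nii`/`.nii.gz` path; the sidecar is written next to
#'   it with extension `.json`.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_study_nifti <- function(study, path, extra = list()) {
  stopifnot(inherits(study, "ctp_study"))
  img <- RNifti::asNifti(study$volume,
                         pixdim = c(study$spacing, stats::median(diff(study$times))))
  RNifti::writeNifti(img, path)
  sidecar <- c(list(times = study$times, spacing = study$spacing,
                    midline_axis = study$midline_axis), extra)
  jsonlite::write_json(sidecar, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study written by [write_study_nifti()]
#'
#' @param path NIfTI path with its JSON sidecar next to it.
#' @param brain_mask,artery_mask Optional masks (recomputed from the data
#'   if omitted: all voxels with any signal).
#' @return A [ctp_study()].
#' @export
read_study_nifti <- function(path, brain_mask = NULL, artery_mask = NULL) {
  vol <- as.array(RNifti::readNifti(path))
  sc <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                            simplifyVector = TRUE)
  if (is.null(brain_mask))
    brain_mask <- apply(abs(vol), 1:3, max) > 0
  ctp_study(vol, sc$times, sc$spacing, brain_mask, artery_mask,
            midline_axis = if (!is.null(sc$midline_axis)) sc$midline_axis else 1L)
}

write_nifti_map <- function(map, study, path) {
  RNifti::writeNifti(RNifti::asNifti(map, pixdim = study$spacing), path)
  invisible(path)
}

write_nifti_mask <- function(mask, study, path) {
  arr <- array(as.integer(mask), dim(mask))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = study$spacing), path,
                     datatype = "uint8")
  invisible(path)
}
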