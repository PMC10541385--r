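#' Lesion threshold configuration
#'
#' Core is thresholded on relative CBF (fraction of a normal-tissue
#' reference), penumbra on Tmax. Defaults carry the standard clinical
#' threshold families: core at rCBF < 20/30/38% with 30% primary, penumbra
#' at Tmax > 4/6/8/10 s with 6 s primary.
#'
#' @param core_rcbf_thresholds Fractions of the reference CBF.
#' @param penumbra_tmax_thresholds Seconds.
#' @param primary_core,primary_penumbra Primary thresholds; must be members
#'   of their families.
#' @return A list of class `lesion_config`.
#' @export
lesion_config <- function(core_rcbf_thresholds = c(0.20, 0.30, 0.38),
                          penumbra_tmax_thresholds = c(4, 6, 8, 10),
                          primary_core = 0.30, primary_penumbra = 6) {
  if (any(core_rcbf_thresholds <= 0) || any(penumbra_tmax_thresholds <= 0))
    stop("thresholds must be positive", call. = FALSE)
  if (!primary_core %in% core_rcbf_thresholds)
    stop("primary_core must be one of core_rcbf_thresholds", call. = FALSE)
  if (!primary_penumbra %in% penumbra_tmax_thresholds)
    stop("primary_penumbra must be one of penumbra_tmax_thresholds", call. = FALSE)
  structure(list(core_rcbf_thresholds = sort(core_rcbf_thresholds),
                 penumbra_tmax_thresholds = sort(penumbra_tmax_thresholds),
                 primary_core = primary_core,
                 primary_penumbra = primary_penumbra),
            class = "lesion_config")
}

#' Normal-tissue reference CBF
#'
#' "Relative CBF" needs a normal-tissue reference. The default rule takes
#' the median CBF of the hemisphere contralateral to the lesion — identified
#' as the hemisphere with the higher median CBF — restricted to voxels with
#' `Tmax <= tmax_limit` (i.e. not hypoperfused). If that region is empty the
#' whole-brain median is used and a warning is issued.
#'
#' @param maps A [perfusion_maps()][compute_maps] object.
#' @param study The [ctp_study()] the maps came from (for the midline axis).
#' @param tmax_limit Hypoperfusion exclusion threshold in s (default 6).
#' @return Reference CBF (mL/100 g/min) with attribute `hemisphere`.
#' @export
reference_cbf <- function(maps, study, tmax_limit = 6) {
  stopifnot(inherits(maps, "perfusion_maps"))
  ax <- study$midline_axis
  dims <- dim(maps$cbf)
  pos <- slice.index(maps$cbf, ax)
  half <- dims[ax] / 2
  ref_val <- NA_real_
  hemi <- NA_character_
  med_lo <- stats::median(maps$cbf[maps$mask & pos <= half])
  med_hi <- stats::median(maps$cbf[maps$mask & pos > half])
  contra <- if (isTRUE(med_lo >= med_hi)) pos <= half else pos > half
  sel <- maps$mask & contra & maps$tmax <= tmax_limit
  if (any(sel)) {
    ref_val <- stats::median(maps$cbf[sel])
    hemi <- if (isTRUE(med_lo >= med_hi)) "low" else "high"
  } else {
    warning("reference region empty; falling back to whole-brain median CBF",
            call. = FALSE)
    ref_val <- stats::median(maps$cbf[maps$mask])
    hemi <- "whole-brain"
  }
  structure(ref_val, hemisphere = hemi)
}

#' Segment core and penumbra and report volumes
#'
#' Core: `CBF < f * reference` for each rCBF fraction `f`; penumbra:
#' `Tmax > tau` for each threshold `tau`; both restricted to the brain mask,
#' strict inequalities. Volumes are voxel counts times voxel volume in mL.
#'
#' @param maps A [perfusion_maps()][compute_maps] object.
#' @param study The [ctp_study()] (for spacing and mask).
#' @param config A [lesion_config()].
#' @param reference Reference CBF from [reference_cbf()] (computed if `NULL`).
#' @return An object of class `lesion_result`: `core_mask` and
#'   `penumbra_mask` (3D logical at the primary thresholds), `volumes_mL`
#'   (data.frame with columns `label`, `volume_mL`), and `reference_cbf`.
#' @export
segment_lesions <- function(maps, study, config = lesion_config(),
                            reference = NULL) {
  stopifnot(inherits(maps, "perfusion_maps"), inherits(config, "lesion_config"))
  if (is.null(reference)) reference <- reference_cbf(maps, study,
                                                     config$primary_penumbra)
  ref <- as.numeric(reference)
  if (!is.finite(ref) || ref <= 0)
    stop("reference CBF must be positive", call. = FALSE)
  voxel_mL <- prod(study$spacing) / 1000
  rows <- list()
  core_mask <- NULL; pen_mask <- NULL
  for (f in config$core_rcbf_thresholds) {
    m <- maps$mask & (maps$cbf < f * ref)
    if (identical(f, config$primary_core)) core_mask <- m
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("CBF < %d%%", round(100 * f)),
      volume_mL = sum(m) * voxel_mL)
  }
  for (tau in config$penumbra_tmax_thresholds) {
    m <- maps$mask & (maps$tmax > tau)
    if (identical(tau, config$primary_penumbra)) pen_mask <- m
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("Tmax > %g s", tau),
      volume_mL = sum(m) * voxel_mL)
  }
  structure(list(core_mask = core_mask, penumbra_mask = pen_mask,
                 volumes_mL = do.call(rbind, rows),
                 reference_cbf = ref),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat("<lesion_result> reference CBF", round(x$reference_cbf, 1), "mL/100g/min\n")
  v <- x$volumes_mL
  v$volume_mL <- round(v$volume_mL, 1)
  print(v, row.names = FALSE)
  invisible(x)
}
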