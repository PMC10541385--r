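#' Automatic AIF selection by recursive cluster analysis
#'
#' Segments arterial voxels inside a region of interest by repeatedly
#' clustering the voxel time curves and keeping the most arterial-looking
#' cluster. Concretely, per round: voxels whose peak is below 20% of the ROI
#' maximum are excluded, remaining curves are normalised to unit area and
#' partitioned by k-means (k = 5); the cluster with the lowest mean first
#' moment (earliest, sharpest bolus) is kept and the procedure recurses on
#' it until at most `min_cluster_size` voxels remain or `max_rounds` rounds
#' have run. The final candidates are the surviving voxels with the highest
#' peak values.
#'
#' @param study A [ctp_study()].
#' @param roi 3D logical array selecting the search region (e.g. around the
#'   middle cerebral artery); must lie inside the brain mask.
#' @param n_aifs Number of candidates to return (default 3).
#' @param k Number of k-means clusters per round (default 5).
#' @param min_cluster_size Stop when at most this many voxels remain (default 10).
#' @param max_rounds Maximum recursion depth (default 5).
#' @param peak_frac Exclusion fraction of the ROI peak (default 0.2).
#' @param seed Integer seed for k-means initialisation.
#' @return A list of `aif_candidate` objects, ranked by peak value; each has
#'   `voxel_indices` (matrix of 1-based 3D indices), `curve`
#'   ([conc_curve()]), `first_moment` and `peak_value`.
#' @export
select_aifs <- function(study, roi, n_aifs = 3L, k = 5L,
                        min_cluster_size = 10L, max_rounds = 5L,
                        peak_frac = 0.2, seed = 1L) {
  stopifnot(inherits(study, "ctp_study"))
  if (!identical(dim(roi), dim(study$brain_mask)))
    stop("`roi` must match the study's spatial grid", call. = FALSE)
  roi <- roi & study$brain_mask
  vox <- which(roi)
  if (length(vox) == 0) stop("ROI is empty", call. = FALSE)

  dims <- dim(study$volume)
  flat <- matrix(study$volume, prod(dims[1:3]), dims[4])
  curves <- flat[vox, , drop = FALSE]
  peaks <- apply(curves, 1, max)
  keep <- peaks > peak_frac * max(peaks)
  vox <- vox[keep]; curves <- curves[keep, , drop = FALSE]; peaks <- peaks[keep]
  if (length(vox) < n_aifs)
    stop("too few eligible voxels with signal in the ROI", call. = FALSE)

  tt <- study$times
  fm <- function(m) {
    v <- pmax(m, 0)
    rs <- rowSums(v)
    ifelse(rs > 0, as.vector(v %*% tt) / rs, Inf)
  }
  set.seed(seed)
  rounds <- 0L
  while (length(vox) > min_cluster_size && rounds < max_rounds) {
    rounds <- rounds + 1L
    areas <- rowSums(pmax(curves, 0))
    norm <- curves / pmax(areas, 1e-12)
    kk <- min(k, nrow(unique(norm)))
    if (kk < 2) break
    cl <- stats::kmeans(norm, centers = kk, nstart = 3)
    moments <- fm(curves)
    mean_fm <- tapply(moments, cl$cluster, mean)
    # tie-break on curve roughness (sum of squared second differences)
    rough <- apply(curves, 1, function(v) sum(diff(v, differences = 2)^2))
    mean_rg <- tapply(rough, cl$cluster, mean)
    ord <- order(round(mean_fm, 10), mean_rg)
    best <- as.integer(names(mean_fm))[ord[1]]
    sel <- cl$cluster == best
    if (sum(sel) == 0 || sum(sel) == length(vox)) break
    vox <- vox[sel]; curves <- curves[sel, , drop = FALSE]
  }
  peaks <- apply(curves, 1, max)
  moments <- fm(curves)
  ord <- order(-peaks)
  take <- ord[seq_len(min(n_aifs, length(ord)))]
  lapply(take, function(i) {
    structure(list(
      voxel_indices = matrix(arrayInd(vox[i], dims[1:3]), ncol = 3,
                             dimnames = list(NULL, c("x", "y", "z"))),
      curve = conc_curve(tt, curves[i, ]),
      first_moment = moments[i],
      peak_value = peaks[i]),
      class = "aif_candidate")
  })
}

#' @export
print.aif_candidate <- function(x, ...) {
  cat(sprintf("<aif_candidate> voxel (%s), peak %.3g a.u., first moment %.2f s\n",
              paste(x$voxel_indices[1, ], collapse = ","),
              x$peak_value, x$first_moment))
  invisible(x)
}

#' Export AIF candidates to CSV
#'
#' Writes a summary table (voxel indices, first moment, peak) and one curve
#' CSV per candidate next to it.
#'
#' @param candidates List returned by [select_aifs()].
#' @param path Path of the summary CSV; per-candidate curves are written as
#'   `<path-sans-ext>_curve<i>.csv`.
#' @return `path`, invisibly.
#' @export
write_aif_candidates <- function(candidates, path) {
  tab <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    ca <- candidates[[i]]
    data.frame(candidate = i,
               x = ca$voxel_indices[1, 1], y = ca$voxel_indices[1, 2],
               z = ca$voxel_indices[1, 3],
               first_moment_s = ca$first_moment, peak = ca$peak_value)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  stem <- sub("\\.csv$", "", path)
  for (i in seq_along(candidates))
    write_curve_csv(candidates[[i]]$curve, sprintf("%s_curve%d.csv", stem, i))
  invisible(path)
}
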