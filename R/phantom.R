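#' Dynamic CTP study container
#'
#' Bundles a 4D dynamic CT perfusion acquisition (x, y, z, time attenuation
#' change in a.u.) with its acquisition times, voxel spacing, brain mask and
#' (for phantoms) the true arterial mask.
#'
#' @param volume 4D numeric array `(x, y, z, time)`.
#' @param times Acquisition time stamps (s), length `dim(volume)[4]`.
#' @param spacing Voxel size in mm, length 3, all > 0.
#' @param brain_mask 3D logical array matching the spatial grid.
#' @param artery_mask Optional 3D logical array, subset of `brain_mask`.
#' @param midline_axis Axis index (1-3) splitting the hemispheres (default 1).
#' @return An object of class `ctp_study`.
#' @export
ctp_study <- function(volume, times, spacing, brain_mask,
                      artery_mask = NULL, midline_axis = 1L) {
  dv <- dim(volume)
  if (length(dv) != 4) stop("`volume` must be a 4D array", call. = FALSE)
  if (dv[4] != length(times))
    stop("4th dimension of `volume` must match length(times)", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes (mm)", call. = FALSE)
  if (!identical(dim(brain_mask), dv[1:3]))
    stop("`brain_mask` must match the spatial grid", call. = FALSE)
  if (!is.null(artery_mask)) {
    if (!identical(dim(artery_mask), dv[1:3]))
      stop("`artery_mask` must match the spatial grid", call. = FALSE)
    if (any(artery_mask & !brain_mask))
      stop("`artery_mask` must be a subset of `brain_mask`", call. = FALSE)
  }
  structure(list(volume = volume, times = as.numeric(times),
                 spacing = as.numeric(spacing),
                 brain_mask = brain_mask, artery_mask = artery_mask,
                 midline_axis = as.integer(midline_axis)),
            class = "ctp_study")
}

#' @export
print.ctp_study <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<ctp_study> %dx%dx%d voxels x %d frames, dt=%g s, spacing %s mm, %d brain voxels\n",
              d[1], d[2], d[3], d[4], stats::median(diff(x$times)),
              paste(x$spacing, collapse = "x"), sum(x$brain_mask)))
  invisible(x)
}

#' Extract the concentration curve of one voxel
#'
#' @param study A [ctp_study()].
#' @param idx Integer vector of length 3, 1-based voxel index.
#' @return A [conc_curve()].
#' @export
voxel_curve <- function(study, idx) {
  conc_curve(study$times, study$volume[idx[1], idx[2], idx[3], ])
}

#' Phantom configuration
#'
#' Defines the digital perfusion phantom: grid, acquisition, arterial bolus,
#' the ellipsoidal penumbra/core lesion and its tissue values, and noise.
#' Tissue classes follow typical stroke physiology: healthy tissue
#' CBF 60 mL/100g/min, MTT 4 s, no delay; penumbra CBF 30, MTT 8 s, delay
#' 8 s; core CBF 12, MTT 12 s, delay 10 s — so that the standard thresholds
#' (Tmax > 6 s, relative CBF < 30%) recover the built-in lesion geometry.
#'
#' @param dims Spatial grid, default `c(64, 64, 4)`.
#' @param n_frames Number of time frames, default 90 (covers bolus washout,
#'   which keeps the deconvolution problem well-posed).
#' @param dt Frame interval in seconds, default 1.
#' @param spacing Voxel size in mm, default `c(3, 3, 10)`.
#' @param aif_params [gamma_params()] of the clean first passage; default
#'   `AT = 5 s`, `alpha = 3`, `beta = 1.5 s`, amplitude scaled to peak 10 a.u.
#' @param recirc_delay,recirc_frac,recirc_beta Recirculation passage: a second
#'   gamma variate delayed `recirc_delay` s after the first-pass arrival
#'   (default 25 s) at `recirc_frac` of the first-pass peak (default 0.2),
#'   with a broader decay constant `recirc_beta` (default 3 s).
#' @param residue_model `"exp"` (default, `R(t) = exp(-t/MTT)`) or `"boxcar"`.
#' @param healthy,penumbra,core Named lists with `cbf` (mL/100g/min), `mtt`
#'   (s) and `delay` (s) per tissue class.
#' @param lesion_center Ellipsoid centre in voxel coordinates (default lateral
#'   in the x > midline hemisphere).
#' @param penumbra_radii,core_radii Ellipsoid semi-axes in voxels.
#' @param lesion_scale Multiplier on both radii vectors (cohort size variation).
#' @param noise_sd Additive Gaussian noise SD in a.u. (default 0.02).
#' @param aif_distortion Optional [distortion_params()] applied to the AIF
#'   written into the arterial voxels (the "measured" AIF); ground truth
#'   keeps the clean curve.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(64, 64, 4),
                           n_frames = 90, dt = 1,
                           spacing = c(3, 3, 10),
                           aif_params = NULL,
                           recirc_delay = 25, recirc_frac = 0.2, recirc_beta = 3,
                           residue_model = c("exp", "boxcar"),
                           healthy = list(cbf = 60, mtt = 4, delay = 0),
                           penumbra = list(cbf = 30, mtt = 8, delay = 8),
                           core = list(cbf = 12, mtt = 12, delay = 10),
                           lesion_center = c(44, 32, (dims[3] + 1) / 2),
                           penumbra_radii = c(10, 12, 1.6),
                           core_radii = c(5, 6, 1.1),
                           lesion_scale = 1,
                           noise_sd = 0.02,
                           aif_distortion = NULL) {
  if (is.null(aif_params)) {
    K <- 10 / ((3 * 1.5)^3 * exp(-3))  # first-pass peak = 10 a.u.
    aif_params <- gamma_params(K, 5, 3, 1.5)
  }
  structure(list(dims = dims, n_frames = n_frames, dt = dt, spacing = spacing,
                 aif_params = aif_params, recirc_delay = recirc_delay,
                 recirc_frac = recirc_frac, recirc_beta = recirc_beta,
                 residue_model = match.arg(residue_model),
                 healthy = healthy, penumbra = penumbra, core = core,
                 lesion_center = lesion_center,
                 penumbra_radii = penumbra_radii * lesion_scale,
                 core_radii = core_radii * lesion_scale,
                 noise_sd = noise_sd, aif_distortion = aif_distortion),
            class = "phantom_config")
}

# clean AIF = gamma first passage + delayed, dispersed recirculation gamma
clean_aif <- function(config, times) {
  p <- config$aif_params
  first <- gamma_eval(times, p$K, p$AT, p$alpha, p$beta)
  pk <- gamma_peak_value(p)
  K2 <- config$recirc_frac * pk /
    ((p$alpha * config$recirc_beta)^p$alpha * exp(-p$alpha))
  rec <- gamma_eval(times, K2, p$AT + config$recirc_delay, p$alpha,
                    config$recirc_beta)
  conc_curve(times, first + rec)
}

ellipsoid_mask <- function(dims, center, radii) {
  x <- (seq_len(dims[1]) - center[1]) / radii[1]
  y <- (seq_len(dims[2]) - center[2]) / radii[2]
  z <- (seq_len(dims[3]) - center[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate a seeded digital CTP phantom with ground truth
#'
#' Builds a 4D dynamic volume in which every tissue voxel carries
#' `C(t) = (CBF/6000) * dt-convolution(Ca, R)(t)` with the residue `R`
#' (exponential or boxcar, time constant MTT) shifted by the tissue delay;
#' arterial voxels carry the clean AIF (first passage plus recirculation),
#' optionally distorted by `config$aif_distortion` to emulate measurement
#' error. Additive Gaussian noise is applied inside the brain mask.
#' Identical seeds give bit-identical phantoms.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A list with elements `study` ([ctp_study()]) and `truth` — a list
#'   with 3D maps `cbf_true`, `mtt_true`, `delay_true`, masks
#'   `core_mask_true`, `penumbra_mask_true`, the clean `aif_clean`
#'   ([conc_curve()]) and its `aif_params`.
#' @examples
#' ph <- generate_phantom(phantom_config(dims = c(16, 16, 2)), seed = 1)
#' @export
generate_phantom <- function(config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$dims
  times <- seq(0, by = config$dt, length.out = config$n_frames)
  ca <- clean_aif(config, times)

  # brain = in-plane ellipse through all slices
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  brain2d <- outer(((seq_len(dims[1]) - cx) / (0.47 * dims[1]))^2,
                   ((seq_len(dims[2]) - cy) / (0.47 * dims[2]))^2, `+`) <= 1
  brain <- array(brain2d, dim = dims)

  pen <- ellipsoid_mask(dims, config$lesion_center, config$penumbra_radii) & brain
  core <- ellipsoid_mask(dims, config$lesion_center, config$core_radii) & brain
  core <- core & pen
  if (!any(pen)) stop("lesion lies outside the brain mask", call. = FALSE)
  lesion_all <- ellipsoid_mask(dims, config$lesion_center, config$penumbra_radii)
  if (sum(lesion_all & !brain) > 0.5 * sum(lesion_all))
    stop("lesion lies mostly outside the brain mask; adjust lesion_center/radii",
         call. = FALSE)

  # artery block in the contralateral hemisphere
  art <- array(FALSE, dims)
  ax <- pmax(1, round(dims[1] * 0.25)); ay <- round(dims[2] / 2)
  az <- pmax(1L, min(dims[3], ceiling(dims[3] / 2)))
  art[ax + (-1:1), ay + (-1:1), az] <- TRUE
  art <- art & brain

  # per-class tissue curves
  tissue_curve <- function(cls) {
    FF <- cls$cbf / 6000  # mL/100g/min -> 1/s (per-100g, per-minute units)
    r <- residue_eval(times, cls$mtt, cls$delay, config$residue_model)
    conv_discrete(ca$values, FF * r, config$dt)
  }
  cur_h <- tissue_curve(config$healthy)
  cur_p <- tissue_curve(config$penumbra)
  cur_c <- tissue_curve(config$core)

  measured_aif <- if (!is.null(config$aif_distortion)) {
    distort_aif(ca, config$aif_distortion, seed = seed + 101L)$values
  } else ca$values

  nvox <- prod(dims)
  vol <- matrix(0, nvox, config$n_frames)
  class_idx <- integer(nvox)          # 0 air, 1 healthy, 2 penumbra, 3 core, 4 artery
  class_idx[which(brain)] <- 1L
  class_idx[which(pen)] <- 2L
  class_idx[which(core)] <- 3L
  class_idx[which(art)] <- 4L
  vol[class_idx == 1L, ] <- matrix(cur_h, sum(class_idx == 1L), config$n_frames, byrow = TRUE)
  vol[class_idx == 2L, ] <- matrix(cur_p, sum(class_idx == 2L), config$n_frames, byrow = TRUE)
  vol[class_idx == 3L, ] <- matrix(cur_c, sum(class_idx == 3L), config$n_frames, byrow = TRUE)
  vol[class_idx == 4L, ] <- matrix(measured_aif, sum(class_idx == 4L), config$n_frames, byrow = TRUE)

  if (config$noise_sd > 0) {
    set.seed(seed)
    inb <- which(class_idx > 0L)
    vol[inb, ] <- vol[inb, ] +
      matrix(stats::rnorm(length(inb) * config$n_frames, 0, config$noise_sd),
             length(inb), config$n_frames)
  }
  vol4d <- array(vol, dim = c(dims, config$n_frames))

  cbf_true <- array(0, dims); mtt_true <- array(0, dims); delay_true <- array(0, dims)
  for (cls in list(list(m = class_idx == 1L, v = config$healthy),
                   list(m = class_idx == 2L, v = config$penumbra),
                   list(m = class_idx == 3L, v = config$core))) {
    cbf_true[cls$m] <- cls$v$cbf
    mtt_true[cls$m] <- cls$v$mtt
    delay_true[cls$m] <- cls$v$delay
  }
  cbf_true[class_idx == 4L] <- config$healthy$cbf
  mtt_true[class_idx == 4L] <- config$healthy$mtt

  study <- ctp_study(vol4d, times, config$spacing, brain, art, midline_axis = 1L)
  truth <- list(cbf_true = cbf_true, mtt_true = mtt_true,
                delay_true = delay_true,
                core_mask_true = core, penumbra_mask_true = pen,
                aif_clean = ca, aif_params = config$aif_params,
                config = config, seed = seed)
  list(study = study, truth = truth)
}

residue_eval <- function(times, mtt, delay, model) {
  tt <- times - delay
  if (model == "exp") {
    r <- ifelse(tt >= 0, exp(-pmax(tt, 0) / mtt), 0)
  } else {
    r <- as.numeric(tt >= 0 & tt < mtt)
  }
  r
}

# causal discrete convolution, rectangle rule, truncated to length(ca)
conv_discrete <- function(ca, r, dt) {
  n <- length(ca)
  out <- stats::convolve(ca, rev(r), type = "open")[seq_len(n)] * dt
  out
}

#' AIF distortion parameters
#'
#' The three distortion classes seen in measured AIF curves: a drifting,
#' noisy baseline; amplitude error in the first passage; and a recirculation
#' passage that differs from curve to curve. All-zero strengths (and
#' `peak_attenuation = 1`) leave the curve unchanged.
#'
#' @param baseline_slope Linear baseline drift (a.u./s), default 0.
#' @param baseline_noise_sd Baseline noise SD (a.u.), default 0.
#' @param peak_attenuation Multiplicative factor in (0, 1] on the first-pass
#'   amplitude, default 1.
#' @param recirc_amplitude If > 0, the recirculation portion is replaced by a
#'   gamma bump with this peak as a fraction of the first-pass peak; 0 keeps
#'   the original recirculation.
#' @param recirc_delay Arrival of the replacement recirculation after the end
#'   of the first passage (s), default 10.
#' @param recirc_jitter SD of the random shift applied to the replacement
#'   recirculation arrival (s), default 0.
#' @return A list of class `distortion_params`.
#' @export
distortion_params <- function(baseline_slope = 0, baseline_noise_sd = 0,
                              peak_attenuation = 1, recirc_amplitude = 0,
                              recirc_delay = 10, recirc_jitter = 0) {
  if (peak_attenuation <= 0 || peak_attenuation > 1)
    stop("peak_attenuation must be in (0, 1]", call. = FALSE)
  if (baseline_noise_sd < 0 || recirc_amplitude < 0 || recirc_jitter < 0)
    stop("amplitudes and jitter must be >= 0", call. = FALSE)
  structure(list(baseline_slope = baseline_slope,
                 baseline_noise_sd = baseline_noise_sd,
                 peak_attenuation = peak_attenuation,
                 recirc_amplitude = recirc_amplitude,
                 recirc_delay = recirc_delay,
                 recirc_jitter = recirc_jitter),
            class = "distortion_params")
}

#' Distort an AIF curve
#'
#' Applies, in order: first-pass amplitude attenuation, recirculation
#' replacement (if `recirc_amplitude > 0`), then baseline drift and noise
#' over the whole curve. The output is clipped at zero only where noise
#' drives it negative.
#'
#' @param curve A [conc_curve()].
#' @param d A [distortion_params()].
#' @param seed Integer seed for the stochastic parts (baseline noise,
#'   recirculation jitter).
#' @return A [conc_curve()] on the same time grid.
#' @export
distort_aif <- function(curve, d, seed = 1L) {
  assert_curve(curve)
  stopifnot(inherits(d, "distortion_params"))
  tt <- curve$times
  v <- curve$values
  fp <- first_passage(curve)
  pk <- v[fp$peak]

  if (d$peak_attenuation < 1)
    v[seq_len(fp$end)] <- v[seq_len(fp$end)] * d$peak_attenuation

  set.seed(seed)
  if (d$recirc_amplitude > 0) {
    shift <- if (d$recirc_jitter > 0) stats::rnorm(1, 0, d$recirc_jitter) else 0
    at2 <- fp$t_end + d$recirc_delay + shift
    alpha2 <- 3; beta2 <- 3
    K2 <- d$recirc_amplitude * pk / ((alpha2 * beta2)^alpha2 * exp(-alpha2))
    bump <- gamma_eval(tt, K2, max(at2, fp$t_end), alpha2, beta2)
    if (fp$end < length(tt)) {
      tail_idx <- seq(fp$end + 1L, length(tt))
      v[tail_idx] <- v[fp$end] * exp(-(tt[tail_idx] - fp$t_end) / 10) +
        bump[tail_idx]
    }
  }
  drift <- d$baseline_slope * tt
  noise <- if (d$baseline_noise_sd > 0)
    stats::rnorm(length(tt), 0, d$baseline_noise_sd) else 0
  out <- v + drift + noise
  conc_curve(tt, pmax(out, 0))
}

#' Synthetic clinical scores from phantom ground truth
#'
#' Emulates the monotone relationships between lesion volume and clinical
#' severity: NIHSS (0-42) increases with penumbra volume, ASPECTS (10 =
#' normal) decreases with core volume.
#'
#' @param truth Phantom `truth` list from [generate_phantom()].
#' @param noise_sd SD of the additive score noise before rounding/clamping.
#' @param seed Integer seed.
#' @param a NIHSS points per mL of penumbra (default 0.15).
#' @param b ASPECTS points lost per mL of core (default 0.2).
#' @return A list with `nihss`, `aspects`, `penumbra_mL`, `core_mL`.
#' @export
synth_clinical_scores <- function(truth, noise_sd = 0, seed = 1L,
                                  a = 0.15, b = 0.2) {
  voxel_mL <- prod(truth$config$spacing) / 1000
  pen_mL <- sum(truth$penumbra_mask_true) * voxel_mL
  core_mL <- sum(truth$core_mask_true) * voxel_mL
  set.seed(seed)
  e1 <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  e2 <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  nihss <- min(max(round(a * pen_mL + e1), 0), 42)
  aspects <- min(max(10 - round(b * core_mL + e2), 0), 10)
  list(nihss = as.integer(nihss), aspects = as.integer(aspects),
       penumbra_mL = pen_mL, core_mL = core_mL)
}
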