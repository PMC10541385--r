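#' Resample a curve to a fixed length by cubic spline
#'
#' Cubic-spline interpolation onto `n_points` uniformly spaced samples
#' spanning the curve's time range. Endpoints are reproduced exactly and
#' polynomials up to degree 3 are preserved.
#'
#' @param curve A [conc_curve()] with at least 4 samples.
#' @param n_points Output length (default 500).
#' @return A [conc_curve()] of length `n_points`.
#' @export
interpolate_curve <- function(curve, n_points = 500L) {
  assert_curve(curve)
  if (length(curve$times) < 4)
    stop("need at least 4 samples to spline-interpolate", call. = FALSE)
  tt <- seq(curve$times[1], curve$times[length(curve$times)],
            length.out = n_points)
  vv <- stats::spline(curve$times, curve$values, xout = tt, method = "fmm")$y
  conc_curve(tt, vv)
}

#' Training pair for the AIF-correction network
#'
#' Holds a distorted input curve and its gamma-fitted label, both resampled
#' onto the same fixed-length grid.
#'
#' @param times Fixed-length uniform grid (s).
#' @param input Distorted curve values on `times`.
#' @param label Gamma-variate fitted curve values on `times` (nonnegative).
#' @return An object of class `curve_pair`.
#' @export
curve_pair <- function(times, input, label) {
  if (length(times) != length(input) || length(input) != length(label))
    stop("times, input and label must have equal length", call. = FALSE)
  if (any(label < 0)) stop("label curve must be nonnegative", call. = FALSE)
  structure(list(times = as.numeric(times), input = as.numeric(input),
                 label = as.numeric(label)),
            class = "curve_pair")
}

#' Augment curve pairs by mirroring and rotation
#'
#' Each source pair yields exactly three augmented pairs: mirrored, rotated,
#' and mirrored-then-rotated, with input and label transformed identically.
#' Mirroring is time reversal of the sampled curve (an exact involution).
#' Rotation turns the normalised (t, value) polyline by an angle drawn
#' uniformly from +/- `max_angle` degrees about its centroid and
#' re-interpolates onto the original grid, clipping negative values.
#'
#' @param pairs Non-empty list of [curve_pair()] objects.
#' @param seed Integer seed for the rotation angles.
#' @param max_angle Maximum rotation angle in degrees (default 5).
#' @param include_originals Prepend the unaugmented pairs (default `FALSE`,
#'   so 384 sources yield exactly 1152 pairs).
#' @return A list of [curve_pair()] objects of length `3 * length(pairs)`
#'   (plus the originals if requested).
#' @export
augment_pairs <- function(pairs, seed = 1L, max_angle = 5,
                          include_originals = FALSE) {
  if (length(pairs) == 0) stop("`pairs` must be non-empty", call. = FALSE)
  set.seed(seed)
  out <- vector("list", 3L * length(pairs))
  k <- 0L
  for (p in pairs) {
    ang1 <- stats::runif(1, -max_angle, max_angle)
    ang2 <- stats::runif(1, -max_angle, max_angle)
    mir <- curve_pair(p$times, rev(p$input), rev(p$label))
    rot <- rotate_pair(p, ang1)
    mirrot <- rotate_pair(mir, ang2)
    out[[k + 1L]] <- mir; out[[k + 2L]] <- rot; out[[k + 3L]] <- mirrot
    k <- k + 3L
  }
  if (include_originals) out <- c(pairs, out)
  out
}

rotate_curve_values <- function(tt, vv, angle_deg) {
  vmax <- max(abs(vv))
  if (vmax == 0) return(vv)
  t0 <- tt[1]; tspan <- tt[length(tt)] - t0
  x <- (tt - t0) / tspan
  y <- vv / vmax
  th <- angle_deg * pi / 180
  cx <- mean(x); cy <- mean(y)
  xr <- cx + (x - cx) * cos(th) - (y - cy) * sin(th)
  yr <- cy + (x - cx) * sin(th) + (y - cy) * cos(th)
  ord <- order(xr)
  out <- stats::approx(xr[ord], yr[ord], xout = x, rule = 2, ties = mean)$y
  # clip rotation-induced negatives without lifting samples that were
  # already negative (keeps zero rotation an exact identity)
  pmax(out * vmax, min(0, min(vv)))
}

rotate_pair <- function(p, angle_deg) {
  curve_pair(p$times,
             rotate_curve_values(p$times, p$input, angle_deg),
             rotate_curve_values(p$times, p$label, angle_deg))
}

#' CNN configuration
#'
#' Architecture and training settings of the 1D curve-regression network:
#' input (interpolated AIF curve, 500 points) -> conv(kernel 2, ReLU) ->
#' conv(kernel 2, ReLU) -> average pooling -> flatten -> dense(36) ->
#' output(input_length) with softmax. The softmax output is read as a
#' normalised curve shape; training minimises the cross-entropy between it
#' and the unit-sum gamma-fit label (reported as KL divergence, which is
#' zero at a perfect fit).
#'
#' @param input_length Curve length (default 500).
#' @param conv_kernel Convolution kernel length (default 2).
#' @param conv_filters Filters per conv layer (default `c(8, 16)`).
#' @param pool_size Average-pooling width/stride (default 2).
#' @param dense_units Hidden dense layer width (default 36).
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate RMSprop learning rate (default 0.001).
#' @param rho RMSprop decay (default 0.9).
#' @param seed Integer seed for initialisation and shuffling.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(input_length = 500L, conv_kernel = 2L,
                       conv_filters = c(8L, 16L), pool_size = 2L,
                       dense_units = 36L, epochs = 300L, batch_size = 32L,
                       learning_rate = 0.001, rho = 0.9, seed = 1L) {
  if (input_length < 4) stop("input_length must be >= 4", call. = FALSE)
  if (length(conv_filters) != 2 || any(conv_filters < 1))
    stop("conv_filters must be two positive counts", call. = FALSE)
  conv_out <- input_length - 2L * (conv_kernel - 1L)
  if (conv_out < pool_size)
    stop("pooling window larger than the convolved sequence", call. = FALSE)
  structure(list(input_length = as.integer(input_length),
                 conv_kernel = as.integer(conv_kernel),
                 conv_filters = as.integer(conv_filters),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the untrained AIF-correction network
#'
#' Initialises all weights (Glorot uniform, seeded: identical seeds give
#' identical initial weights) for the architecture described in
#' [cnn_config()].
#'
#' @param config A [cnn_config()].
#' @return An object of class `aif_cnn` with the parameter list, the
#'   parameter count (`n_params`) and `trained = FALSE`.
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  set.seed(config$seed)
  k <- config$conv_kernel
  f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
  L <- config$input_length
  Lp <- (L - 2L * (k - 1L)) %/% config$pool_size
  nf <- Lp * f2
  params <- list(
    W1 = glorot(k, f1, k, k * f1), b1 = numeric(f1),
    W2 = glorot(k * f1, f2, k * f1, k * f2), b2 = numeric(f2),
    Wd1 = glorot(nf, config$dense_units, nf, config$dense_units),
    bd1 = numeric(config$dense_units),
    Wd2 = glorot(config$dense_units, L, config$dense_units, L),
    bd2 = numeric(L))
  n_params <- sum(vapply(params, length, integer(1)))
  structure(list(config = config, params = params,
                 n_params = n_params, trained = FALSE,
                 history = NULL),
            class = "aif_cnn")
}

#' @export
print.aif_cnn <- function(x, ...) {
  cat(sprintf("<aif_cnn> input %d, conv %d/%d (k=%d), pool %d, dense %d -> %d; %s; %d parameters\n",
              x$config$input_length, x$config$conv_filters[1],
              x$config$conv_filters[2], x$config$conv_kernel,
              x$config$pool_size, x$config$dense_units,
              x$config$input_length,
              if (x$trained) "trained" else "untrained", x$n_params))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns intermediates for backprop
cnn_forward <- function(params, x, config) {
  B <- nrow(x); L <- config$input_length
  f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
  L1 <- L - 1L; L2 <- L - 2L; P <- L2 %/% config$pool_size
  Xc <- cbind(as.vector(x[, 1:L1, drop = FALSE]),
              as.vector(x[, 2:L, drop = FALSE]))
  Z1 <- sweep(Xc %*% params$W1, 2, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  a1 <- array(A1, c(B, L1, f1))
  X2 <- cbind(matrix(a1[, 1:L2, , drop = FALSE], B * L2, f1),
              matrix(a1[, 2:L1, , drop = FALSE], B * L2, f1))
  Z2 <- sweep(X2 %*% params$W2, 2, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  a2 <- array(A2, c(B, L2, f2))
  odd <- seq(1L, 2L * P, by = 2L); even <- odd + 1L
  ap <- (a2[, odd, , drop = FALSE] + a2[, even, , drop = FALSE]) / 2
  Fm <- matrix(ap, B, P * f2)
  H <- pmax(sweep(Fm %*% params$Wd1, 2, params$bd1, `+`), 0)
  O <- sweep(H %*% params$Wd2, 2, params$bd2, `+`)
  Pr <- softmax_rows(O)
  list(Xc = Xc, A1 = A1, X2 = X2, A2 = A2, Fm = Fm, H = H, prob = Pr,
       B = B, L = L, L1 = L1, L2 = L2, P = P, f1 = f1, f2 = f2,
       odd = odd, even = even)
}

cnn_backward <- function(params, fw, target) {
  B <- fw$B
  dO <- (fw$prob - target) / B
  g <- list()
  g$Wd2 <- crossprod(fw$H, dO); g$bd2 <- colSums(dO)
  dH <- (dO %*% t(params$Wd2)) * (fw$H > 0)
  g$Wd1 <- crossprod(fw$Fm, dH); g$bd1 <- colSums(dH)
  dF <- dH %*% t(params$Wd1)
  dap <- array(dF, c(B, fw$P, fw$f2)) / 2
  da2 <- array(0, c(B, fw$L2, fw$f2))
  da2[, fw$odd, ] <- dap
  da2[, fw$even, ] <- dap
  dZ2 <- matrix(da2, B * fw$L2, fw$f2) * (fw$A2 > 0)
  g$W2 <- crossprod(fw$X2, dZ2); g$b2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(params$W2)
  da1 <- array(0, c(B, fw$L1, fw$f1))
  da1[, 1:fw$L2, ] <- da1[, 1:fw$L2, , drop = FALSE] +
    array(dX2[, 1:fw$f1, drop = FALSE], c(B, fw$L2, fw$f1))
  da1[, 2:fw$L1, ] <- da1[, 2:fw$L1, , drop = FALSE] +
    array(dX2[, fw$f1 + 1:fw$f1, drop = FALSE], c(B, fw$L2, fw$f1))
  dZ1 <- matrix(da1, B * fw$L1, fw$f1) * (fw$A1 > 0)
  g$W1 <- crossprod(fw$Xc, dZ1); g$b1 <- colSums(dZ1)
  g
}

# mean KL(target || prob): cross-entropy minus target entropy, >= 0
kl_loss <- function(prob, target) {
  eps <- 1e-12
  ce <- -rowSums(target * log(prob + eps))
  ent <- -rowSums(ifelse(target > 0, target * log(target + eps), 0))
  mean(ce - ent)
}

# normalisation conventions shared by training and prediction
normalize_input <- function(m) m / pmax(apply(abs(m), 1, max), 1e-12)
normalize_label <- function(m) m / pmax(rowSums(m), 1e-12)

#' Train the AIF-correction network
#'
#' Minibatch RMSprop on the KL divergence between the softmax output and the
#' unit-sum gamma-fit labels. Inputs are peak-normalised, labels sum-
#' normalised. Reproducible for a given `config$seed`.
#'
#' @param model An `aif_cnn` from [build_cnn()].
#' @param pairs List of [curve_pair()] objects (>= one batch).
#' @param epochs Override of `config$epochs` (optional).
#' @param verbose Print the loss every 10 epochs.
#' @return The trained `aif_cnn`, with `history` (per-epoch mean loss).
#' @export
train_cnn <- function(model, pairs, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "aif_cnn"))
  config <- model$config
  if (is.null(epochs)) epochs <- config$epochs
  if (length(pairs) < 1) stop("no training pairs", call. = FALSE)
  X <- normalize_input(t(vapply(pairs, `[[`, numeric(config$input_length), "input")))
  Tm <- normalize_label(t(vapply(pairs, `[[`, numeric(config$input_length), "label")))
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  params <- model$params
  cache <- lapply(params, function(p) p * 0)
  lr <- config$learning_rate; rho <- config$rho
  set.seed(config$seed + 1L)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      id <- ord[start:min(start + bs - 1L, n)]
      fw <- cnn_forward(params, X[id, , drop = FALSE], config)
      loss <- kl_loss(fw$prob, Tm[id, , drop = FALSE])
      if (!is.finite(loss)) stop("training diverged (non-finite loss)", call. = FALSE)
      g <- cnn_backward(params, fw, Tm[id, , drop = FALSE])
      for (nm in names(params)) {
        cache[[nm]] <- rho * cache[[nm]] + (1 - rho) * g[[nm]]^2
        params[[nm]] <- params[[nm]] - lr * g[[nm]] / (sqrt(cache[[nm]]) + 1e-8)
      }
      losses <- c(losses, loss)
    }
    history[ep] <- mean(losses)
    if (verbose && (ep %% 10 == 0 || ep == 1))
      message(sprintf("epoch %d/%d  loss %.5f", ep, epochs, history[ep]))
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict a gamma-shaped AIF from a distorted curve
#'
#' Interpolates the raw curve to the network's input length, applies the
#' trained network, and rescales the softmax output shape to physical units
#' by the input curve's first-pass area, mapping the result back onto the
#' curve's native time grid. The output is nonnegative everywhere.
#'
#' @param model A trained `aif_cnn`.
#' @param raw_curve A [conc_curve()].
#' @return A [conc_curve()] on `raw_curve`'s time grid.
#' @export
predict_aif <- function(model, raw_curve) {
  stopifnot(inherits(model, "aif_cnn"))
  if (!model$trained) stop("model is untrained; call train_cnn() first", call. = FALSE)
  assert_curve(raw_curve, "raw_curve")
  interp <- interpolate_curve(raw_curve, model$config$input_length)
  x <- matrix(interp$values, 1)
  fw <- cnn_forward(model$params, normalize_input(x), model$config)
  shape <- drop(fw$prob)
  fp <- first_passage(interp)
  # first-pass area of the input after removing any linear baseline drift
  # (fitted on the pre-arrival samples) sets the physical amplitude
  vals <- interp$values
  if (fp$arrival > 3) {
    pre <- seq_len(fp$arrival - 1L)
    bl <- stats::lm.fit(cbind(1, interp$times[pre]), vals[pre])$coefficients
    vals <- vals - (bl[1] + bl[2] * interp$times)
  }
  win <- seq_len(fp$end)
  scale <- sum(pmax(vals[win], 0)) / sum(shape[win])
  pred <- shape * max(scale, 0)
  out <- stats::approx(interp$times, pred, xout = raw_curve$times, rule = 2)$y
  conc_curve(raw_curve$times, pmax(out, 0))
}

#' Generate a synthetic training/validation curve bank
#'
#' Emulates the label-generation front end at curve level: for each of
#' `n_datasets` synthetic cases, `n_aifs` arterial candidate curves are
#' drawn (gamma-variate first passage with recirculation, parameters jittered
#' per candidate), each is distorted (baseline drift and noise, first-pass
#' attenuation, perturbed recirculation), and the gamma-variate fit of the
#' distorted curve becomes its label. Curves live on a 500-point grid over
#' the acquisition window.
#'
#' @param n_datasets Number of synthetic cases (default 128).
#' @param n_aifs Candidate curves per case (default 3).
#' @param seed Integer seed.
#' @param times Native acquisition grid (default 90 frames at 1 s).
#' @param n_points Fixed curve length (default 500).
#' @return A list with `pairs` (list of [curve_pair()]), and `meta`
#'   (data.frame of generating and distortion parameters per curve).
#' @export
make_curve_bank <- function(n_datasets = 128L, n_aifs = 3L, seed = 1L,
                            times = seq(0, 89), n_points = 500L) {
  set.seed(seed)
  pairs <- vector("list", n_datasets * n_aifs)
  meta <- vector("list", n_datasets * n_aifs)
  k <- 0L
  for (d in seq_len(n_datasets)) {
    peak <- stats::runif(1, 8, 12)
    AT <- stats::runif(1, 3, 8)
    alpha <- stats::runif(1, 2, 4)
    beta <- stats::runif(1, 1, 2.2)
    rec_delay <- stats::runif(1, 20, 30)
    rec_frac <- stats::runif(1, 0.15, 0.25)
    rec_beta <- stats::runif(1, 2.5, 4)
    for (j in seq_len(n_aifs)) {
      jit <- stats::runif(4, 0.95, 1.05)
      a_j <- alpha * jit[2]; b_j <- beta * jit[3]
      K_j <- peak * jit[1] / ((a_j * b_j)^a_j * exp(-a_j))
      p_j <- gamma_params(K_j, AT * jit[4], a_j, b_j)
      base <- gamma_eval(times, p_j$K, p_j$AT, p_j$alpha, p_j$beta)
      K2 <- rec_frac * peak / ((a_j * rec_beta)^a_j * exp(-a_j))
      rec <- gamma_eval(times, K2, p_j$AT + rec_delay, a_j, rec_beta)
      clean <- conc_curve(times, base + rec)
      dp <- distortion_params(
        baseline_slope = stats::runif(1, -0.04, 0.06),
        baseline_noise_sd = stats::runif(1, 0.05, 0.2),
        peak_attenuation = stats::runif(1, 0.4, 0.9),
        recirc_amplitude = stats::runif(1, 0.15, 0.4),
        recirc_delay = stats::runif(1, 8, 15),
        recirc_jitter = 2)
      dseed <- sample.int(.Machine$integer.max %/% 2L, 1)
      distorted <- distort_aif(clean, dp, seed = dseed)
      fitp <- suppressWarnings(tryCatch(fit_gamma(distorted),
                                        error = function(e) fit_gamma(clean)))
      interp <- interpolate_curve(distorted, n_points)
      label <- gamma_eval(interp$times, fitp$K, fitp$AT, fitp$alpha, fitp$beta)
      k <- k + 1L
      pairs[[k]] <- curve_pair(interp$times, interp$values, label)
      meta[[k]] <- data.frame(dataset = d, aif = j,
                              K = p_j$K, AT = p_j$AT, alpha = p_j$alpha,
                              beta = p_j$beta,
                              peak_attenuation = dp$peak_attenuation,
                              baseline_slope = dp$baseline_slope,
                              dseed = dseed)
    }
  }
  list(pairs = pairs, meta = do.call(rbind, meta))
}

#' Read and write curve banks
#'
#' A curve bank is stored as a directory with `inputs.csv` and `labels.csv`
#' (one row per curve) plus a `manifest.json` recording the time grid and
#' provenance.
#'
#' @param bank List with `pairs` (and optionally `meta`), as from
#'   [make_curve_bank()] or [augment_pairs()] wrapped in a list.
#' @param dir Directory path.
#' @return `write_curve_bank` returns `dir` invisibly; `read_curve_bank`
#'   a list with `pairs` and `manifest`.
#' @export
write_curve_bank <- function(bank, dir) {
  pairs <- if (is.list(bank) && !is.null(bank$pairs)) bank$pairs else bank
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- t(vapply(pairs, `[[`, numeric(length(pairs[[1]]$times)), "input"))
  Y <- t(vapply(pairs, `[[`, numeric(length(pairs[[1]]$times)), "label"))
  utils::write.csv(X, file.path(dir, "inputs.csv"), row.names = FALSE)
  utils::write.csv(Y, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(times = pairs[[1]]$times, n_curves = length(pairs)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_curve_bank
#' @export
read_curve_bank <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  X <- as.matrix(utils::read.csv(file.path(dir, "inputs.csv")))
  Y <- as.matrix(utils::read.csv(file.path(dir, "labels.csv")))
  pairs <- lapply(seq_len(nrow(X)), function(i)
    curve_pair(man$times, X[i, ], Y[i, ]))
  list(pairs = pairs, manifest = man)
}
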