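#' Gamma-variate bolus parameters
#'
#' The four parameters of the gamma-variate hemodynamic function
#' \deqn{C(t) = K (t - AT)^\alpha \exp(-(t - AT)/\beta), \quad t > AT}
#' the standard model of a contrast bolus first passage. `K` is an amplitude
#' scale (a.u.), `AT` the bolus arrival time (s), and `alpha`, `beta`
#' (dimensionless, s) shape the rise and decay. The curve peaks at
#' `AT + alpha*beta` with value `K (alpha*beta)^alpha exp(-alpha)`.
#'
#' @param K Amplitude scale, >= 0 (a.u.).
#' @param AT Bolus arrival time, >= 0 (s).
#' @param alpha Shape exponent, > 0.
#' @param beta Decay time constant, > 0 (s).
#' @return An object of class `gamma_params`.
#' @examples
#' p <- gamma_params(K = 1, AT = 5, alpha = 3, beta = 1.5)
#' gamma_peak_time(p)   # 9.5 s
#' @export
gamma_params <- function(K, AT, alpha, beta) {
  vals <- c(K = K, AT = AT, alpha = alpha, beta = beta)
  if (any(!is.finite(vals))) stop("gamma parameters must be finite", call. = FALSE)
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (AT < 0) stop("AT must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(K = K, AT = AT, alpha = alpha, beta = beta),
            class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf("<gamma_params> K=%.4g AT=%.4g s alpha=%.4g beta=%.4g s (peak at %.4g s)\n",
              x$K, x$AT, x$alpha, x$beta, gamma_peak_time(x)))
  invisible(x)
}

#' @rdname gamma_params
#' @param params A `gamma_params` object.
#' @export
gamma_peak_time <- function(params) params$AT + params$alpha * params$beta

#' @rdname gamma_params
#' @export
gamma_peak_value <- function(params) {
  with(params, K * (alpha * beta)^alpha * exp(-alpha))
}

#' Evaluate the gamma-variate function on a time grid
#'
#' Returns zero for all `t <= AT` and
#' `K (t-AT)^alpha exp(-(t-AT)/beta)` beyond arrival.
#'
#' @param times Strictly increasing time grid (s).
#' @param params A [gamma_params()] object (or list with K, AT, alpha, beta).
#' @return A [conc_curve()] on `times`.
#' @examples
#' cc <- gamma_variate(seq(0, 40, 0.5), gamma_params(1, 5, 3, 1.5))
#' @export
gamma_variate <- function(times, params) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing with >= 2 samples", call. = FALSE)
  if (!inherits(params, "gamma_params"))
    params <- gamma_params(params$K, params$AT, params$alpha, params$beta)
  conc_curve(times, gamma_eval(times, params$K, params$AT, params$alpha, params$beta))
}

# bare numeric evaluation (used by the fitter)
gamma_eval <- function(t, K, AT, alpha, beta) {
  v <- numeric(length(t))
  idx <- t > AT
  dt <- t[idx] - AT
  v[idx] <- K * dt^alpha * exp(-dt / beta)
  v
}

#' Fit the gamma-variate function to a bolus curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) fit of the
#' gamma-variate model to the first passage of a concentration curve.
#' Starting values come from the curve itself: arrival at the first sample
#' exceeding 10% of the peak, then a log-linearisation of the model
#' (log C linear in log(t-AT) and (t-AT)) for `alpha`, `beta`, `K`.
#' By default the fit window runs from the first sample to the first local
#' minimum after the global peak, so the recirculation passage is excluded;
#' the model describes the first passage only.
#'
#' @param curve A [conc_curve()] with at least 8 samples in the window.
#' @param fit_window Optional length-2 numeric `c(t0, t1)` restricting the
#'   fit to samples with `t0 <= t <= t1`. Default: first-passage window.
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 500).
#' @param ptol Relative parameter-step convergence tolerance (default 1e-8).
#' @return A [gamma_params()] object with attributes `rss` (residual
#'   sum-of-squares), `resid_norm`, `converged`, `n_used`, and `window`.
#' @examples
#' truth <- gamma_params(1, 5, 3, 1.5)
#' cc <- gamma_variate(0:60, truth)
#' fit <- fit_gamma(cc)
#' @export
fit_gamma <- function(curve, fit_window = NULL, max_iter = 500, ptol = 1e-8) {
  assert_curve(curve)
  if (is.null(fit_window)) {
    fp <- first_passage(curve)
    keep <- seq_len(fp$end)
  } else {
    if (length(fit_window) != 2 || fit_window[1] >= fit_window[2])
      stop("`fit_window` must be c(t0, t1) with t0 < t1", call. = FALSE)
    keep <- which(curve$times >= fit_window[1] & curve$times <= fit_window[2])
  }
  tt <- curve$times[keep]
  vv <- curve$values[keep]
  if (length(tt) < 8)
    stop("need at least 8 samples inside the fit window", call. = FALSE)
  rng <- max(vv) - min(vv)
  if (!(rng > 1e-8 * max(abs(vv), 1)) || max(vv) <= 0)
    stop("degenerate curve: dynamic range too small to fit", call. = FALSE)

  start <- gamma_start(tt, vv)
  lower <- c(K = 0, AT = 0, alpha = 1e-3, beta = 1e-3)
  upper <- c(K = Inf, AT = max(tt), alpha = 50, beta = max(tt))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = lower, upper = upper,
      fn = function(p) gamma_eval(tt, p[["K"]], p[["AT"]], p[["alpha"]], p[["beta"]]) - vv,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = ptol,
                                           ftol = 1e-12)),
    error = function(e) stop("gamma fit failed: ", conditionMessage(e), call. = FALSE))
  p <- fit$par
  out <- gamma_params(max(p[["K"]], 0), max(p[["AT"]], 0), p[["alpha"]], p[["beta"]])
  rss <- sum(fit$fvec^2)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("gamma fit did not converge (info = ", fit$info,
            "); returning best-so-far parameters", call. = FALSE)
  attr(out, "rss") <- rss
  attr(out, "resid_norm") <- sqrt(rss)
  attr(out, "converged") <- converged
  attr(out, "n_used") <- length(tt)
  attr(out, "window") <- range(tt)
  out
}

# moment/log-linearisation starting values for the gamma fit
gamma_start <- function(tt, vv) {
  ip <- which.max(vv)
  pk <- vv[ip]
  ia <- which(vv > 0.1 * pk)[1]
  AT0 <- if (ia > 1) tt[ia - 1] else max(tt[1] - (tt[2] - tt[1]), 0)
  use <- which(tt > AT0 & vv > 0.05 * pk)
  alpha0 <- 3; beta0 <- max((tt[ip] - AT0) / 3, 1e-2); K0 <- pk
  if (length(use) >= 3) {
    x1 <- log(tt[use] - AT0)
    x2 <- tt[use] - AT0
    co <- tryCatch(stats::coef(stats::lm(log(vv[use]) ~ x1 + x2)),
                   error = function(e) NULL)
    if (!is.null(co) && is.finite(co[2]) && is.finite(co[3]) &&
        co[2] > 0 && co[3] < 0) {
      alpha0 <- min(max(co[2], 0.2), 20)
      beta0 <- min(max(-1 / co[3], 1e-2), max(tt))
      K0 <- exp(co[1])
    }
  }
  if (!is.finite(K0) || K0 <= 0)
    K0 <- pk / max((alpha0 * beta0)^alpha0 * exp(-alpha0), 1e-12)
  c(K = unname(K0), AT = max(AT0, 0), alpha = unname(alpha0), beta = unname(beta0))
}
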