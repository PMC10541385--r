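#' Concentration-time curve
#'
#' Container for a sampled contrast-concentration time series: a strictly
#' increasing time grid (seconds) and one concentration value (arbitrary
#' CT attenuation-change units) per time point.
#'
#' @param times Numeric vector of sample times in seconds, strictly increasing.
#' @param values Numeric vector of concentrations, same length as `times`.
#' @return An object of class `conc_curve` with elements `times` and `values`.
#' @examples
#' cc <- conc_curve(0:10, c(0, 0, 1, 4, 8, 6, 3, 2, 1, 0.5, 0.2))
#' peak_value(cc)
#' @export
conc_curve <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a concentration curve needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("`times` and `values` must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values), class = "conc_curve")
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("<conc_curve> %d samples, t = [%g, %g] s, peak %.4g at %g s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              max(x$values), x$times[which.max(x$values)]))
  invisible(x)
}

#' @export
length.conc_curve <- function(x) length(x$times)

is_conc_curve <- function(x) inherits(x, "conc_curve")

assert_curve <- function(x, arg = "curve") {
  if (!is_conc_curve(x)) stop(sprintf("`%s` must be a conc_curve", arg), call. = FALSE)
  invisible(x)
}

#' Peak value and first moment of a curve
#'
#' `peak_value()` returns the maximum concentration; `first_moment()` the
#' intensity-weighted mean time sum(t*C)/sum(C), the standard "early and
#' sharp" summary used to rank arterial candidates.
#'
#' @param curve A [conc_curve()].
#' @return A single number (seconds for `first_moment`).
#' @export
peak_value <- function(curve) {
  assert_curve(curve)
  max(curve$values)
}

#' @rdname peak_value
#' @export
first_moment <- function(curve) {
  assert_curve(curve)
  v <- pmax(curve$values, 0)
  s <- sum(v)
  if (s <= 0) return(NA_real_)
  sum(curve$times * v) / s
}

#' Bolus first-passage window of a curve
#'
#' Locates the first-passage portion of a bolus curve. The curve is lightly
#' smoothed (moving average) for landmark detection; the first-pass peak is
#' the earliest local maximum rising at least half of the global excursion
#' above the early baseline -- so a drifting baseline or a large
#' recirculation hump later in the curve is not mistaken for the bolus.
#' Arrival is the first sample exceeding `frac` of the peak height above
#' baseline. The window ends at the first valley after the peak that is
#' followed by a genuine second passage (recirculation or a strong drift
#' hump); when the tail simply decays, the window stays open to the last
#' sample.
#'
#' @param curve A [conc_curve()].
#' @param frac Arrival-detection fraction of the peak (default 0.1).
#' @return A list with integer indices `arrival`, `peak`, `end` and the
#'   corresponding times `t_arrival`, `t_peak`, `t_end`.
#' @export
first_passage <- function(curve, frac = 0.1) {
  assert_curve(curve)
  v <- curve$values
  n <- length(v)
  w <- max(3L, 2L * (n %/% 60L) + 1L)        # odd smoothing window
  s <- moving_avg(v, w)
  base <- stats::median(s[seq_len(max(3L, round(0.08 * n)))])
  gm <- max(s)
  interior <- 2:(n - 1L)
  locmax <- interior[s[interior] >= s[interior - 1L] & s[interior] >= s[interior + 1L]]
  eligible <- locmax[s[locmax] - base >= 0.5 * (gm - base)]
  ip_s <- if (length(eligible) > 0) eligible[1] else which.max(s)
  lo <- max(1L, ip_s - w); hi <- min(n, ip_s + w)
  ip <- lo - 1L + which.max(v[lo:hi])
  pk <- v[ip]
  below <- which(v[seq_len(ip)] <= base + frac * (pk - base))
  ia <- if (length(below) > 0) min(below[length(below)] + 1L, ip) else 1L
  # end of first passage on the smoothed curve: washout to 20% of the peak
  # height, or an earlier valley that is followed by a genuine second
  # passage (a rise of at least 10% of the peak height); whichever comes
  # first, else the last sample
  ie <- n
  if (ip < n - 2L) {
    post <- s[(ip + 1L):n]
    np <- length(post)
    hgt <- s[ip_s] - base
    low <- which(post < base + 0.2 * hgt)
    if (length(low) > 0) ie <- ip + low[1]
    vall <- which(post[2:(np - 1L)] <= post[1:(np - 2L)] &
                    post[2:(np - 1L)] <= post[3:np]) + 1L
    for (vi in vall) {
      if (vi >= ie - ip) break
      if (max(post[vi:np]) > post[vi] + 0.1 * hgt) { ie <- ip + vi; break }
    }
  }
  list(arrival = ia, peak = ip, end = ie,
       t_arrival = curve$times[ia], t_peak = curve$times[ip],
       t_end = curve$times[ie])
}

#' Read and write curves as two-column CSV
#'
#' Curves serialise to CSV with columns `time_s` and `value`.
#'
#' @param curve A [conc_curve()].
#' @param path File path.
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv` a
#'   [conc_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  assert_curve(curve)
  utils::write.csv(data.frame(time_s = curve$times, value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("curve CSV must have columns time_s and value", call. = FALSE)
  conc_curve(d$time_s, d$value)
}

# uniform-grid check/resampling used before deconvolution
is_uniform_grid <- function(times, rel_tol = 1e-6) {
  dts <- diff(times)
  diff(range(dts)) <= rel_tol * stats::median(dts)
}

resample_uniform <- function(curve, dt = NULL) {
  assert_curve(curve)
  if (is.null(dt)) dt <- stats::median(diff(curve$times))
  tt <- seq(curve$times[1], curve$times[length(curve$times)], by = dt)
  vv <- stats::approx(curve$times, curve$values, xout = tt, rule = 2)$y
  conc_curve(tt, vv)
}

# centred moving average with edge replication
moving_avg <- function(v, w) {
  half <- w %/% 2L
  vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
  as.numeric(stats::filter(vp, rep(1 / w, w), sides = 2))[half + seq_along(v)]
}
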