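#' Welch power spectral density of an LFP trace
#'
#' The trace is low-pass filtered (6th-order Butterworth, zero-phase),
#' linearly detrended, its initial transient discarded, and the spectrum
#' estimated by averaging Hann-windowed modified periodograms over
#' overlapping segments.
#'
#' @param trace LFP samples, uV.
#' @param dt sample interval, ms.
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param discard_ms transient discarded from the start, ms.
#' @param window_ms Welch segment length, ms.
#' @param overlap segment overlap fraction.
#' @param filter apply the Butterworth low-pass stage.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
lfp_spectrum <- function(trace, dt = 0.1, cutoff_hz = 200,
                         discard_ms = 200, window_ms = 400, overlap = 0.5,
                         filter = TRUE) {
  fs <- 1000 / dt
  nseg <- round(window_ms / dt)
  if (length(trace) < (discard_ms / dt) + nseg)
    stop("trace too short: need the discard interval plus one window")
  x <- trace
  if (filter) {
    bf <- signal::butter(6, cutoff_hz / (fs / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  t <- seq_along(x)
  x <- stats::residuals(stats::lm(x ~ t))
  x <- x[-seq_len(round(discard_ms / dt))]
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  norm <- sum(win^2) * fs
  nf <- nseg %/% 2
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)] * win
    p <- abs(stats::fft(seg))^2 / norm
    acc <- acc + 2 * p[2:(nf + 1)]
  }
  data.frame(freq = (1:nf) * fs / nseg, power = acc / length(starts))
}

#' Dominant spectral peak in a band
#'
#' @param spec output of [lfp_spectrum()].
#' @param band frequency band, Hz.
#' @return frequency of the maximum power inside the band, Hz.
#' @export
spectral_peak <- function(spec, band = c(10, 100)) {
  s <- spec[spec$freq >= band[1] & spec$freq <= band[2], ]
  s$freq[which.max(s$power)]
}

#' Windowed firing-rate matrix
#'
#' Spike counts per sliding window divided by the window length.
#'
#' @param spikes data.frame with `id` and `t` (ms), e.g. the MC rows of a
#'   simulation's spike table.
#' @param cell_ids cells forming the matrix rows.
#' @param window window length, ms.
#' @param overlap overlap fraction between consecutive windows.
#' @param duration total spike-train duration, ms.
#' @param t0 start of the first window, ms.
#' @return matrix cells x windows of rates in Hz, with window start times
#'   as an attribute `t_start`.
#' @export
windowed_rates <- function(spikes, cell_ids, window, overlap = 0.5,
                           duration, t0 = 0) {
  stopifnot(window > 0)
  step <- window * (1 - overlap)
  starts <- seq(t0, duration - window, by = step)
  m <- matrix(0, length(cell_ids), length(starts),
              dimnames = list(cell_ids, NULL))
  idx <- match(spikes$id, cell_ids)
  ok <- !is.na(idx)
  ts <- spikes$t[ok]
  idx <- idx[ok]
  for (w in seq_along(starts)) {
    sel <- ts > starts[w] & ts <= starts[w] + window
    if (any(sel)) {
      tab <- tabulate(idx[sel], length(cell_ids))
      m[, w] <- m[, w] + tab
    }
  }
  m <- m / (window / 1000)
  attr(m, "t_start") <- starts
  attr(m, "window") <- window
  m
}

#' Per-window Pearson correlation between two rate matrices
#'
#' Correlates the two cell-rate vectors window by window. Windows in
#' which either matrix has zero variance are undefined and returned as
#' `NA`; the summary mean covers windows after the first sniff.
#'
#' @param rates_a,rates_b matrices from [windowed_rates()] with matching
#'   dimensions.
#' @param first_sniff_ms windows starting before this time are excluded
#'   from the summary mean (one sniff at 6 Hz by default).
#' @return list with `correlation` per window, `t_start`, `mean`
#'   (post-first-sniff summary) and `n_skipped` zero-variance windows.
#' @export
correlation_timecourse <- function(rates_a, rates_b,
                                   first_sniff_ms = 1000 / 6) {
  stopifnot(all(dim(rates_a) == dim(rates_b)))
  nw <- ncol(rates_a)
  r <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    va <- rates_a[, w]
    vb <- rates_b[, w]
    if (stats::sd(va) > 0 && stats::sd(vb) > 0)
      r[w] <- stats::cor(va, vb)
  }
  ts <- attr(rates_a, "t_start")
  keep <- ts >= first_sniff_ms & !is.na(r)
  list(correlation = r, t_start = ts,
       mean = if (any(keep)) mean(r[keep]) else NA_real_,
       n_skipped = sum(is.na(r)))
}

#' Fit a stretched exponential a * exp(-b * x^n)
#'
#' Nonlinear least squares (Levenberg-Marquardt) with log-linear
#' initialisation.
#'
#' @param x distances, um.
#' @param y means per distance.
#' @param fix_n fit with the exponent fixed at this value (ordinary
#'   exponential for `fix_n = 1`), or `NULL` to fit it.
#' @return list with `a`, `b`, `n`, fitted values and residuals.
#' @export
fit_stretched_exp <- function(x, y, fix_n = NULL) {
  stopifnot(length(x) >= 4, length(x) == length(y))
  pos <- y > 0 & x > 0
  ln <- stats::lm(log(y[pos]) ~ x[pos])
  b0 <- max(1e-6, -stats::coef(ln)[2])
  a0 <- max(max(y), exp(stats::coef(ln)[1]))
  df <- data.frame(x = x, y = y)
  if (is.null(fix_n)) {
    fit <- minpack.lm::nlsLM(y ~ a * exp(-b * x^n), data = df,
                             start = list(a = a0, b = b0, n = 1),
                             lower = c(0, 1e-12, 0.1), upper = c(Inf, 1, 5),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    n <- fix_n
    fit <- minpack.lm::nlsLM(y ~ a * exp(-b * x^n), data = df,
                             start = list(a = a0, b = b0),
                             lower = c(0, 1e-12), upper = c(Inf, 1),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
       fitted = stats::fitted(fit), residuals = stats::residuals(fit))
}

#' Skew-normal density
#'
#' `f(x) = (2/omega) phi((x - xi)/omega) Phi(shape * (x - xi)/omega)`,
#' with `xi` the shift, `omega` the scale and `shape` the skewness.
#'
#' @param x quantiles.
#' @param xi shift.
#' @param omega scale (> 0).
#' @param shape skewness.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, shape = 0) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(shape * z)
}

#' Maximum-likelihood skew-normal fit
#'
#' @param x observations (e.g. granule-cell degrees).
#' @return list with `xi`, `omega`, `shape` and the log-likelihood.
#' @export
fit_skew_normal <- function(x) {
  stopifnot(length(x) >= 10)
  nll <- function(p) {
    om <- exp(p[2])
    d <- dskewnorm(x, p[1], om, p[3])
    if (any(d <= 0) || any(!is.finite(d))) return(1e12)
    -sum(log(d))
  }
  st <- c(mean(x) - stats::sd(x), log(stats::sd(x) * 1.5), 2)
  op <- stats::optim(st, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000))
  list(xi = op$par[1], omega = exp(op$par[2]), shape = op$par[3],
       loglik = -op$value, convergence = op$convergence)
}
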