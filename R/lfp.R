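#' Per-transistor switching event streams
#'
#' "Switching" counts both edges (off-to-on and on-to-off) of the
#' conduction state by default, which is what the field-potential analogue
#' integrates; restrict to rising edges with `edges = "rising"` to match
#' the spike definition.
#'
#' @param trace a `state_trace` or T x units binary matrix.
#' @param edges `"both"` or `"rising"`.
#' @return T x units 0/1 matrix of events (first row all zero).
#' @export
switching_events <- function(trace, edges = c("both", "rising")) {
  edges <- match.arg(edges)
  m <- if (inherits(trace, "state_trace")) trace$transistor_on else as.matrix(trace)
  d <- diff(m)
  ev <- if (edges == "both") (d != 0) * 1L else (d > 0) * 1L
  rbind(matrix(0L, 1, ncol(m)), ev)
}

#' Local field potential channel
#'
#' The LFP analogue: transistor switching integrated over space with a
#' Gaussian weight `w_i = exp(-d_i^2 / (2 sigma^2))` around a recording
#' point, then low-pass filtered with a centered moving average. The
#' moving-average window covers `width` samples (for even widths, one more
#' sample forward than backward); edge windows are truncated to the
#' available samples.
#'
#' @param trace a `state_trace` (positions are taken from its netlist), or
#'   a T x units event matrix (then supply `positions`).
#' @param center length-2 numeric recording position (micrometres), or a
#'   module label from the netlist (channel centered on the module's
#'   centroid).
#' @param sigma Gaussian spatial scale in micrometres (default 500).
#' @param width low-pass moving-average width in timesteps (default 4).
#' @param edges event convention, see [switching_events()].
#' @param positions units x 2 matrix of coordinates, required when `trace`
#'   is a plain matrix.
#' @return an `lfp_channel`: list with `samples`, `center`, `sigma`,
#'   `width`.
#' @export
lfp_channel <- function(trace, center, sigma = 500, width = 4,
                        edges = "both", positions = NULL) {
  stopifnot(sigma > 0, width >= 1)
  if (inherits(trace, "state_trace")) {
    tr <- trace$netlist$transistors
    positions <- cbind(tr$x, tr$y)
    if (is.character(center)) {
      mod <- trace$netlist$modules[[center]]
      if (is.null(mod)) stop("unknown module label: ", center)
      sel <- tr$id %in% mod
      center <- c(mean(tr$x[sel]), mean(tr$y[sel]))
    }
    ev <- switching_events(trace, edges)
  } else {
    ev <- as.matrix(trace)
    if (is.null(positions)) stop("positions required for a plain event matrix")
  }
  d2 <- (positions[, 1] - center[1])^2 + (positions[, 2] - center[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  if (!any(d2 <= (4 * sigma)^2)) {
    warning("no transistors within 4 sigma of the channel center; zero channel")
  }
  raw <- as.numeric(ev %*% w)
  structure(list(samples = moving_average(raw, width),
                 raw = raw, center = center, sigma = sigma, width = width),
            class = "lfp_channel")
}

# centered moving average, even widths lean forward, edges truncated
moving_average <- function(x, width) {
  n <- length(x)
  back <- (width - 1L) %/% 2L
  fwd <- width - 1L - back
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' @export
print.lfp_channel <- function(x, ...) {
  cat("<lfp_channel> ", length(x$samples), " samples, center (",
      paste(round(x$center, 1), collapse = ", "), "), sigma ",
      x$sigma, "\n", sep = "")
  invisible(x)
}

#' Welch power spectrum of an LFP channel
#'
#' Welch's method: the signal is split into non-overlapping segments of
#' `nfft` samples (trailing remainder dropped), each segment is demeaned
#' (constant detrend, so the mean switching load does not leak through the
#' window sidelobes into the low bins) and tapered with a Hann window, and
#' the squared DFT magnitudes are averaged. Frequencies are reported in
#' cycles/timestep up to Nyquist (0.5); multiply by a clock rate to convert
#' to physical units.
#'
#' @param channel an `lfp_channel` or numeric vector.
#' @param nfft segment length (default 256).
#' @param detrend subtract each segment's mean before windowing (default
#'   TRUE).
#' @return an `lfp_spectrum`: tibble with `frequency`, `power`, and
#'   attributes recording the estimator settings.
#' @export
welch_periodogram <- function(channel, nfft = 256, detrend = TRUE) {
  x <- if (inherits(channel, "lfp_channel")) channel$samples else as.numeric(channel)
  n_seg <- length(x) %/% nfft
  if (n_seg < 1) stop("signal shorter than one segment (", nfft, " samples)")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
  scale <- sum(w^2)
  acc <- numeric(nfft)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * nfft + 1):(s * nfft)]
    if (detrend) seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * w))^2 / scale
  }
  pxx <- acc / n_seg
  half <- nfft %/% 2
  # fold the two-sided spectrum into one-sided power
  p1 <- pxx[1:(half + 1)]
  p1[2:half] <- p1[2:half] + rev(pxx)[1:(half - 1)]
  out <- tibble::tibble(frequency = (0:half) / nfft, power = p1)
  structure(out, class = c("lfp_spectrum", class(out)),
            nfft = nfft, window = "hann", overlap = 0, n_segments = n_seg)
}

#' Dominant spectral frequency
#'
#' @param spec an `lfp_spectrum`.
#' @param exclude_dc drop the zero-frequency bin before taking the argmax
#'   (default TRUE; the DC term reflects mean switching load, not rhythm).
#' @return frequency (cycles/timestep) of maximal power.
#' @export
spectrum_peak <- function(spec, exclude_dc = TRUE) {
  s <- if (exclude_dc) spec[spec$frequency > 0, ] else spec
  s$frequency[which.max(s$power)]
}

#' @method autoplot lfp_spectrum
#' @export
autoplot.lfp_spectrum <- function(object, ...) {
  ggplot2::ggplot(object[object$frequency > 0, ],
                  ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (cycles/timestep)", y = "power") +
    ggplot2::theme_minimal()
}
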