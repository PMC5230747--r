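#' Extract spikes (off-to-on transitions) from a trace
#'
#' A "spike" is the off-to-on transition of a transistor's conduction
#' state, the circuit analogue of an action potential. Events are defined on
#' conduction state, not wire voltage (the latter would be the analogue of
#' measuring transmembrane voltage). Timesteps are 1-based; an event at time
#' `t` requires the unit off at `t - 1` and on at `t`, so a unit already on
#' at the first timestep does not spike there.
#'
#' @param trace a `state_trace`, or a T x units binary matrix.
#' @return a `spike_set`: list of strictly increasing integer event-time
#'   vectors, one per unit (named by unit id), with attribute
#'   `n_timesteps`.
#' @export
extract_spikes <- function(trace) {
  m <- if (inherits(trace, "state_trace")) trace$transistor_on else as.matrix(trace)
  rises <- m[-1, , drop = FALSE] == 1L & m[-nrow(m), , drop = FALSE] == 0L
  spikes <- lapply(seq_len(ncol(m)), function(j) which(rises[, j]) + 1L)
  names(spikes) <- colnames(m)
  structure(spikes, class = "spike_set", n_timesteps = nrow(m))
}

#' @export
print.spike_set <- function(x, ...) {
  cat("<spike_set> ", length(x), " units, ",
      sum(lengths(x)), " events over ", attr(x, "n_timesteps"),
      " timesteps\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble spike_set
#' @export
as_tibble.spike_set <- function(x, ...) {
  tibble::tibble(
    unit = rep(names(x) %||% as.character(seq_along(x)), lengths(x)),
    time = unlist(x, use.names = FALSE))
}

#' Bin spike counts
#'
#' Counts events per unit in consecutive windows of `bin_width` timesteps.
#' Binning conserves the total spike count except when the trace length is
#' not a multiple of the bin width, in which case the trailing partial bin
#' is dropped (with a message).
#'
#' @param spikes a `spike_set`.
#' @param bin_width bin width in timesteps (default 100).
#' @param n_timesteps trace length; defaults to the spike set's.
#' @return a `binned_activity` matrix, units x bins, with attribute
#'   `bin_width`.
#' @export
bin_counts <- function(spikes, bin_width = 100, n_timesteps = NULL) {
  stopifnot(bin_width >= 1)
  if (is.null(n_timesteps)) n_timesteps <- attr(spikes, "n_timesteps")
  n_bins <- n_timesteps %/% bin_width
  if (n_bins * bin_width < n_timesteps) {
    message("dropping partial final bin (",
            n_timesteps - n_bins * bin_width, " timesteps)")
  }
  counts <- t(vapply(spikes, function(ev) {
    ev <- ev[ev <= n_bins * bin_width]
    tabulate((ev - 1L) %/% bin_width + 1L, nbins = n_bins)
  }, integer(n_bins)))
  structure(counts, class = c("binned_activity", "matrix"),
            bin_width = bin_width,
            dimnames = list(names(spikes), NULL))
}

#' Sliding-window firing rate
#'
#' `rate[t]` is the number of events in the window `(t - window, t]`, the
#' "sum activity over the previous timesteps" convention used for tuning
#' curves.
#'
#' @param spikes a `spike_set`.
#' @param window window length in timesteps (default 100).
#' @param n_timesteps trace length; defaults to the spike set's.
#' @return units x T integer matrix of rates.
#' @export
sliding_rate <- function(spikes, window = 100, n_timesteps = NULL) {
  stopifnot(window >= 1)
  if (is.null(n_timesteps)) n_timesteps <- attr(spikes, "n_timesteps")
  t(vapply(spikes, function(ev) {
    x <- tabulate(ev, nbins = n_timesteps)
    cs <- cumsum(x)
    cs - c(rep(0L, min(window, n_timesteps)),
           cs[seq_len(max(0L, n_timesteps - window))])
  }, integer(n_timesteps)))
}

#' Z-score binned activity rows
#'
#' Subtracts each unit's mean and divides by its standard deviation using
#' the population (1/N) variance convention. Constant rows map to all
#' zeros.
#'
#' @param binned a `binned_activity` matrix (or any units x bins matrix).
#' @return numeric matrix of the same shape, class `binned_activity`.
#' @export
zscore <- function(binned) {
  m <- unclass(as.matrix(binned))
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  structure(z, class = c("binned_activity", "matrix"),
            bin_width = attr(binned, "bin_width"),
            dimnames = dimnames(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
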