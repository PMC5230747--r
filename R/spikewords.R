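#' Select units closest to the population mean rate
#'
#' Picks the `n` units whose firing rates are nearest the population mean
#' rate. Ties on the rate distance are broken by unit order (lower id
#' first); the seed only matters when subsampling among exact ties.
#'
#' @param binned a `binned_activity` (units x bins counts) matrix.
#' @param n number of units to keep (default 64).
#' @param seed optional integer used only to break exact rate ties.
#' @return integer row indices of the selected units, in rate-distance
#'   order.
#' @export
select_units <- function(binned, n = 64, seed = NULL) {
  m <- as.matrix(binned)
  stopifnot(n <= nrow(m))
  rates <- rowMeans(m)
  d <- abs(rates - mean(rates))
  ord <- order(d, seq_along(d))
  if (!is.null(seed) && anyDuplicated(d)) {
    # permute within exact-distance ties, reproducibly
    ord <- withr_seed(seed, {
      grp <- match(d[ord], unique(d[ord]))
      unlist(lapply(split(ord, grp), function(ix) {
        if (length(ix) > 1) sample(ix) else ix
      }), use.names = FALSE)
    })
  }
  sort(ord[seq_len(n)])
}

# evaluate expr under a temporary RNG seed, restoring RNG state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spike-word population statistics
#'
#' A spike word is the binary population vector of which units are active
#' in one time bin; its weight is the number of active units. Returns the
#' word-weight histogram P(k active units) and the pairwise correlation
#' matrix of the binarized unit trains.
#'
#' @param words units x bins matrix; entries are binarized (> 0 means
#'   active).
#' @return a `word_stats`: list with `weight_histogram` (tibble `weight`,
#'   `probability`, summing to 1 over 0..n_units) and `correlation`
#'   (symmetric matrix, unit diagonal; units with zero variance get 0
#'   off-diagonal entries).
#' @export
word_stats <- function(words) {
  m <- (as.matrix(words) > 0) * 1L
  n_units <- nrow(m)
  k <- colSums(m)
  hist <- tabulate(k + 1L, nbins = n_units + 1L)
  hist <- hist / sum(hist)
  v <- apply(m, 1, stats::var)
  cm <- diag(1, n_units)
  ok <- v > 0
  if (sum(ok) > 1) cm[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  diag(cm) <- 1
  structure(
    list(weight_histogram = tibble::tibble(weight = 0:n_units,
                                           probability = hist),
         correlation = cm,
         n_units = n_units, n_bins = ncol(m)),
    class = "word_stats")
}

#' @export
print.word_stats <- function(x, ...) {
  cat("<word_stats> ", x$n_units, " units, ", x$n_bins, " bins; mean weight ",
      round(sum(x$weight_histogram$weight * x$weight_histogram$probability), 3),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy word_stats
#' @export
tidy.word_stats <- function(x, ...) x$weight_histogram

#' @method autoplot word_stats
#' @export
autoplot.word_stats <- function(object, ...) {
  ggplot2::ggplot(object$weight_histogram,
                  ggplot2::aes(x = .data$weight, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "spikes per word", y = "probability") +
    ggplot2::theme_minimal()
}

#' Shuffle control for spike words
#'
#' Destroys cross-unit alignment while preserving each unit's marginal
#' statistics: every unit's train is circularly shifted in time by an
#' independent uniform offset. Per-unit counts (and autocorrelations) are
#' preserved exactly; synchrony is not. An alternative that permutes unit
#' labels within each bin independently is available via
#' `method = "label_permutation"`.
#'
#' @param words units x bins matrix.
#' @param seed integer seed.
#' @param method `"circular_shift"` (default) or `"label_permutation"`.
#' @return shuffled matrix of the same shape.
#' @export
shuffle_control <- function(words, seed, method = "circular_shift") {
  m <- as.matrix(words)
  nb <- ncol(m)
  withr_seed(seed, {
    if (method == "circular_shift") {
      shifts <- sample.int(nb, nrow(m), replace = TRUE) - 1L
      out <- m
      for (i in seq_len(nrow(m))) {
        if (shifts[i] > 0) {
          out[i, ] <- m[i, c((nb - shifts[i] + 1L):nb, 1L:(nb - shifts[i]))]
        }
      }
      out
    } else if (method == "label_permutation") {
      apply(m, 2, sample)
    } else stop("unknown shuffle method: ", method)
  })
}

#' Word-weight histogram under the shuffle null
#'
#' The shuffle control is the expected word-weight distribution when
#' cross-unit alignment is destroyed; it is estimated by averaging the
#' histograms of several independent shuffles, which removes the sampling
#' noise a single shuffle draw would add on top of the raw histogram's own.
#'
#' @param words units x bins matrix.
#' @param seed integer seed.
#' @param n_shuffles independent shuffle draws to average (default 20).
#' @param method passed to [shuffle_control()].
#' @return probability vector over word weights `0..n_units`.
#' @export
shuffle_histogram <- function(words, seed, n_shuffles = 20,
                              method = "circular_shift") {
  hs <- vapply(seq_len(n_shuffles), function(i) {
    word_stats(shuffle_control(words, seed + i - 1L,
                               method = method))$weight_histogram$probability
  }, numeric(nrow(as.matrix(words)) + 1L))
  rowMeans(hs)
}

#' Total-variation distance between two word-weight histograms
#'
#' @param a,b `word_stats` objects or probability vectors over the same
#'   support.
#' @return TV distance in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  pa <- if (inherits(a, "word_stats")) a$weight_histogram$probability else a
  pb <- if (inherits(b, "word_stats")) b$weight_histogram$probability else b
  stopifnot(length(pa) == length(pb))
  sum(abs(pa - pb)) / 2
}
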