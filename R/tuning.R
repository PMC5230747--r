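#' Stimulus tuning curve of a single unit
#'
#' Computes the mean sliding-window rate at each observed stimulus value,
#' normalized by the frequency of occurrence of that value (occupancy
#' normalization): `curve[s]` is the mean of `rate[t]` over timesteps with
#' `stimulus[t] == s`. Stimulus values with zero occupancy are absent from
#' the curve. Duplicating timesteps of a given stimulus value leaves its
#' curve entry unchanged.
#'
#' @param rate numeric vector of rates for one unit (a row of
#'   [sliding_rate()]).
#' @param stimulus numeric vector of per-timestep scalar stimulus values
#'   (the "luminance" analogue, e.g. an output-bus value), same length as
#'   `rate`.
#' @return a `tuning_curve`: list with `curve` (tibble `stimulus`,
#'   `occupancy`, `mean_rate`), plus the grand mean and total rate variance
#'   used downstream for effect-size computation.
#' @export
tuning_curve <- function(rate, stimulus) {
  stopifnot(length(rate) == length(stimulus), all(is.finite(stimulus)))
  if (length(rate) == 0) stop("empty overlap between rate and stimulus")
  curve <- tibble::tibble(stimulus = stimulus, rate = rate) |>
    dplyr::group_by(stimulus) |>
    dplyr::summarise(occupancy = dplyr::n(), mean_rate = mean(rate),
                     .groups = "drop") |>
    dplyr::arrange(stimulus)
  structure(
    list(curve = curve,
         grand_mean = mean(rate),
         ss_total = sum((rate - mean(rate))^2),
         n = length(rate)),
    class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("<tuning_curve> ", nrow(x$curve), " stimulus values, ",
      x$n, " timesteps\n", sep = "")
  print(x$curve)
  invisible(x)
}

#' Classify a tuning curve as simple, complex, or untuned
#'
#' Replaces by-eye classification with an explicit rule: fit a unimodal
#' Gaussian plus baseline, `a * exp(-(s - mu)^2 / (2 w^2)) + b`, by least
#' squares on the curve points. The unit is `simple` if the fit attains
#' `R^2 >= r2_threshold` and the fitted peak lies strictly inside the
#' observed stimulus range; `complex` if the Gaussian fails but the
#' stimulus still explains at least `eta2_threshold` of the rate variance
#' (eta-squared from the occupancy-weighted group means); otherwise
#' `untuned`. Degenerate (near-zero) curve variance is `untuned` outright.
#' Classification is invariant to scaling the rates by a positive constant.
#'
#' @param tc a `tuning_curve`.
#' @param r2_threshold Gaussian goodness-of-fit cut (default 0.8).
#' @param eta2_threshold variance-explained cut for `complex` (default
#'   0.1).
#' @return the `tuning_curve` with a `fit` element: `class`, `peak`,
#'   `width`, `amplitude`, `baseline`, `r2`, `eta2`.
#' @export
classify_tuning <- function(tc, r2_threshold = 0.8, eta2_threshold = 0.1) {
  stopifnot(inherits(tc, "tuning_curve"))
  cv <- tc$curve
  if (nrow(cv) < 4) stop("need at least 4 distinct stimulus values")
  ss_between <- sum(cv$occupancy * (cv$mean_rate - tc$grand_mean)^2)
  eta2 <- if (tc$ss_total > 0) ss_between / tc$ss_total else 0

  y <- cv$mean_rate
  s <- cv$stimulus
  fit <- list(class = "untuned", peak = NA_real_, width = NA_real_,
              amplitude = NA_real_, baseline = NA_real_,
              r2 = NA_real_, eta2 = eta2)
  sst <- sum((y - mean(y))^2)
  if (sst > 1e-12 * max(1, mean(y)^2)) {
    start <- list(a = max(y) - min(y), b = min(y),
                  mu = s[which.max(y)], w = diff(range(s)) / 4)
    gfit <- tryCatch(
      minpack.lm::nlsLM(
        mean_rate ~ a * exp(-(stimulus - mu)^2 / (2 * w^2)) + b,
        data = cv, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(gfit)) {
      co <- stats::coef(gfit)
      r2 <- 1 - sum(stats::resid(gfit)^2) / sst
      fit$peak <- unname(co["mu"])
      fit$width <- abs(unname(co["w"]))
      fit$amplitude <- unname(co["a"])
      fit$baseline <- unname(co["b"])
      fit$r2 <- r2
      interior <- co["mu"] > min(s) && co["mu"] < max(s)
      if (r2 >= r2_threshold && interior && co["a"] > 0) {
        fit$class <- "simple"
      } else if (eta2 >= eta2_threshold) {
        fit$class <- "complex"
      }
    } else if (eta2 >= eta2_threshold) {
      fit$class <- "complex"
    }
  }
  tc$fit <- fit
  tc
}

#' Tuning curves and classification for every unit
#'
#' @param rates units x T matrix from [sliding_rate()].
#' @param stimulus per-timestep stimulus values.
#' @param ... thresholds passed to [classify_tuning()].
#' @return tibble with one row per unit: `unit`, `class`, `peak`, `width`,
#'   `amplitude`, `baseline`, `r2`, `eta2`.
#' @export
classify_units <- function(rates, stimulus, ...) {
  units <- rownames(rates) %||% as.character(seq_len(nrow(rates)))
  purrr::map_dfr(seq_len(nrow(rates)), function(i) {
    tc <- classify_tuning(tuning_curve(rates[i, ], stimulus), ...)
    tibble::as_tibble(tc$fit[c("class", "peak", "width", "amplitude",
                               "baseline", "r2", "eta2")]) |>
      dplyr::mutate(unit = units[i], .before = 1)
  })
}

#' @method tidy tuning_curve
#' @export
tidy.tuning_curve <- function(x, ...) x$curve

#' @method glance tuning_curve
#' @export
glance.tuning_curve <- function(x, ...) {
  if (is.null(x$fit)) stop("run classify_tuning() first")
  tibble::as_tibble(x$fit[c("class", "peak", "width", "amplitude",
                            "baseline", "r2", "eta2")])
}

#' @method autoplot tuning_curve
#' @export
autoplot.tuning_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$stimulus, y = .data$mean_rate)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$occupancy), alpha = 0.7) +
    ggplot2::labs(x = "stimulus value", y = "mean rate (events / window)") +
    ggplot2::theme_minimal()
  f <- object$fit
  if (!is.null(f) && is.finite(f$peak)) {
    grid <- tibble::tibble(
      stimulus = seq(min(object$curve$stimulus),
                     max(object$curve$stimulus), length.out = 200))
    grid$mean_rate <- f$amplitude *
      exp(-(grid$stimulus - f$peak)^2 / (2 * f$width^2)) + f$baseline
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
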