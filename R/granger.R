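#' Segment channels into equal-length trials
#'
#' Trials are formed by cutting one long multichannel recording into equal
#' non-overlapping segments; lagged regressors never cross a trial
#' boundary.
#'
#' @param x channels x T numeric matrix (rows named by channel), or an
#'   existing 3-d trial array which is returned unchanged.
#' @param n_trials number of trials; `T %/% n_trials` samples each,
#'   remainder dropped.
#' @return `trial_set`: array with dim (trial, channel, time).
#' @export
as_trials <- function(x, n_trials = 100) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  x <- as.matrix(x)
  m <- nrow(x)
  len <- ncol(x) %/% n_trials
  stopifnot(len > 1)
  out <- array(NA_real_, c(n_trials, m, len),
               dimnames = list(NULL, rownames(x), NULL))
  for (r in seq_len(n_trials)) {
    out[r, , ] <- x[, ((r - 1) * len + 1):(r * len)]
  }
  out
}

# stacked lagged design for the given channels: returns list(Y, X) where
# X = [1 | lag1..lagp of each channel] pooled over trials
lagged_design <- function(trials, channels, p) {
  nt <- dim(trials)[1]
  len <- dim(trials)[3]
  stopifnot(len > p)
  rows_per <- len - p
  m <- length(channels)
  Y <- matrix(NA_real_, nt * rows_per, m)
  X <- matrix(NA_real_, nt * rows_per, 1 + m * p)
  X[, 1] <- 1
  for (r in seq_len(nt)) {
    idx <- ((r - 1) * rows_per + 1):(r * rows_per)
    seg <- matrix(trials[r, channels, , drop = FALSE], nrow = m)
    Y[idx, ] <- t(seg[, (p + 1):len, drop = FALSE])
    if (p > 0) {
      for (lag in seq_len(p)) {
        cols <- 1 + (lag - 1) * m + seq_len(m)
        X[idx, cols] <- t(seg[, (p + 1 - lag):(len - lag), drop = FALSE])
      }
    }
  }
  list(Y = Y, X = X)
}

#' Fit a vector autoregression across trials
#'
#' Least squares over all trials jointly: lagged regressors are stacked
#' across trials (no lag crosses a trial boundary) and an intercept is
#' included. With `p = 0` the model is just the per-channel mean and the
#' residual covariance equals the sample covariance. The residual
#' covariance uses the pooled-residual maximum-likelihood (1/N) convention.
#'
#' @param trials a `trial_set` array (trial, channel, time) from
#'   [as_trials()].
#' @param p model order (number of lags).
#' @return a `var_model`: list with `p`, `coef` (array p x m x m,
#'   `coef[l, i, j]` = effect of channel j at lag l on channel i),
#'   `intercept`, `sigma` (m x m residual covariance), `n_obs`, `channels`.
#' @export
fit_var <- function(trials, p) {
  chans <- dimnames(trials)[[2]] %||% as.character(seq_len(dim(trials)[2]))
  m <- length(chans)
  d <- lagged_design(trials, seq_len(m), p)
  xtx <- crossprod(d$X)
  if (rcond(xtx) < 1e-12) {
    stop("rank-deficient regressor matrix; try a smaller model order p")
  }
  B <- solve(xtx, crossprod(d$X, d$Y))
  resid <- d$Y - d$X %*% B
  n_obs <- nrow(d$Y)
  sigma <- crossprod(resid) / n_obs
  co <- array(0, c(max(p, 1), m, m), dimnames = list(NULL, chans, chans))
  if (p > 0) {
    for (lag in seq_len(p)) {
      co[lag, , ] <- t(B[1 + (lag - 1) * m + seq_len(m), , drop = FALSE])
    }
  }
  structure(list(p = p, coef = if (p > 0) co else array(0, c(0, m, m)),
                 intercept = B[1, ], sigma = sigma, n_obs = n_obs,
                 channels = chans),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("<var_model> order ", x$p, ", ", length(x$channels),
      " channels, ", x$n_obs, " observations\n", sep = "")
  invisible(x)
}

#' @method tidy var_model
#' @export
tidy.var_model <- function(x, ...) {
  if (x$p == 0) return(tibble::tibble(lag = integer(), target = character(),
                                      source = character(), estimate = double()))
  purrr::map_dfr(seq_len(x$p), function(l) {
    tidyr::expand_grid(target = x$channels, source = x$channels) |>
      dplyr::mutate(lag = l,
                    estimate = purrr::map2_dbl(
                      .data$target, .data$source,
                      function(ti, si) x$coef[l, ti, si]), .before = 1)
  })
}

#' @method glance var_model
#' @export
glance.var_model <- function(x, ...) {
  tibble::tibble(p = x$p, n_obs = x$n_obs,
                 logdet_sigma = determinant(x$sigma)$modulus[1],
                 n_channels = length(x$channels))
}

#' BIC over VAR model orders, and order selection
#'
#' `BIC(p) = log det(Sigma_p) + log(N) * p * m^2 / N`, with `Sigma_p` the
#' pooled ML residual covariance and `N` the number of stacked
#' observations at that order. The default rule returns the argmin; the
#' `"plateau"` rule returns the smallest order whose BIC is within
#' `tol` of the minimum, measured as a fraction of the BIC range over
#' `p_range` (the operational version of picking the order where the BIC
#' curve flattens).
#'
#' @param trials a `trial_set`.
#' @param p_range candidate orders (default 1:31).
#' @param rule `"argmin"` (default) or `"plateau"`.
#' @param tol plateau tolerance as a fraction of the BIC range (default
#'   0.01).
#' @return selected order (integer) with attribute `"bic"`: a tibble of
#'   `p`, `bic`.
#' @export
select_order <- function(trials, p_range = 1:31, rule = c("argmin", "plateau"),
                         tol = 0.01) {
  rule <- match.arg(rule)
  bic <- vapply(p_range, function(p) {
    fit <- fit_var(trials, p)
    ld <- determinant(fit$sigma)$modulus[1]
    m <- length(fit$channels)
    as.numeric(ld + log(fit$n_obs) * (p * m^2) / fit$n_obs)
  }, double(1))
  sel <- if (rule == "argmin") {
    p_range[which.min(bic)]
  } else {
    thr <- min(bic) + tol * diff(range(bic))
    p_range[which(bic <= thr)[1]]
  }
  structure(as.integer(sel), bic = tibble::tibble(p = p_range, bic = bic))
}

# residual variance of `target` regressed on p lags of `regressors`
resid_var <- function(trials, target, regressors, p) {
  d <- lagged_design(trials, regressors, p)
  y <- d$Y[, match(target, regressors)]
  fit <- stats::lm.fit(d$X, y)
  mean(fit$residuals^2)
}

#' Conditional Granger causality between two channels
#'
#' Compares a full VAR in which the target is predicted from its own past,
#' the source's past, and the conditioning channels' pasts, against a
#' reduced model omitting only the source's lags. The magnitude is
#' `ln(reduced residual variance / full residual variance)`, clipped at
#' zero. The measure is invariant to separately rescaling each channel.
#'
#' @param trials a `trial_set`.
#' @param source,target channel indices or names.
#' @param conditioning channels conditioned on in both models (default
#'   none); must not contain the source.
#' @param p model order.
#' @return non-negative GC magnitude (scalar).
#' @export
conditional_gc <- function(trials, source, target, conditioning = integer(),
                           p = 1) {
  chans <- dimnames(trials)[[2]]
  ix <- function(v) if (is.character(v)) match(v, chans) else as.integer(v)
  source <- ix(source); target <- ix(target); conditioning <- ix(conditioning)
  if (source %in% conditioning) stop("source must not be in the conditioning set")
  if (source == target) stop("source and target must differ")
  full <- unique(c(target, conditioning, source))
  red <- unique(c(target, conditioning))
  rv_full <- resid_var(trials, target, full, p)
  rv_red <- resid_var(trials, target, red, p)
  max(0, log(rv_red / rv_full))
}

#' Conditional Granger-causality graph with permutation significance
#'
#' Tests every ordered channel pair, conditioning on all remaining
#' channels. Significance uses a trial-permutation null: the source
#' channel's trials are permuted relative to the target's, destroying any
#' cross-channel temporal relation while preserving within-trial structure;
#' p-values are `(1 + #{perm >= observed}) / (n_perm + 1)` and edges are
#' called significant after Bonferroni correction over the `m (m - 1)`
#' tests.
#'
#' @param trials a `trial_set`.
#' @param p model order (e.g. from [select_order()]).
#' @param alpha family-wise significance level (default 0.01).
#' @param n_perm permutations per pair (default 500).
#' @param seed integer seed for the permutation draws.
#' @return a `gc_graph` tibble: `source`, `target`, `magnitude`,
#'   `p_value`, `significant`. No self-edges.
#' @export
gc_graph <- function(trials, p, alpha = 0.01, n_perm = 500, seed = 1) {
  chans <- dimnames(trials)[[2]] %||% as.character(seq_len(dim(trials)[2]))
  m <- length(chans)
  stopifnot(m >= 2)
  n_tests <- m * (m - 1)
  pairs <- tidyr::expand_grid(source = seq_len(m), target = seq_len(m)) |>
    dplyr::filter(.data$source != .data$target)
  nt <- dim(trials)[1]
  perms <- withr_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(nt))
  })
  res <- purrr::pmap_dfr(pairs, function(source, target) {
    cond <- setdiff(seq_len(m), c(source, target))
    obs <- conditional_gc(trials, source, target, cond, p)
    null <- vapply(perms, function(pp) {
      tp <- trials
      tp[, source, ] <- trials[pp, source, ]
      conditional_gc(tp, source, target, cond, p)
    }, double(1))
    pval <- (1 + sum(null >= obs)) / (n_perm + 1)
    tibble::tibble(source = chans[source], target = chans[target],
                   magnitude = obs, p_value = pval)
  })
  res$significant <- res$p_value <= alpha / n_tests
  class(res) <- c("gc_graph", class(res))
  res
}

#' Export a GC graph
#'
#' @param graph a `gc_graph` tibble.
#' @param path output path; format by extension: `.graphml` (via igraph)
#'   or `.tsv` edge list.
#' @param significant_only keep only significant edges (default TRUE for
#'   graphml, FALSE for tsv).
#' @return `path`, invisibly.
#' @export
write_gc_graph <- function(graph, path, significant_only = grepl("graphml$", path)) {
  g <- if (significant_only) graph[graph$significant, ] else graph
  if (grepl("graphml$", path)) {
    ig <- igraph::graph_from_data_frame(
      g[, c("source", "target", "magnitude", "p_value")],
      vertices = unique(c(graph$source, graph$target)))
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @method autoplot gc_graph
#' @export
autoplot.gc_graph <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$source, y = .data$target,
                               fill = .data$magnitude)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object[object$significant, ], size = 1) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "conditional Granger causality",
                  subtitle = "dot = significant after Bonferroni") +
    ggplot2::theme_minimal()
}
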