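#' Non-negative matrix factorization of population activity
#'
#' Factorizes a non-negative units x bins activity matrix `X` into
#' `W` (units x k loadings) and `H` (k x bins time courses) minimizing the
#' Frobenius objective `||X - W H||_F^2` with multiplicative updates,
#' initialized by non-negative double singular value decomposition with
#' mean filling (NNDSVDa), which is deterministic; `init = "random"` uses
#' the seed. The objective is non-increasing over iterations and the trace
#' is recorded.
#'
#' @param X non-negative matrix (e.g. the binary transistor state matrix
#'   or binned switching counts). Negative entries raise an error telling
#'   the caller to use counts/states, not z-scores.
#' @param k latent dimensionality (default 6).
#' @param seed integer seed (used for random initialization only).
#' @param max_iter maximum update iterations (default 200).
#' @param tol relative objective decrease below which iteration stops
#'   (default 1e-4).
#' @param init `"nndsvda"` (default) or `"random"`.
#' @return a `factorization`: list with `W`, `H`, `k`, `objective`
#'   (per-iteration trace, starting at the initialization), `iterations`,
#'   `converged`, `seed`.
#' @export
nmf_fit <- function(X, k = 6, seed = 1, max_iter = 200, tol = 1e-4,
                    init = c("nndsvda", "random")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (any(X < 0)) {
    stop("X has negative entries; NMF needs counts or state occupancies, ",
         "not z-scored activity")
  }
  storage.mode(X) <- "double"
  eps <- 1e-10
  if (init == "nndsvda") {
    wh <- nndsvda_init(X, k)
  } else {
    wh <- withr_seed(seed, {
      sc <- sqrt(mean(X) / k)
      list(W = matrix(stats::runif(nrow(X) * k, 0, sc), ncol = k),
           H = matrix(stats::runif(k * ncol(X), 0, sc), nrow = k))
    })
  }
  W <- wh$W
  H <- wh$H
  obj <- sum((X - W %*% H)^2)
  trace <- obj
  converged <- FALSE
  iters <- 0
  for (it in seq_len(max_iter)) {
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_obj <- sum((X - W %*% H)^2)
    trace <- c(trace, new_obj)
    iters <- it
    if (obj - new_obj < tol * max(obj, eps)) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  structure(list(W = W, H = H, k = k, objective = trace,
                 iterations = iters, converged = converged, seed = seed),
            class = "factorization")
}

# NNDSVD initialization with mean filling (the "a" variant): the leading
# singular pairs are split into sign-consistent parts, and zeros are
# replaced by the matrix mean so multiplicative updates can escape them
nndsvda_init <- function(X, k) {
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      upn <- sqrt(sum(up^2)); unn <- sqrt(sum(un^2))
      vpn <- sqrt(sum(vp^2)); vnn <- sqrt(sum(vn^2))
      if (upn * vpn >= unn * vnn) {
        sig <- upn * vpn
        if (sig > 0) {
          W[, j] <- sqrt(s$d[j] * sig) * up / upn
          H[j, ] <- sqrt(s$d[j] * sig) * vp / vpn
        }
      } else {
        sig <- unn * vnn
        W[, j] <- sqrt(s$d[j] * sig) * un / unn
        H[j, ] <- sqrt(s$d[j] * sig) * vn / vnn
      }
    }
  }
  avg <- mean(X)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

#' @export
print.factorization <- function(x, ...) {
  cat("<factorization> k = ", x$k, ", ", nrow(x$W), " units x ",
      ncol(x$H), " bins; objective ",
      format(utils::tail(x$objective, 1), digits = 6),
      if (x$converged) " (converged)" else " (max_iter)", "\n", sep = "")
  invisible(x)
}

#' @method tidy factorization
#' @export
tidy.factorization <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::as_tibble(x$W, .name_repair = ~ paste0("comp", seq_len(x$k))) |>
      dplyr::mutate(unit = rownames(x$W) %||% as.character(dplyr::row_number()),
                    .before = 1) |>
      tidyr::pivot_longer(-"unit", names_to = "component",
                          values_to = "loading")
  } else {
    tibble::as_tibble(t(x$H), .name_repair = ~ paste0("comp", seq_len(x$k))) |>
      dplyr::mutate(bin = dplyr::row_number(), .before = 1) |>
      tidyr::pivot_longer(-"bin", names_to = "component",
                          values_to = "activity")
  }
}

#' @method glance factorization
#' @export
glance.factorization <- function(x, ...) {
  tibble::tibble(k = x$k, objective = utils::tail(x$objective, 1),
                 iterations = x$iterations, converged = x$converged)
}

#' @method autoplot factorization
#' @export
autoplot.factorization <- function(object, ...) {
  ggplot2::ggplot(tidy(object, "H"),
                  ggplot2::aes(x = .data$bin, y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time bin", y = "component activity") +
    ggplot2::theme_minimal()
}

#' Interpret NMF components against known signals
#'
#' Computes the signed Pearson correlation of each component time course
#' (row of `H`) with each known signal, binned identically to the activity
#' matrix, and assigns each unit its dominant component (argmax of its `W`
#' row) with the loading magnitude — the machine-readable version of
#' coloring each transistor by the dimension where it has maximum value.
#'
#' @param fit a `factorization`.
#' @param signals bins x n_signals numeric matrix (columns named), on the
#'   same bin grid as the factorized matrix.
#' @param positions optional units x 2 coordinate matrix for the dominant
#'   component map.
#' @return a `component_interpretation`: list with `correlations`
#'   (k x n_signals matrix, entries in `[-1, 1]`; constant signals or
#'   components give NA) and `dominant` (tibble `unit`, `component`,
#'   `magnitude`, plus `x`, `y` when positions are given).
#' @export
interpret_components <- function(fit, signals, positions = NULL) {
  signals <- as.matrix(signals)
  stopifnot(ncol(fit$H) == nrow(signals))
  co <- suppressWarnings(stats::cor(t(fit$H), signals))
  rownames(co) <- paste0("comp", seq_len(fit$k))
  dom <- tibble::tibble(
    unit = rownames(fit$W) %||% as.character(seq_len(nrow(fit$W))),
    component = apply(fit$W, 1, which.max),
    magnitude = apply(fit$W, 1, max))
  if (!is.null(positions)) {
    dom$x <- positions[, 1]
    dom$y <- positions[, 2]
  }
  structure(list(correlations = co, dominant = dom),
            class = "component_interpretation")
}

#' @export
print.component_interpretation <- function(x, ...) {
  cat("<component_interpretation> ", nrow(x$correlations), " components x ",
      ncol(x$correlations), " signals\n", sep = "")
  best <- apply(abs(x$correlations), 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  for (i in seq_along(best)) {
    if (!is.na(best[i])) {
      cat("  ", rownames(x$correlations)[i], " ~ ",
          colnames(x$correlations)[best[i]], " (r = ",
          round(x$correlations[i, best[i]], 3), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Match estimated components to planted ones
#'
#' Resolves NMF's permutation/scale ambiguity for scoring: finds the
#' one-to-one assignment of estimated to reference components maximizing
#' the total absolute Pearson correlation (exhaustive over permutations
#' for small k), and reports the per-pair correlations.
#'
#' @param H_hat,H_ref k x bins matrices (or units x k, matched on the
#'   common dimension).
#' @return tibble `estimated`, `reference`, `correlation` (absolute), one
#'   row per matched pair.
#' @export
match_components <- function(H_hat, H_ref) {
  stopifnot(nrow(H_hat) == nrow(H_ref))
  k <- nrow(H_hat)
  if (k > 8) stop("exhaustive matching supported for k <= 8")
  co <- abs(stats::cor(t(H_hat), t(H_ref)))
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(co[cbind(seq_len(k), p)]), double(1))
  best <- perms[[which.max(scores)]]
  tibble::tibble(estimated = seq_len(k), reference = best,
                 correlation = co[cbind(seq_len(k), best)])
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}
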