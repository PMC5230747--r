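#' Terminal-pair relation graphs of a netlist
#'
#' Builds the six binary adjacency matrices over transistors, one per
#' ordered terminal pair — G->C1, G->C2, C1->C2, C2->C1, C1->G, C2->G —
#' where relation A->B has edge (i, j) iff terminal A of transistor i and
#' terminal B of transistor j sit on the same wire. Power and ground wires
#' are excluded (they would connect nearly everything); self-edges are
#' excluded. By construction an edge in C1->C2 of (i, j) corresponds to an
#' edge in C2->C1 of (j, i).
#'
#' @param nl a `netlist`.
#' @return a `relation_graphs`: named list of six 0/1 matrices (node order
#'   = transistor id order) plus `distance`, the pairwise layout distance
#'   matrix.
#' @export
build_relations <- function(nl) {
  tr <- nl$transistors
  excl <- c(power_id(nl), ground_id(nl))
  mask <- function(w) ifelse(w %in% excl, NA_integer_, w)
  term <- list(G = mask(tr$gate), C1 = mask(tr$c1), C2 = mask(tr$c2))
  shares <- function(a, b) {
    m <- outer(term[[a]], term[[b]], function(x, y) !is.na(x) & x == y)
    m[is.na(m)] <- FALSE
    diag(m) <- FALSE
    m * 1L
  }
  rels <- list(
    G_C1 = shares("G", "C1"), G_C2 = shares("G", "C2"),
    C1_C2 = shares("C1", "C2"), C2_C1 = shares("C2", "C1"),
    C1_G = shares("C1", "G"), C2_G = shares("C2", "G"))
  structure(list(relations = rels,
                 distance = as.matrix(stats::dist(cbind(tr$x, tr$y))),
                 node_ids = tr$id),
            class = "relation_graphs")
}

#' @export
print.relation_graphs <- function(x, ...) {
  n <- length(x$node_ids)
  cat("<relation_graphs> ", n, " nodes; edges per relation: ",
      paste(names(x$relations),
            vapply(x$relations, sum, double(1)), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Bernoulli-Beta(1,1) collapsed log marginal likelihood of one relation
# given block assignment counts; e = edge counts, n = pair counts
block_loglik <- function(e, n) sum(lbeta(1 + e, 1 + n - e) - lbeta(1, 1))

block_counts <- function(A, z, K) {
  # e[a,b] = edges from block a to block b (diagonal pairs i==j excluded)
  Z <- matrix(0, length(z), K)
  Z[cbind(seq_along(z), z)] <- 1
  t(Z) %*% A %*% Z
}

pair_counts <- function(sizes) {
  n <- outer(sizes, sizes)
  diag(n) <- sizes * (sizes - 1)
  n
}

#' Joint log posterior of a shared block assignment
#'
#' Bernoulli stochastic block model with Beta(1, 1) edge-probability priors
#' applied jointly to all relations with one shared node-to-block
#' assignment; the label prior is uniform, so this is the collapsed log
#' marginal likelihood up to a constant. Invariant under label
#' permutations.
#'
#' @param rg a `relation_graphs` (or list of adjacency matrices).
#' @param z integer block labels in `1..K`.
#' @param K number of blocks.
#' @return scalar log posterior (up to an additive constant).
#' @export
sbm_log_posterior <- function(rg, z, K = max(z)) {
  rels <- if (inherits(rg, "relation_graphs")) rg$relations else rg
  sizes <- tabulate(z, nbins = K)
  n <- pair_counts(sizes)
  sum(vapply(rels, function(A) block_loglik(block_counts(A, z, K), n),
             double(1)))
}

#' Fit a shared-assignment stochastic block model
#'
#' Collapsed Gibbs sampling for a fixed-K Bernoulli SBM fit jointly to the
#' six terminal-pair relations with one shared assignment: edge
#' probabilities are integrated out under Beta(1, 1) priors and node labels
#' are resampled one at a time from their full conditionals. The
#' best-posterior assignment visited is tracked and returned, so the
#' reported posterior never decreases below the initialization.
#' Deterministic given the seed.
#'
#' This is a documented simplification of the nonparametric
#' distance-dependent block model this analysis descends from: K is fixed,
#' and distance enters only through the optional logistic distance-decay
#' reweighting flag.
#'
#' @param rg a `relation_graphs` or list of square 0/1 matrices.
#' @param K number of blocks (>= 1; error if K exceeds the node count).
#' @param seed integer seed.
#' @param sweeps full Gibbs sweeps per chain (default 30).
#' @param restarts independent chains from random initializations; the
#'   assignment with the best posterior across chains is returned. Single-
#'   site Gibbs mixes poorly between block-relabeling modes, so a few
#'   restarts are the standard way to reach the dominant mode (default 5).
#' @param distance_decay if TRUE, edges are logistically downweighted with
#'   layout distance when computing the likelihood (experimental flag;
#'   default FALSE).
#' @return a `block_assignment`: list with `labels` (tibble `node`,
#'   `cluster`), `K`, `log_posterior` (best found), `trace` (best-so-far
#'   log posterior per sweep), `edge_probability` (per-relation K x K
#'   posterior-mean matrices).
#' @export
sbm_fit <- function(rg, K, seed = 1, sweeps = 30, restarts = 5,
                    distance_decay = FALSE) {
  rels <- if (inherits(rg, "relation_graphs")) rg$relations else rg
  node_ids <- if (inherits(rg, "relation_graphs")) rg$node_ids else
    seq_len(nrow(rels[[1]]))
  n <- nrow(rels[[1]])
  stopifnot(K >= 1)
  if (K > n) stop("K exceeds the number of nodes (", n, ")")
  if (distance_decay && inherits(rg, "relation_graphs")) {
    d <- rg$distance
    wgt <- 1 / (1 + exp((d - stats::median(d)) / (stats::mad(d) + 1e-9)))
    rels <- lapply(rels, function(A) A * wgt)
  }
  R <- length(rels)

  run <- withr_seed(seed, {
    best <- NULL
    for (chain in seq_len(restarts)) {
      res <- sbm_gibbs_chain(rels, n, K, R, sweeps)
      if (is.null(best) || res$lp > best$lp) best <- res
      if (K == 1) break
    }
    best
  })

  sizes <- tabulate(run$z, nbins = K)
  np <- pair_counts(sizes)
  probs <- lapply(rels, function(A) {
    e <- block_counts(A, run$z, K)
    (e + 1) / (np + 2)
  })
  structure(
    list(labels = tibble::tibble(node = node_ids, cluster = run$z),
         K = K, log_posterior = run$lp, trace = run$trace,
         edge_probability = probs),
    class = "block_assignment")
}

# one Gibbs chain from a random initialization; uses the caller's RNG stream
sbm_gibbs_chain <- function(rels, n, K, R, sweeps) {
  {
    z <- sample.int(K, n, replace = TRUE)
    sizes <- tabulate(z, nbins = K)
    E <- lapply(rels, function(A) block_counts(A, z, K))
    cur_lp <- function() {
      np <- pair_counts(sizes)
      sum(vapply(E, function(e) block_loglik(e, np), double(1)))
    }
    best_lp <- cur_lp()
    best_z <- z
    trace <- numeric(sweeps)
    if (K > 1) {
      for (sw in seq_len(sweeps)) {
        Zmat <- matrix(0, n, K)
        Zmat[cbind(seq_len(n), z)] <- 1
        for (i in sample.int(n)) {
          zi <- z[i]
          out_i <- lapply(rels, function(A) as.numeric(A[i, ] %*% Zmat))
          in_i <- lapply(rels, function(A) as.numeric(A[, i] %*% Zmat))
          for (r in seq_len(R)) {
            E[[r]][zi, ] <- E[[r]][zi, ] - out_i[[r]]
            E[[r]][, zi] <- E[[r]][, zi] - in_i[[r]]
          }
          sizes[zi] <- sizes[zi] - 1L
          # candidate score = (row/col-k terms with i in block k) minus the
          # same terms without i; the remaining table entries are identical
          # across candidates only after this base subtraction
          score <- vapply(seq_len(K), function(k) {
            sz <- sizes
            sz[k] <- sz[k] + 1L
            np_row <- sz[k] * sz
            np_row[k] <- sz[k] * (sz[k] - 1L)
            np0_row <- sizes[k] * sizes
            np0_row[k] <- sizes[k] * (sizes[k] - 1L)
            tot <- 0
            for (r in seq_len(R)) {
              rowv <- E[[r]][k, ] + out_i[[r]]
              rowv[k] <- rowv[k] + in_i[[r]][k]
              colv <- E[[r]][, k] + in_i[[r]]
              tot <- tot + sum(lbeta(1 + rowv, 1 + np_row - rowv)) +
                sum(lbeta(1 + colv[-k], 1 + np_row[-k] - colv[-k])) -
                sum(lbeta(1 + E[[r]][k, ], 1 + np0_row - E[[r]][k, ])) -
                sum(lbeta(1 + E[[r]][-k, k], 1 + np0_row[-k] - E[[r]][-k, k]))
            }
            tot
          }, double(1))
          pr <- exp(score - max(score))
          znew <- sample.int(K, 1, prob = pr)
          z[i] <- znew
          Zmat[i, ] <- 0
          Zmat[i, znew] <- 1
          for (r in seq_len(R)) {
            E[[r]][znew, ] <- E[[r]][znew, ] + out_i[[r]]
            E[[r]][, znew] <- E[[r]][, znew] + in_i[[r]]
          }
          sizes[znew] <- sizes[znew] + 1L
        }
        lp_now <- cur_lp()
        if (lp_now > best_lp) {
          best_lp <- lp_now
          best_z <- z
        }
        trace[sw] <- best_lp
      }
    } else {
      trace <- rep(best_lp, sweeps)
    }
    list(z = best_z, lp = best_lp, trace = trace)
  }
}

#' @export
print.block_assignment <- function(x, ...) {
  cat("<block_assignment> K = ", x$K, ", sizes: ",
      paste(tabulate(x$labels$cluster, nbins = x$K), collapse = "/"),
      ", log posterior ", format(x$log_posterior, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @method tidy block_assignment
#' @export
tidy.block_assignment <- function(x, ...) x$labels

#' @method glance block_assignment
#' @export
glance.block_assignment <- function(x, ...) {
  tibble::tibble(K = x$K, log_posterior = x$log_posterior,
                 n_nodes = nrow(x$labels))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same nodes;
#' 1 means identical up to label permutation, 0 is chance level.
#'
#' @param a,b integer label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Write a block assignment and relation matrices to CSV
#' @param x a `block_assignment`.
#' @param rg the `relation_graphs` it was fit to (optional; writes sparse
#'   triplets per relation when given).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sbm <- function(x, rg = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$labels, file.path(dir, "assignment.csv"),
                   row.names = FALSE)
  if (!is.null(rg)) {
    for (nm in names(rg$relations)) {
      A <- rg$relations[[nm]]
      ij <- which(A != 0, arr.ind = TRUE)
      utils::write.csv(
        tibble::tibble(from = rg$node_ids[ij[, 1]],
                       to = rg$node_ids[ij[, 2]],
                       value = A[ij]),
        file.path(dir, paste0("relation_", nm, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
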