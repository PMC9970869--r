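#' Single KL-divergence NMF factorization
#'
#' Factorizes a non-negative catalog \code{M} (channels x samples) into
#' \code{S A} with \code{S} a channels x k signature matrix (columns sum to
#' 1, scale absorbed into \code{A}) by the multiplicative-update algorithm
#' minimizing the generalized Kullback-Leibler divergence, the
#' maximum-likelihood objective under a Poisson count model. \code{S} and
#' \code{A} are initialized with uniform(0,1] draws (strictly positive so
#' multiplicative updates cannot lock at zero). All-zero rows of \code{M}
#' are removed before factorization and restored as zero signature rows.
#'
#' @param M Non-negative numeric matrix (channels x samples).
#' @param k Rank, \code{1 <= k <= min(dim(M))}.
#' @param seed Integer seed for the random initialization.
#' @param min_iter,max_iter Iteration bounds (defaults 10000 and 1e6).
#' @param tol Relative objective-change convergence tolerance (default 1e-14).
#' @param check_every Objective checkpoint interval in iterations.
#' @return List of class \code{nmf_solution}: \code{S}, \code{A},
#'   \code{objective} (final KL divergence), \code{iterations}, \code{seed}.
#' @export
nmf_kl <- function(M, k, seed = 1L, min_iter = 10000L, max_iter = 1000000L,
                   tol = 1e-14, check_every = 100L) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("M must be non-negative")
  if (k < 1 || k > min(dim(M))) stop("k must lie in [1, min(dim(M))]")
  keep_rows <- rowSums(M) > 0
  keep_cols <- colSums(M) > 0
  Mr <- M[keep_rows, keep_cols, drop = FALSE]
  if (!nrow(Mr) || !ncol(Mr)) stop("M has no positive entries")
  if (k > min(dim(Mr))) stop("k exceeds the dimensions of the nonzero submatrix")
  init <- with_seed(seed, {
    list(S = matrix(1 - stats::runif(nrow(Mr) * k), nrow(Mr), k),
         A = matrix(1 - stats::runif(k * ncol(Mr)), k, ncol(Mr)))
  })
  init$S <- sweep(init$S, 2, colSums(init$S), "/")
  init$A <- init$A * (sum(Mr) / sum(init$A))  # start near the data scale
  fit <- nmf_kl_engine(Mr, init$S, init$A, as.integer(min_iter),
                       as.integer(max_iter), tol, as.integer(check_every))
  S <- matrix(0, nrow(M), k, dimnames = list(rownames(M), paste0("Sig", seq_len(k))))
  S[keep_rows, ] <- fit$S
  A <- matrix(0, k, ncol(M), dimnames = list(paste0("Sig", seq_len(k)), colnames(M)))
  A[, keep_cols] <- fit$A
  structure(list(S = S, A = A, objective = fit$objective,
                 iterations = fit$iterations, seed = seed),
            class = "nmf_solution")
}

cosine_matrix <- function(X, Y) {
  nx <- sqrt(colSums(X^2)); ny <- sqrt(colSums(Y^2))
  crossprod(X, Y) / outer(pmax(nx, 1e-300), pmax(ny, 1e-300))
}

# Greedy one-to-one assignment of columns of X to columns of Y maximizing
# cosine similarity (k is small; greedy on the sorted similarity matrix).
greedy_assign <- function(sim) {
  k <- nrow(sim)
  assign <- integer(k)
  free_r <- rep(TRUE, k); free_c <- rep(TRUE, k)
  for (step in seq_len(k)) {
    m <- sim
    m[!free_r, ] <- -Inf; m[, !free_c] <- -Inf
    idx <- arrayInd(which.max(m), dim(m))
    assign[idx[1]] <- idx[2]
    free_r[idx[1]] <- FALSE; free_c[idx[2]] <- FALSE
  }
  assign
}

# silhouette widths under cosine distance for a hard partition
silhouette_cosine <- function(X, cluster) {
  k <- max(cluster)
  d <- 1 - cosine_matrix(X, X)
  n <- ncol(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cluster == cluster[i]); own <- setdiff(own, i)
    a <- if (length(own)) mean(d[i, own]) else 0
    b <- Inf
    for (cl in setdiff(seq_len(k), cluster[i])) {
      mem <- which(cluster == cl)
      if (length(mem)) b <- min(b, mean(d[i, mem]))
    }
    s[i] <- if (is.finite(b) && max(a, b) > 0) (b - a) / max(a, b) else 1
  }
  s
}

#' Replicated extraction with consensus clustering and stability
#'
#' Runs \code{n_replicates} independent KL-NMF factorizations from random
#' initializations (distinct derived seeds), pools the replicate signature
#' columns and partitions them into \code{k} clusters: each replicate's
#' columns are matched one-to-one to the columns of the best (lowest
#' objective) replicate by cosine similarity, then the partition is refined
#' by alternating centroid computation and per-replicate optimal
#' reassignment. The consensus signature is the normalized cluster centroid;
#' per-signature stability is the mean silhouette width of its cluster under
#' cosine distance (1 by convention at k = 1). Consensus activities are
#' obtained by per-sample NNLS refit of \code{M} against the consensus
#' signatures.
#'
#' @param M Catalog matrix (channels x samples).
#' @param k Rank.
#' @param n_replicates Number of replicate factorizations (>= 2; the
#'   published protocol uses 500).
#' @param seed Integer seed; replicate r uses a seed derived from it.
#' @param ... Passed to \code{\link{nmf_kl}} (\code{min_iter},
#'   \code{max_iter}, \code{tol}, \code{check_every}).
#' @return List of class \code{extraction_solution}: \code{k}, \code{S}
#'   (consensus signatures), \code{A} (consensus activities),
#'   \code{stability} (per signature), \code{avg_stability},
#'   \code{reconstruction_error} (Frobenius), \code{kl_error},
#'   \code{n_replicates}, \code{seed}.
#' @export
extract_consensus <- function(M, k, n_replicates = 100L, seed = 1L, ...) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  M <- as.matrix(M)
  reps <- lapply(seq_len(n_replicates), function(r)
    nmf_kl(M, k, seed = derive_seed(seed, 100L + r), ...))
  objective <- vapply(reps, `[[`, 0, "objective")
  best <- which.min(objective)
  pooled <- do.call(cbind, lapply(reps, `[[`, "S"))     # channels x (k*nrep)
  rep_id <- rep(seq_len(n_replicates), each = k)
  cluster <- integer(ncol(pooled))
  ref <- reps[[best]]$S
  for (r in seq_len(n_replicates)) {
    cols <- which(rep_id == r)
    cluster[cols] <- greedy_assign(cosine_matrix(pooled[, cols, drop = FALSE], ref))
  }
  if (k > 1) {
    for (sweep_i in 1:20) {
      centroids <- sapply(seq_len(k), function(cl)
        rowMeans(pooled[, cluster == cl, drop = FALSE]))
      new_cluster <- cluster
      for (r in seq_len(n_replicates)) {
        cols <- which(rep_id == r)
        new_cluster[cols] <- greedy_assign(
          cosine_matrix(pooled[, cols, drop = FALSE], centroids))
      }
      if (identical(new_cluster, cluster)) break
      cluster <- new_cluster
    }
  } else cluster <- rep(1L, ncol(pooled))
  centroids <- sapply(seq_len(k), function(cl)
    rowMeans(pooled[, cluster == cl, drop = FALSE]))
  centroids <- matrix(centroids, nrow = nrow(M))
  S <- sweep(centroids, 2, colSums(centroids), "/")
  dimnames(S) <- list(rownames(M), paste0("Sig", seq_len(k)))
  stab <- if (k == 1) 1 else {
    sil <- silhouette_cosine(pooled, cluster)
    vapply(seq_len(k), function(cl) mean(sil[cluster == cl]), 0)
  }
  stab <- rep_len(stab, k)
  A <- refit_exposures(M, S)
  recon <- S %*% A
  structure(list(k = k, S = S, A = A, stability = stab,
                 avg_stability = mean(stab),
                 reconstruction_error = norm(M - recon, "F"),
                 kl_error = generalized_kl(M, recon),
                 n_replicates = n_replicates, seed = seed,
                 replicate_objectives = objective),
            class = "extraction_solution")
}

generalized_kl <- function(M, R) {
  R <- pmax(R, 1e-12)
  pos <- M > 0
  sum(M[pos] * log(M[pos] / R[pos]) - M[pos]) + sum(R)
}

# per-sample NNLS refit of counts against normalized signatures
refit_exposures <- function(M, S) {
  A <- vapply(seq_len(ncol(M)), function(s)
    pracma::lsqnonneg(S, M[, s])$x, numeric(ncol(S)))
  A <- matrix(A, nrow = ncol(S),
              dimnames = list(colnames(S), colnames(M)))
  A
}

#' @export
print.extraction_solution <- function(x, ...) {
  cat(sprintf("extraction_solution: k = %d, %d replicates, avg stability %.3f (min %.3f)\n",
              x$k, x$n_replicates, x$avg_stability, min(x$stability)))
  invisible(x)
}

#' Match estimated signatures to a reference set
#'
#' One-to-one assignment of estimated signature columns to reference
#' columns maximizing total cosine similarity (exhaustive over
#' permutations for k <= 7, greedy otherwise).
#'
#' @param estimated,truth Channels x k matrices with equal k.
#' @return List: \code{index} (for each truth column, the matching
#'   estimated column), \code{cosine} (per truth signature).
#' @export
match_signatures <- function(estimated, truth) {
  k <- ncol(truth)
  stopifnot(ncol(estimated) == k)
  sim <- cosine_matrix(estimated, truth)  # rows = estimated, cols = truth
  if (k <= 7) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(sim[cbind(p, seq_len(k))]), 0)
    best <- perms[[which.max(scores)]]
  } else {
    best <- greedy_assign(t(sim))         # truth rows pick estimated columns
  }
  list(index = best, cosine = sim[cbind(best, seq_len(k))])
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L)) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Stability-based rank selection
#'
#' Returns the largest rank whose solution has average stability at least
#' \code{min_avg} and no individual signature with stability below
#' \code{min_each}. If no rank qualifies, the rank with maximal average
#' stability is returned flagged unstable. An optional manual override
#' shifts the selection by +/-1 within the evaluated range (recorded in the
#' result), mirroring the visual-inspection adjustment of the published
#' protocol.
#'
#' @param solutions List of \code{extraction_solution} objects (one per rank).
#' @param min_avg Minimum average stability (default 0.80).
#' @param min_each Minimum per-signature stability (default 0.2).
#' @param manual_override 0 (default), +1 or -1.
#' @return List: \code{k} (selected rank), \code{stable} (logical),
#'   \code{override_applied}, \code{table} (per-rank stability summary).
#' @export
select_rank <- function(solutions, min_avg = 0.80, min_each = 0.2,
                        manual_override = 0L) {
  if (!length(solutions)) stop("no solutions supplied")
  ks <- vapply(solutions, function(s) as.integer(s$k), 0L)
  avg <- vapply(solutions, `[[`, 0, "avg_stability")
  mn <- vapply(solutions, function(s) min(s$stability), 0)
  pass <- avg >= min_avg & mn >= min_each
  if (any(pass)) {
    k_sel <- max(ks[pass])   # ties toward larger k
    stable <- TRUE
  } else {
    k_sel <- ks[which.max(avg)]
    stable <- FALSE
  }
  override_applied <- 0L
  if (manual_override != 0) {
    k_new <- k_sel + sign(manual_override)
    if (k_new %in% ks) { k_sel <- k_new; override_applied <- as.integer(sign(manual_override)) }
  }
  list(k = k_sel, stable = stable, override_applied = override_applied,
       table = data.frame(k = ks, avg_stability = avg, min_stability = mn,
                          pass = pass))
}
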