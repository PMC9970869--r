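#' Cosine similarity of two channel vectors
#' @param u,v Equal-length non-negative numeric vectors, each with at least
#'   one positive entry.
#' @return Cosine similarity in [0, 1] for non-negative inputs.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Non-negative least squares fit
#'
#' Minimizes the Euclidean residual \code{||basis w - target||} subject to
#' \code{w >= 0} (Lawson-Hanson active set).
#'
#' @param target Channel vector.
#' @param basis Channels x signatures matrix.
#' @return Named non-negative weight vector.
#' @export
nnls_fit <- function(target, basis) {
  basis <- as.matrix(basis)
  if (!ncol(basis)) stop("empty basis")
  w <- pracma::lsqnonneg(basis, as.numeric(target))$x
  stats::setNames(w, colnames(basis))
}

recon_cosine <- function(target, basis, w) {
  r <- as.matrix(basis) %*% w
  if (sum(r) == 0) return(0)
  cosine_similarity(as.numeric(target), as.numeric(r))
}

#' Decompose a de novo signature into a reference catalog
#'
#' Greedy forward addition: at each step the reference signature whose
#' addition maximally improves the NNLS reconstruction cosine is added,
#' provided the improvement is at least \code{min_gain}. Backward removal
#' then drops any selected signature whose removal decreases the cosine by
#' less than \code{min_gain} (NNLS refit after every change). The
#' decomposition is accepted when the final reconstruction cosine reaches
#' \code{min_cosine}; otherwise the de novo signature is reported novel.
#' Equal gains are broken toward the lexicographically smaller label.
#'
#' @param denovo Channel probability vector.
#' @param reference Channels x signatures reference matrix (columns sum to
#'   1) with signature labels as colnames.
#' @param min_cosine Acceptance threshold on the reconstruction cosine
#'   (default 0.85).
#' @param min_gain Minimum cosine improvement to add (or keep) a signature
#'   (default 0.01).
#' @return List of class \code{decomposition}: \code{weights} (non-negative,
#'   sum 1, over selected signatures), \code{cosine}, \code{accepted},
#'   \code{selected}.
#' @export
decompose_to_reference <- function(denovo, reference, min_cosine = 0.85,
                                   min_gain = 0.01) {
  reference <- as.matrix(reference)
  if (length(denovo) != nrow(reference)) stop("channel schemes do not match")
  labels <- colnames(reference)
  if (is.null(labels)) stop("reference signatures must be labelled")
  labels <- labels[order(labels)]
  selected <- character(0)
  current_cos <- 0
  repeat {
    cands <- setdiff(labels, selected)
    if (!length(cands)) break
    gains <- vapply(cands, function(lab) {
      basis <- reference[, c(selected, lab), drop = FALSE]
      recon_cosine(denovo, basis, nnls_fit(denovo, basis))
    }, 0)
    best <- which.max(gains)  # first max = lexicographically smallest label
    if (gains[best] - current_cos >= min_gain) {
      selected <- c(selected, cands[best])
      current_cos <- gains[best]
    } else break
  }
  # backward removal
  changed <- TRUE
  while (changed && length(selected) > 1) {
    changed <- FALSE
    for (lab in sort(selected)) {
      rest <- setdiff(selected, lab)
      basis <- reference[, rest, drop = FALSE]
      cos_wo <- recon_cosine(denovo, basis, nnls_fit(denovo, basis))
      if (current_cos - cos_wo < min_gain) {
        selected <- rest
        current_cos <- cos_wo
        changed <- TRUE
        break
      }
    }
  }
  basis <- reference[, selected, drop = FALSE]
  w <- nnls_fit(denovo, basis)
  cosine <- recon_cosine(denovo, basis, w)
  weights <- if (sum(w) > 0) w / sum(w) else w
  structure(list(weights = weights, cosine = cosine,
                 accepted = cosine >= min_cosine, selected = sort(selected)),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("decomposition: cosine %.4f, %s\n", x$cosine,
              if (x$accepted) "accepted" else "novel/unexplained"))
  print(round(x$weights, 4))
  invisible(x)
}

#' Background-signature rule for per-sample refitting
#'
#' Clock-like SBS1 and SBS5 are assumed active in every sample; the tested
#' signature (default SBS3) is admitted only when adding it to the NNLS fit
#' improves the reconstruction cosine by at least \code{delta}.
#'
#' @param sample_counts Channel count vector for one sample.
#' @param reference Reference signature matrix.
#' @param delta Minimum cosine improvement (default 0.02).
#' @param background Always-allowed labels (default SBS1, SBS5).
#' @param test Conditionally added label (default SBS3).
#' @return Character vector of allowed signature labels.
#' @export
apply_background_rule <- function(sample_counts, reference, delta = 0.02,
                                  background = c("SBS1", "SBS5"),
                                  test = "SBS3") {
  reference <- as.matrix(reference)
  need <- c(background, test)
  if (!all(need %in% colnames(reference)))
    stop("reference lacks required signatures: ",
         paste(setdiff(need, colnames(reference)), collapse = ", "))
  base_basis <- reference[, background, drop = FALSE]
  cos_base <- recon_cosine(sample_counts, base_basis,
                           nnls_fit(sample_counts, base_basis))
  full_basis <- reference[, c(background, test), drop = FALSE]
  cos_full <- recon_cosine(sample_counts, full_basis,
                           nnls_fit(sample_counts, full_basis))
  if (cos_full - cos_base >= delta) c(background, test) else background
}

#' Refit one sample's exposures against an allowed signature set
#'
#' NNLS fit of the probability-normalized sample profile against the
#' allowed reference signatures; weights are rescaled to mutation counts so
#' the exposures sum to the sample total times the fitted fraction.
#'
#' @param sample_counts Channel count vector.
#' @param allowed Labels of the allowed signatures.
#' @param reference Reference signature matrix.
#' @return List: \code{exposures} (named, count units), \code{cosine}.
#' @export
refit_sample <- function(sample_counts, allowed, reference) {
  reference <- as.matrix(reference)
  if (!length(allowed)) stop("empty allowed signature set")
  if (!all(allowed %in% colnames(reference)))
    stop("allowed set contains labels absent from the reference")
  total <- sum(sample_counts)
  basis <- reference[, allowed, drop = FALSE]
  if (total == 0)
    return(list(exposures = stats::setNames(numeric(length(allowed)), allowed),
                cosine = NA_real_))
  p <- sample_counts / total
  w <- nnls_fit(p, basis)
  list(exposures = w * total, cosine = recon_cosine(p, basis, w))
}

#' Refit every sample of a catalog, optionally under the background rule
#'
#' @param M Catalog (channels x samples).
#' @param reference Reference signature matrix.
#' @param allowed Signature labels to fit (default: all reference columns).
#' @param background_rule If TRUE, restrict each sample to the background
#'   set plus the conditionally tested signature (see
#'   \code{\link{apply_background_rule}}).
#' @param delta Cosine-improvement threshold for the tested signature.
#' @param background,test Passed to \code{apply_background_rule}.
#' @return List: \code{exposures} (signatures x samples), \code{cosine}
#'   (per sample).
#' @export
refit_catalog <- function(M, reference, allowed = NULL,
                          background_rule = FALSE, delta = 0.02,
                          background = c("SBS1", "SBS5"), test = "SBS3") {
  M <- as.matrix(M)
  reference <- as.matrix(reference)
  labels <- colnames(reference)
  if (is.null(allowed)) allowed <- labels
  E <- matrix(0, length(labels), ncol(M), dimnames = list(labels, colnames(M)))
  cosv <- stats::setNames(rep(NA_real_, ncol(M)), colnames(M))
  for (s in seq_len(ncol(M))) {
    al <- if (background_rule)
      apply_background_rule(M[, s], reference, delta = delta,
                            background = background, test = test)
    else allowed
    fit <- refit_sample(M[, s], al, reference)
    E[names(fit$exposures), s] <- fit$exposures
    cosv[s] <- fit$cosine
  }
  list(exposures = E, cosine = cosv)
}

#' Zero out low-activity signatures per sample
#'
#' Signatures contributing less than \code{threshold} of a sample's fitted
#' mutation total are set to zero; the removed mass is not redistributed,
#' so column totals drop and the removed fraction is reported.
#'
#' @param exposures Signatures x samples non-negative matrix.
#' @param threshold Minimum activity fraction (default 0.05).
#' @return Filtered exposure matrix; attribute \code{removed_mass} gives
#'   the per-sample mass removed.
#' @export
filter_min_activity <- function(exposures, threshold = 0.05) {
  exposures <- as.matrix(exposures)
  if (any(exposures < 0)) stop("exposures must be non-negative")
  out <- exposures
  removed <- numeric(ncol(out))
  for (s in seq_len(ncol(out))) {
    tot <- sum(out[, s])
    if (tot == 0) next
    low <- out[, s] / tot < threshold
    removed[s] <- sum(out[low, s])
    out[low, s] <- 0
  }
  attr(out, "removed_mass") <- stats::setNames(removed, colnames(out))
  out
}
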