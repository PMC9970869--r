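#' Benjamini-Hochberg adjustment
#' @param p Vector of p-values in [0, 1].
#' @return Step-up adjusted p-values (monotone, capped at 1).
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities not exceeding that of the observed
#' table. A table with a zero margin carries no information and returns
#' p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Two-sided Wilcoxon rank sum test
#'
#' Exact distribution for small samples without ties (n + m <= 20), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                      correct = !use_exact)$p.value)
}

#' Clock-like age correlation of signature activities
#'
#' Per signature, Spearman and Pearson correlation of exposure with age at
#' diagnosis, with Benjamini-Hochberg adjustment across signatures within
#' each coefficient family.
#'
#' @param exposures Signatures x samples matrix.
#' @param ages Per-sample ages (years), aligned to columns.
#' @return Data frame: signature, spearman_r/p/fdr, pearson_r/p/fdr.
#'   Signatures with constant exposure are reported with NA coefficients
#'   and excluded from the adjustment families.
#' @export
age_correlation <- function(exposures, ages) {
  exposures <- as.matrix(exposures)
  ok <- !is.na(ages)
  if (sum(ok) < 3) stop("need >= 3 samples with non-missing age")
  res <- data.frame(signature = rownames(exposures),
                    spearman_r = NA_real_, spearman_p = NA_real_,
                    pearson_r = NA_real_, pearson_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(exposures))) {
    e <- exposures[i, ok]
    if (stats::sd(e) == 0 || stats::sd(ages[ok]) == 0) next
    sp <- suppressWarnings(stats::cor.test(e, ages[ok], method = "spearman",
                                           exact = FALSE))
    pe <- stats::cor.test(e, ages[ok], method = "pearson")
    res$spearman_r[i] <- unname(sp$estimate); res$spearman_p[i] <- sp$p.value
    res$pearson_r[i] <- unname(pe$estimate); res$pearson_p[i] <- pe$p.value
  }
  res$spearman_fdr <- NA_real_; res$pearson_fdr <- NA_real_
  tested <- !is.na(res$spearman_p)
  res$spearman_fdr[tested] <- benjamini_hochberg(res$spearman_p[tested])
  tested <- !is.na(res$pearson_p)
  res$pearson_fdr[tested] <- benjamini_hochberg(res$pearson_p[tested])
  res
}

#' Covariate association of signature activity
#'
#' Per eligible signature, ordinary least squares of exposure on a binary
#' status, cancer-type indicator contrasts and age
#' (\code{exposure ~ status + cancer_type + age}); the status coefficient
#' and p-value are extracted and adjusted (Benjamini-Hochberg) across the
#' tested signatures. A signature is eligible when present (exposure > 0)
#' in at least \code{min_tumors} tumors and \code{min_types} cancer types.
#' Significance requires a positive status coefficient and adjusted
#' p < \code{alpha}.
#'
#' @param exposures Signatures x samples matrix.
#' @param covariates Data frame aligned to the sample columns, with
#'   \code{status} (binary), \code{cancer_type}, \code{age}.
#' @param min_tumors,min_types Eligibility thresholds (defaults 5 and 3).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return Data frame: signature, coefficient, p, fdr, n_tumors, n_types,
#'   eligible, rank_deficient, significant.
#' @export
covariate_association <- function(exposures, covariates, min_tumors = 5L,
                                  min_types = 3L, alpha = 0.05) {
  exposures <- as.matrix(exposures)
  stopifnot(ncol(exposures) == nrow(covariates))
  res <- data.frame(signature = rownames(exposures),
                    coefficient = NA_real_, p = NA_real_, fdr = NA_real_,
                    n_tumors = 0L, n_types = 0L, eligible = FALSE,
                    rank_deficient = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(exposures))) {
    e <- exposures[i, ]
    present <- e > 0
    res$n_tumors[i] <- sum(present)
    res$n_types[i] <- length(unique(covariates$cancer_type[present]))
    res$eligible[i] <- res$n_tumors[i] >= min_tumors && res$n_types[i] >= min_types
    if (!res$eligible[i]) next
    dat <- data.frame(exposure = e, status = covariates$status,
                      cancer_type = factor(covariates$cancer_type),
                      age = covariates$age)
    fit <- stats::lm(exposure ~ status + cancer_type + age, data = dat)
    cf <- summary(fit)$coefficients
    if (!"status" %in% rownames(cf) || is.na(stats::coef(fit)["status"])) {
      res$rank_deficient[i] <- TRUE
      next
    }
    res$coefficient[i] <- cf["status", "Estimate"]
    res$p[i] <- cf["status", "Pr(>|t|)"]
  }
  tested <- res$eligible & !res$rank_deficient & !is.na(res$p)
  res$fdr[tested] <- benjamini_hochberg(res$p[tested])
  res$significant <- tested & res$coefficient > 0 & res$fdr < alpha
  res$significant[is.na(res$significant)] <- FALSE
  res
}

#' Genomic-instability correlation of signature activity
#'
#' Correlates each signature's exposure with the per-tumor structural
#' variant count; an association is significant when p < 0.05 and the
#' correlation exceeds 0.2.
#'
#' @param exposures Signatures x samples matrix.
#' @param sv_counts Non-negative per-sample structural-variant totals.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return Data frame: signature, r, p, significant.
#' @export
instability_correlation <- function(exposures, sv_counts,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  exposures <- as.matrix(exposures)
  if (any(sv_counts < 0)) stop("sv_counts must be non-negative")
  res <- data.frame(signature = rownames(exposures), r = NA_real_,
                    p = NA_real_, significant = FALSE, stringsAsFactors = FALSE)
  if (stats::sd(sv_counts) == 0) return(res)
  for (i in seq_len(nrow(exposures))) {
    e <- exposures[i, ]
    if (stats::sd(e) == 0) next
    ct <- suppressWarnings(stats::cor.test(e, sv_counts, method = method,
                                           exact = FALSE))
    res$r[i] <- unname(ct$estimate); res$p[i] <- ct$p.value
  }
  res$significant <- !is.na(res$p) & res$p < 0.05 & res$r > 0.2
  res
}

#' Strand asymmetry test against a resampling null
#'
#' For every (signature, substitution class) cell, observed strand-label
#' counts are compared with pooled counts from \code{n_sim} simulations in
#' which each mutation's strand label is redrawn from the genome-wide
#' availability of labels for its substitution class (two-sided Fisher
#' exact test, Benjamini-Hochberg adjustment across cells).
#'
#' @param variants Data frame with a strand column and \code{ref},
#'   \code{alt} (SBS rows are used).
#' @param signature_assignment Character vector, one signature label per
#'   variant row (e.g. maximum-posterior attribution).
#' @param n_sim Number of simulations (default 100).
#' @param seed Integer seed.
#' @param strand_col Column holding the labels (default
#'   \code{"strand_class"}; use \code{"replication_class"} with labels
#'   \code{c("lagging","leading")} for replicative asymmetry).
#' @param labels The two strand labels tested (observed ratio is
#'   first/second).
#' @param availability Null probability of the first label: a single value
#'   (default 0.5, both strands equally available genome-wide), a named
#'   vector per substitution class (e.g. computed from an annotation
#'   track), or \code{"pooled"} to estimate it from the label frequencies
#'   of all supplied mutations per class.
#' @param alpha FDR level for the asymmetric flag.
#' @return Data frame: signature, class, n1, n2 (observed counts), ratio,
#'   sim_ratio, p, fdr, asymmetric.
#' @export
strand_asymmetry_test <- function(variants, signature_assignment, n_sim = 100L,
                                  seed = 1L, strand_col = "strand_class",
                                  labels = c("transcribed", "untranscribed"),
                                  availability = 0.5, alpha = 0.05) {
  stopifnot(strand_col %in% names(variants))
  strand <- variants[[strand_col]]
  keep <- variants$kind == "SBS" & strand %in% labels
  if (!any(keep)) {
    return(data.frame(signature = character(0), class = character(0),
                      n1 = integer(0), n2 = integer(0), ratio = numeric(0),
                      sim_ratio = numeric(0), p = numeric(0), fdr = numeric(0),
                      asymmetric = logical(0)))
  }
  v <- variants[keep, , drop = FALSE]
  strand <- strand[keep]
  sig <- signature_assignment[keep]
  cls <- sbs_class(v$ref, v$alt)
  p1 <- if (identical(availability, "pooled")) {
    # context-conditional availability estimated from all supplied mutations
    avail <- tapply(strand == labels[1], cls, mean)
    avail[cls]
  } else if (length(availability) > 1 || !is.null(names(availability))) {
    if (!all(cls %in% names(availability)))
      stop("availability lacks classes: ",
           paste(setdiff(unique(cls), names(availability)), collapse = ", "))
    availability[cls]
  } else rep(availability, length(cls))
  groups <- split(seq_along(sig), paste(sig, cls, sep = "\r"))
  sims <- with_seed(derive_seed(seed, 7L), {
    lapply(seq_len(n_sim), function(s) stats::runif(length(sig)) < p1)
  })
  out <- lapply(names(groups), function(gk) {
    idx <- groups[[gk]]
    parts <- strsplit(gk, "\r", fixed = TRUE)[[1]]
    n1 <- sum(strand[idx] == labels[1]); n2 <- length(idx) - n1
    s1 <- sum(vapply(sims, function(b) sum(b[idx]), 0))
    s2 <- length(idx) * n_sim - s1
    p <- fisher_exact_2x2(matrix(c(n1, n2, s1, s2), 2))
    data.frame(signature = parts[1], class = parts[2], n1 = n1, n2 = n2,
               ratio = if (n2 > 0) n1 / n2 else Inf,
               sim_ratio = if (s2 > 0) s1 / s2 else Inf,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$fdr <- benjamini_hochberg(res$p)
  res$asymmetric <- res$fdr < alpha
  rownames(res) <- NULL
  res
}

# pyrimidine-centric substitution class of an SBS ("C>T" etc.)
sbs_class <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, complement_base(ref), ref)
  a <- ifelse(pur, complement_base(alt), alt)
  paste0(r, ">", a)
}

#' Microhomology-deletion proportions of an ID83 profile
#'
#' @param id_counts Named ID83 count vector (or one catalog column).
#' @return List: \code{mh_fraction} (deletions in Del:M channels / all
#'   deletions), \code{long_mh_fraction} (5+ bp Del:M deletions / all
#'   deletions). NA when there are no deletions.
#' @export
mh_deletion_proportion <- function(id_counts) {
  id_counts <- drop(as.matrix(id_counts))
  labs <- names(id_counts)
  if (is.null(labs)) stop("id_counts must be named with ID83 labels")
  del <- grepl(":Del:", labs)
  mh <- grepl(":Del:M:", labs)
  long_mh <- grepl("^5:Del:M:", labs)
  tot <- sum(id_counts[del])
  if (tot == 0) return(list(mh_fraction = NA_real_, long_mh_fraction = NA_real_))
  list(mh_fraction = sum(id_counts[mh]) / tot,
       long_mh_fraction = sum(id_counts[long_mh]) / tot)
}

#' Long nonrepeat-insertion (IDN-like) feature counts of an ID83 profile
#'
#' Counts insertions of length >= 2 at nonrepeat sites (adjacent repeat
#' count 0; \code{max_repeat = 1} widens "nonrepeat" to <= 1 copy), the
#' subset of length 5+ insertions, and their fractions of all insertions.
#'
#' @param id_counts Named ID83 count vector.
#' @param max_repeat Maximum adjacent repeat count still called nonrepeat
#'   (default 0).
#' @return List: \code{idn_count}, \code{long_count}, \code{idn_fraction},
#'   \code{long_fraction}.
#' @export
idn_features <- function(id_counts, max_repeat = 0L) {
  id_counts <- drop(as.matrix(id_counts))
  labs <- names(id_counts)
  if (is.null(labs)) stop("id_counts must be named with ID83 labels")
  ins <- grepl(":Ins:", labs)
  rep_n <- suppressWarnings(as.integer(sub("^.*:", "", labs)))
  len_class <- suppressWarnings(as.integer(sub(":.*$", "", labs)))
  idn <- ins & grepl(":Ins:R:", labs) & len_class >= 2 & rep_n <= max_repeat
  long <- idn & len_class == 5
  tot_ins <- sum(id_counts[ins])
  list(idn_count = sum(id_counts[idn]),
       long_count = sum(id_counts[long]),
       idn_fraction = if (tot_ins > 0) sum(id_counts[idn]) / tot_ins else NA_real_,
       long_fraction = if (tot_ins > 0) sum(id_counts[long]) / tot_ins else NA_real_)
}

#' Co-occurrence of SBS and ID signature activities
#'
#' Spearman correlation for every (SBS, ID) signature pair over the shared
#' samples, Benjamini-Hochberg adjusted across all pairs.
#'
#' @param sbs_exposures,id_exposures Signatures x samples matrices with
#'   sample names; at least 3 shared samples required.
#' @return Data frame: sbs, id, r, p, fdr.
#' @export
exposure_cooccurrence <- function(sbs_exposures, id_exposures) {
  sbs_exposures <- as.matrix(sbs_exposures)
  id_exposures <- as.matrix(id_exposures)
  shared <- intersect(colnames(sbs_exposures), colnames(id_exposures))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  res <- expand.grid(sbs = rownames(sbs_exposures), id = rownames(id_exposures),
                     stringsAsFactors = FALSE)
  res$r <- NA_real_; res$p <- NA_real_
  for (i in seq_len(nrow(res))) {
    x <- sbs_exposures[res$sbs[i], shared]
    y <- id_exposures[res$id[i], shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    res$r[i] <- unname(ct$estimate); res$p[i] <- ct$p.value
  }
  tested <- !is.na(res$p)
  res$fdr <- NA_real_
  res$fdr[tested] <- benjamini_hochberg(res$p[tested])
  res
}

#' Maximum-posterior signature assignment of individual mutations
#'
#' Given a sample's fitted exposures and the reference signatures, each
#' mutation in channel c of sample s is assigned the signature g maximizing
#' \code{S[c,g] * E[g,s]}.
#'
#' @param channels Channel label per mutation.
#' @param samples Sample id per mutation.
#' @param signatures Channels x signatures matrix.
#' @param exposures Signatures x samples matrix.
#' @return Character vector of signature labels (NA where the channel has
#'   zero posterior mass).
#' @export
assign_mutations <- function(channels, samples, signatures, exposures) {
  signatures <- as.matrix(signatures); exposures <- as.matrix(exposures)
  out <- rep(NA_character_, length(channels))
  for (i in seq_along(channels)) {
    c_i <- channels[i]; s_i <- samples[i]
    if (is.na(c_i) || !c_i %in% rownames(signatures) ||
        !s_i %in% colnames(exposures)) next
    post <- signatures[c_i, ] * exposures[, s_i]
    if (all(post == 0)) next
    out[i] <- colnames(signatures)[which.max(post)]
  }
  out
}
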