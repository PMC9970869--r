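#' Generate a random reference sequence
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc_fraction Target GC content in (0, 1).
#' @param seed Integer seed; the same (length, gc_fraction, seed) always
#'   yields the same sequence.
#' @return Single character string over A,C,G,T.
#' @export
make_reference_sequence <- function(length, gc_fraction = 0.41, seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                        collapse = ""))
}

# Realize one channel label as a local sequence patch plus the variant that,
# placed on that patch, classifies back to the label. Returns list(patch,
# rel_pos [anchor offset within patch], ref, alt, strand_class).
realize_channel <- function(label) {
  other <- function(excl) setdiff(BASES, excl)[1]
  if (grepl("\\[", label)) {                      # SBS96/SBS288/SBS1536
    strand <- NULL
    if (grepl("^[TUN]:", label)) {
      strand <- switch(substr(label, 1, 1), T = "transcribed",
                       U = "untranscribed", N = "nontranscribed")
      label <- substr(label, 3, nchar(label))
    }
    m <- regmatches(label, regexec("^([ACGT]+)\\[([ACGT])>([ACGT])\\]([ACGT]+)$",
                                   label))[[1]]
    if (!length(m)) stop("invalid SBS channel label: ", label)
    f5 <- m[2]; ref <- m[3]; alt <- m[4]; f3 <- m[5]
    return(list(patch = paste0(f5, ref, f3), rel_pos = nchar(f5) + 1L,
                ref = ref, alt = alt, strand_class = strand))
  }
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4) stop("invalid ID83 channel label: ", label)
  size <- as.integer(parts[1]); ty <- parts[2]; cls <- parts[3]
  n <- as.integer(parts[4])
  if (cls %in% c("C", "T")) {                     # 1-bp events
    b <- cls
    x <- other(b); y <- other(c(b, x))            # run breakers
    if (ty == "Del") {
      run <- strrep(b, n + 1L)
      patch <- paste0(x, run, y)
      return(list(patch = patch, rel_pos = 1L, ref = paste0(x, b), alt = x,
                  strand_class = NULL))
    }
    run <- strrep(b, n)
    patch <- paste0(x, run, y)
    anchor_rel <- 1L + n                          # insert 3' of existing run
    anchor <- if (n > 0) b else x
    return(list(patch = patch, rel_pos = anchor_rel, ref = anchor,
                alt = paste0(anchor, b), strand_class = NULL))
  }
  units <- c(`2` = "AC", `3` = "ACG", `4` = "ACGT", `5` = "ACGTC")
  if (cls == "M") {
    # deletion with microhomology n, zero full copies remaining
    D <- if (size < 5) units[[as.character(size)]] else "ACGTCG"
    L <- nchar(D)
    if (n > mh_cap(size) || n > L - 1) stop("unsatisfiable MH for ", label)
    pref <- substr(D, 1L, n)
    x <- other(substr(D, L, L))                   # kills suffix homology
    ybad <- c(substr(D, n + 1L, n + 1L), substr(D, 1L, 1L))
    y <- other(ybad)                              # stops prefix match at n
    patch <- paste0(x, D, pref, y)
    return(list(patch = patch, rel_pos = 1L, ref = paste0(x, D), alt = x,
                strand_class = NULL))
  }
  U <- units[[as.character(size)]]
  L <- nchar(U)
  x <- other(substr(U, L, L)); y <- other(c(substr(U, 1L, 1L), x))
  if (ty == "Del") {
    patch <- paste0(x, strrep(U, n + 1L), y)
    return(list(patch = patch, rel_pos = 1L, ref = paste0(x, U), alt = x,
                strand_class = NULL))
  }
  patch <- paste0(x, strrep(U, n), y)
  anchor_rel <- 1L + n * L
  anchor <- substr(patch, anchor_rel, anchor_rel)
  list(patch = patch, rel_pos = anchor_rel, ref = anchor,
       alt = paste0(anchor, U), strand_class = NULL)
}

#' Plant variants with known channel labels into a sequence
#'
#' For every requested channel the generator writes the sequence context the
#' channel requires (homopolymer runs, tandem repeat copies, microhomology
#' flanks) into a copy of the input sequence and emits the corresponding
#' variant. Planted sites are spaced so that context edits cannot interact.
#' Classifying the emitted variants against the returned (edited) sequence
#' reproduces the requested labels exactly.
#'
#' @param sequence Reference sequence (single contig string).
#' @param spec Named integer vector or list of (channel label = count).
#' @param seed Integer seed (placement order shuffling).
#' @param chrom Contig name used in the emitted variants.
#' @param sample Sample id assigned to the variants.
#' @param spacing Minimum unedited bases between planted patches (>= 20).
#' @return List with \code{variants} (a \code{variant_set}),
#'   \code{labels} (truth channel per variant, in variant order) and
#'   \code{sequence} (named character vector holding the edited contig).
#' @export
plant_variants <- function(sequence, spec, seed = 1L, chrom = "synth1",
                           sample = "S1", spacing = 40L) {
  spacing <- max(20L, as.integer(spacing))
  counts <- unlist(spec)
  labels <- rep(names(counts), times = counts)
  if (!length(labels)) stop("empty plant specification")
  real <- lapply(unique(labels), realize_channel)
  names(real) <- unique(labels)
  labels <- with_seed(seed, sample(labels))
  patch_len <- vapply(real, function(r) nchar(r$patch), 1L)
  slot <- max(patch_len) + spacing
  first <- 61L  # clear of the contig edge so indel scan windows fit
  need <- first + length(labels) * slot + 61L
  if (nchar(sequence) < need)
    stop("sequence too short to host ", length(labels), " planted variants (need ",
         need, " bases)")
  chars <- strsplit(sequence, "")[[1]]
  rows <- vector("list", length(labels))
  strand <- character(length(labels))
  for (i in seq_along(labels)) {
    r <- real[[labels[i]]]
    at <- first + (i - 1L) * slot            # patch start (1-based)
    chars[at:(at + nchar(r$patch) - 1L)] <- strsplit(r$patch, "")[[1]]
    rows[[i]] <- data.frame(chrom = chrom, pos = at + r$rel_pos - 1L,
                            ref = r$ref, alt = r$alt, sample = sample,
                            stringsAsFactors = FALSE)
    strand[i] <- r$strand_class %||% NA_character_
  }
  df <- do.call(rbind, rows)
  df$strand_class <- strand
  ord <- order(df$chrom, df$pos, df$ref, df$alt, df$sample)
  out_seq <- stats::setNames(paste(chars, collapse = ""), chrom)
  list(variants = variant_set(df), labels = labels[ord], sequence = out_seq)
}

#' Generate synthetic mutational signatures
#'
#' Sparse random probability profiles drawn from a gamma prior and
#' normalized, with rejection sampling enforcing a maximum pairwise cosine
#' similarity so the signatures are well separated.
#'
#' @param n_signatures Number of signatures.
#' @param scheme Channel scheme.
#' @param seed Integer seed.
#' @param max_cosine Maximum allowed pairwise cosine (default 0.6).
#' @param shape Gamma shape controlling sparsity (smaller = sparser).
#' @return Channels x signatures probability matrix (columns sum to 1).
#' @export
synthetic_signatures <- function(n_signatures, scheme = "SBS96", seed = 1L,
                                 max_cosine = 0.6, shape = 0.1) {
  labs <- scheme_labels(scheme)
  with_seed(seed, {
    S <- matrix(0, length(labs), 0)
    tries <- 0L
    while (ncol(S) < n_signatures) {
      v <- stats::rgamma(length(labs), shape = shape) + 1e-12
      v <- v / sum(v)
      ok <- !ncol(S) ||
        all(apply(S, 2, function(u) cosine_similarity(u, v)) <= max_cosine)
      if (ok) S <- cbind(S, v)
      tries <- tries + 1L
      if (tries > 1000L * n_signatures)
        stop("could not satisfy max_cosine = ", max_cosine)
    }
    dimnames(S) <- list(labs, paste0("SigT", seq_len(n_signatures)))
    S
  })
}

#' Simulate a ground-truth catalog cohort
#'
#' Draws per-sample exposures from a sparse log-normal burden model (or
#' uses the supplied exposure matrix) and samples catalog counts
#' independently as Poisson with mean \code{(S A)[c,s]}, the count model
#' under which KL-divergence NMF is the maximum-likelihood estimator.
#' Each signature is active in a given sample with probability
#' \code{presence} (active exposures log-normal, absent ones zero),
#' mirroring real cohorts in which most signatures are found in only a
#' fraction of tumors; exposure vectors touching the orthant boundary are
#' also what makes the factorization identifiable.
#'
#' @param signatures Channels x signatures probability matrix (columns sum
#'   to 1 within 1e-9).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param exposures Optional signatures x samples exposure matrix; when
#'   given, \code{exposure_model} is ignored.
#' @param exposure_model List with \code{mean} (per-signature mean active
#'   exposure, recycled), \code{sdlog} (log-normal spread, default 1) and
#'   \code{presence} (per-signature activity probability, default 0.6).
#' @return \code{truth_cohort} list: \code{signatures}, \code{exposures},
#'   \code{catalog}, \code{covariates} (NULL until
#'   \code{simulate_covariates()}), \code{seed}.
#' @export
simulate_catalog_cohort <- function(signatures, n_samples, seed = 1L,
                                    exposures = NULL,
                                    exposure_model = list(mean = 1000, sdlog = 1,
                                                          presence = 0.6)) {
  cs <- colSums(signatures)
  if (any(abs(cs - 1) > 1e-9)) stop("signature columns must sum to 1")
  g <- ncol(signatures)
  if (is.null(exposures)) {
    mu <- rep_len(exposure_model$mean %||% 1000, g)
    sdlog <- exposure_model$sdlog %||% 1
    presence <- rep_len(exposure_model$presence %||% 0.6, g)
    exposures <- with_seed(derive_seed(seed, 1L), {
      e <- matrix(stats::rlnorm(g * n_samples, meanlog = log(mu) - sdlog^2 / 2,
                                sdlog = sdlog),
                  nrow = g, ncol = n_samples)
      on <- matrix(stats::runif(g * n_samples) < presence, g, n_samples)
      # keep every signature represented so the truth rank is as requested
      for (i in seq_len(g)) if (!any(on[i, ])) on[i, sample.int(n_samples, 1)] <- TRUE
      e * on
    })
  } else {
    exposures <- as.matrix(exposures)
    if (nrow(exposures) != g || ncol(exposures) != n_samples)
      stop("exposures must be signatures x samples")
  }
  if (any(exposures < 0)) stop("exposure model produced negative exposures")
  rownames(exposures) <- colnames(signatures)
  colnames(exposures) <- sprintf("Sample%03d", seq_len(n_samples))
  lambda <- signatures %*% exposures
  counts <- with_seed(derive_seed(seed, 2L), {
    matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda),
           dimnames = dimnames(lambda))
  })
  structure(list(signatures = signatures, exposures = exposures,
                 catalog = structure(counts, scheme = attr_scheme(signatures),
                                     class = c("mutation_catalog", class(counts))),
                 covariates = NULL, seed = seed),
            class = "truth_cohort")
}

attr_scheme <- function(signatures) {
  n <- nrow(signatures)
  switch(as.character(n), `96` = "SBS96", `288` = "SBS288",
         `1536` = "SBS1536", `83` = "ID83", `1619` = "COMPOSITE", "custom")
}

#' @export
print.truth_cohort <- function(x, ...) {
  cat(sprintf("truth_cohort: %d signatures, %d samples, %d channels (seed %d)\n",
              ncol(x$signatures), ncol(x$exposures), nrow(x$catalog), x$seed))
  invisible(x)
}

#' Attach simulated covariates to a truth cohort
#'
#' Ages are drawn proportional to the summed truth exposure of the
#' clock-like signatures plus Gaussian noise; a binary status flag
#' multiplies the exposure of a chosen signature by a stated factor in
#' flagged samples (the catalog is re-drawn from the updated means); the
#' structural-variant count is generated with a configurable Spearman
#' correlation to a chosen signature via a Gaussian copula.
#'
#' @param cohort \code{truth_cohort}.
#' @param clock_signatures Signature labels driving age.
#' @param effect_spec Optional list \code{(signature, multiplier)}; a
#'   multiplier of 1 plants no effect.
#' @param sv_spec Optional list \code{(signature, rho, lambda)} for the SV
#'   count copula (default rho 0, lambda 50).
#' @param n_types Number of cancer-type levels.
#' @param age_noise_sd Age noise standard deviation in years.
#' @param age_max Oldest age the clock maps to (years).
#' @param seed Integer seed.
#' @return Updated \code{truth_cohort} with \code{covariates} filled and,
#'   when an effect was planted, exposures and catalog updated.
#' @export
simulate_covariates <- function(cohort, clock_signatures = NULL,
                                effect_spec = NULL, sv_spec = NULL,
                                n_types = 4L, age_noise_sd = 1,
                                age_max = 18, seed = 1L) {
  A <- cohort$exposures
  sigs <- rownames(A)
  for (lab in c(clock_signatures, effect_spec$signature, sv_spec$signature))
    if (!is.null(lab) && !lab %in% sigs) stop("unknown signature label: ", lab)
  n <- ncol(A)
  with_seed(derive_seed(seed, 3L), {
    status <- stats::rbinom(n, 1L, 0.5)
    cancer_type <- paste0("CT", sample.int(n_types, n, replace = TRUE))
    if (!is.null(effect_spec) && effect_spec$multiplier != 1) {
      A[effect_spec$signature, status == 1L] <-
        A[effect_spec$signature, status == 1L] * effect_spec$multiplier
    }
    clock <- if (is.null(clock_signatures)) colSums(A) else
      colSums(A[clock_signatures, , drop = FALSE])
    age <- clock / max(clock) * age_max + stats::rnorm(n, 0, age_noise_sd)
    age <- pmax(age, 0)
    if (is.null(sv_spec)) {
      sv_count <- stats::rpois(n, 50)
    } else {
      rho <- sv_spec$rho %||% 0.5
      z <- rank(A[sv_spec$signature, ], ties.method = "average")
      z <- stats::qnorm(z / (n + 1))
      latent <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
      sv_count <- stats::qpois(stats::pnorm(latent), sv_spec$lambda %||% 50)
    }
    cohort$covariates <- data.frame(sample = colnames(A), age = age,
                                    status = status, cancer_type = cancer_type,
                                    sv_count = sv_count,
                                    stringsAsFactors = FALSE)
  })
  if (!is.null(effect_spec) && effect_spec$multiplier != 1) {
    cohort$exposures <- A
    lambda <- cohort$signatures %*% A
    cohort$catalog <- with_seed(derive_seed(seed, 4L), {
      structure(matrix(stats::rpois(length(lambda), lambda),
                       nrow = nrow(lambda), dimnames = dimnames(lambda)),
                scheme = attr(cohort$catalog, "scheme"),
                class = class(cohort$catalog))
    })
  }
  cohort
}

#' Write a truth cohort to disk as plain-text tables
#' @param cohort \code{truth_cohort}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_catalog(cohort$catalog, file.path(dir, "catalog.tsv"))
  write_catalog(cohort$signatures, file.path(dir, "truth_signatures.tsv"))
  ex <- data.frame(Signature = rownames(cohort$exposures), cohort$exposures,
                   check.names = FALSE)
  utils::write.table(ex, file.path(dir, "truth_exposures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$covariates))
    utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a sequence store as FASTA
#' @param sequences Named character vector of contig sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (nm in names(sequences)) {
      writeLines(paste0(">", nm), con)
      s <- sequences[[nm]]
      starts <- seq(1L, nchar(s), by = 70L)
      writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a FASTA file into the internal sequence-store form
#' @param path FASTA path.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  stopifnot(length(hdr) > 0)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), "")
  names(out) <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  toupper(out)
}
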