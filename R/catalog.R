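#' Classify a single base substitution into its context channel
#'
#' Labels are pyrimidine-centric: when the reference base is a purine the
#' substitution and its flanks are reverse-complemented, so e.g. G>A with 5'
#' C and 3' T becomes \code{A[C>T]G}. \code{SBS96} uses one flanking base on
#' each side, \code{SBS1536} two; \code{SBS288} prefixes the SBS96 label
#' with the transcriptional strand class (\code{T:}, \code{U:} or
#' \code{N:} for transcribed / untranscribed / nontranscribed).
#'
#' @param ref,alt Single reference/alternate bases.
#' @param flank5,flank3 Flanking sequence 5' and 3' of the mutated base (1
#'   base for SBS96/SBS288, 2 for SBS1536), on the reference strand.
#' @param scheme \code{"SBS96"}, \code{"SBS288"} or \code{"SBS1536"}.
#' @param strand_class For SBS288: \code{"transcribed"},
#'   \code{"untranscribed"} or \code{"nontranscribed"}.
#' @return Channel label, or \code{NA} if a flank contains N.
#' @export
classify_sbs <- function(ref, alt, flank5, flank3,
                         scheme = c("SBS96", "SBS288", "SBS1536"),
                         strand_class = NULL) {
  scheme <- match.arg(scheme)
  k <- if (scheme == "SBS1536") 2L else 1L
  if (nchar(flank5) != k || nchar(flank3) != k)
    stop("expected ", k, "-base flanks for ", scheme)
  if (grepl("N", paste0(flank5, ref, alt, flank3))) return(NA_character_)
  if (ref %in% c("G", "A")) {
    new5 <- revcomp(flank3); new3 <- revcomp(flank5)
    ref <- complement_base(ref); alt <- complement_base(alt)
    flank5 <- new5; flank3 <- new3
  }
  lab <- paste0(flank5, "[", ref, ">", alt, "]", flank3)
  if (scheme == "SBS288") {
    code <- switch(strand_class %||% "nontranscribed",
                   transcribed = "T:", untranscribed = "U:",
                   nontranscribed = "N:",
                   stop("unknown strand_class: ", strand_class))
    lab <- paste0(code, lab)
  }
  lab
}

# run length of `base` scanning right from position p (inclusive)
run_right <- function(seq, p, base) {
  n <- 0L
  while (p <= nchar(seq) && substr(seq, p, p) == base) { n <- n + 1L; p <- p + 1L }
  n
}

run_left <- function(seq, p, base) {
  n <- 0L
  while (p >= 1L && substr(seq, p, p) == base) { n <- n + 1L; p <- p - 1L }
  n
}

# number of consecutive full copies of `unit` starting at p going right
copies_right <- function(seq, p, unit) {
  L <- nchar(unit); n <- 0L
  while (p + L - 1L <= nchar(seq) && substr(seq, p, p + L - 1L) == unit) {
    n <- n + 1L; p <- p + L
  }
  n
}

copies_left <- function(seq, p, unit) {
  L <- nchar(unit); n <- 0L
  while (p - L + 1L >= 1L && substr(seq, p - L + 1L, p) == unit) {
    n <- n + 1L; p <- p - L
  }
  n
}

# length of the longest prefix of `x` equal to the sequence starting at p
prefix_match <- function(seq, p, x, maxlen) {
  n <- 0L
  while (n < maxlen && p + n <= nchar(seq) &&
         substr(seq, p + n, p + n) == substr(x, n + 1L, n + 1L)) n <- n + 1L
  n
}

# length of the longest suffix of `x` equal to the sequence ending at p
suffix_match <- function(seq, p, x, maxlen) {
  n <- 0L; L <- nchar(x)
  while (n < maxlen && p - n >= 1L &&
         substr(seq, p - n, p - n) == substr(x, L - n, L - n)) n <- n + 1L
  n
}

mh_cap <- function(size) if (size < 5L) size - 1L else 5L

#' Classify an insertion or deletion into its ID83 channel
#'
#' Labels have the form \code{L:Type:Class:N} where \code{L = min(length,5)}
#' (5 meaning "5+"). One-base events are classed by the pyrimidine
#' representation of the affected base (\code{C} or \code{T}) with \code{N}
#' the number of identical bases adjacent in the post-event sequence
#' (deletions: copies remaining; insertions: copies already present), capped
#' at 5. Longer events are classed \code{R} with \code{N} the number of full
#' adjacent tandem copies of the indel sequence, capped at 5. Deletions with
#' zero remaining copies but flanking homology are classed \code{M} with
#' \code{N} the microhomology length: the maximum of the longest proper
#' prefix of the deleted sequence matching the sequence immediately 3' of
#' the deleted span and the longest proper suffix matching the sequence
#' immediately 5' of it, capped per length class (2:1, 3:2, 4:3, 5+:5).
#'
#' @param chrom,pos,ref,alt VCF-style call (anchor base included; the indel
#'   sequence is the inserted/deleted run after stripping the anchor).
#' @param reference Named character vector of contig sequences.
#' @return ID83 channel label, or \code{NA} when the contig window around
#'   the indel is too short to decide the channel (the caller logs these).
#' @export
classify_indel <- function(chrom, pos, ref, alt, reference) {
  kind <- variant_kind(ref, alt)
  if (!kind %in% c("INS", "DEL")) stop("not an indel: ", ref, ">", alt)
  contig <- reference[[chrom]]
  if (is.null(contig) || is.na(contig)) stop("contig '", chrom, "' not in reference")
  seqlen <- nchar(contig)
  if (kind == "DEL") {
    indel <- substr(ref, 2L, nchar(ref))
    L <- nchar(indel)
    left_end <- pos                      # last base before the deleted span
    right_start <- pos + L + 1L          # first base after the deleted span
  } else {
    indel <- substr(alt, 2L, nchar(alt))
    L <- nchar(indel)
    left_end <- pos
    right_start <- pos + 1L
  }
  # need >= 6 indel lengths of context each side to saturate repeat counts
  if (left_end - 6L * L < 0L || right_start + 6L * L - 1L > seqlen)
    return(NA_character_)
  # scan inside a local window: substr on multi-megabase strings is O(n),
  # so slice once and address the window with shifted coordinates
  wstart <- left_end - 6L * L + 1L
  wend <- right_start + 6L * L - 1L
  win <- substr(contig, wstart, wend)
  w_left <- left_end - wstart + 1L
  w_right <- right_start - wstart + 1L
  size <- min(L, 5L)
  if (L == 1L) {
    n <- run_left(win, w_left, indel) + run_right(win, w_right, indel)
    base <- if (indel %in% c("A", "G")) complement_base(indel) else indel
    return(paste0("1:", if (kind == "DEL") "Del" else "Ins", ":", base, ":",
                  min(n, 5L)))
  }
  ncopy <- copies_left(win, w_left, indel) + copies_right(win, w_right, indel)
  ty <- if (kind == "DEL") "Del" else "Ins"
  if (kind == "DEL" && ncopy == 0L) {
    mh <- max(prefix_match(win, w_right, indel, L - 1L),
              suffix_match(win, w_left, indel, L - 1L))
    if (mh >= 1L) return(paste0(size, ":Del:M:", min(mh, mh_cap(size))))
  }
  paste0(size, ":", ty, ":R:", min(ncopy, 5L))
}

classify_variant <- function(chrom, pos, ref, alt, kind, reference, scheme,
                             strand_class = NULL) {
  if (scheme == "ID83") {
    if (!kind %in% c("INS", "DEL")) return(NA_character_)
    return(classify_indel(chrom, pos, ref, alt, reference))
  }
  if (kind != "SBS") return(NA_character_)
  k <- if (scheme == "SBS1536") 2L else 1L
  contig <- reference[[chrom]]
  if (is.null(contig) || is.na(contig)) stop("contig '", chrom, "' not in reference")
  if (pos - k < 1L || pos + k > nchar(contig)) return(NA_character_)
  refbase <- substr(contig, pos, pos)
  if (refbase != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (expected ", ref,
         ", reference has ", refbase, ")")
  f5 <- substr(contig, pos - k, pos - 1L)
  f3 <- substr(contig, pos + 1L, pos + k)
  classify_sbs(ref, alt, f5, f3, scheme, strand_class = strand_class)
}

#' Build a mutation catalog from a variant set
#'
#' Classifies every variant of the matching kind against the reference and
#' tabulates counts per channel and sample. Variants that cannot be
#' classified (wrong kind for the scheme, N in context, contig-edge windows)
#' are skipped and counted per sample in the \code{skipped} attribute.
#'
#' @param variants \code{variant_set}.
#' @param reference Named character vector of contig sequences.
#' @param scheme Channel scheme name.
#' @param samples Optional sample set fixing catalog columns (defaults to
#'   samples present in \code{variants}).
#' @return Integer matrix (channels x samples) of class
#'   \code{mutation_catalog} with a \code{scheme} attribute.
#' @export
build_catalog <- function(variants, reference,
                          scheme = c("SBS96", "SBS288", "SBS1536", "ID83"),
                          samples = NULL) {
  scheme <- match.arg(scheme)
  labs <- scheme_labels(scheme)
  if (is.null(samples)) samples <- sort(unique(variants$sample))
  counts <- matrix(0L, nrow = length(labs), ncol = length(samples),
                   dimnames = list(labs, samples))
  skipped <- stats::setNames(integer(length(samples)), samples)
  strand <- if ("strand_class" %in% names(variants)) variants$strand_class else
    rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    s <- variants$sample[i]
    if (!s %in% samples) next
    sc <- if (is.na(strand[i])) NULL else strand[i]
    lab <- classify_variant(variants$chrom[i], variants$pos[i], variants$ref[i],
                            variants$alt[i], variants$kind[i], reference,
                            scheme, strand_class = sc)
    if (is.na(lab)) skipped[s] <- skipped[s] + 1L
    else counts[lab, s] <- counts[lab, s] + 1L
  }
  structure(counts, scheme = scheme, skipped = skipped,
            class = c("mutation_catalog", class(counts)))
}

#' Mutation burden in mutations per megabase
#'
#' Divides the mutation count by the effective human genome size assessable
#' by whole-genome sequencing (2,800 Mb).
#'
#' @param n_mutations Non-negative mutation count(s).
#' @param genome_mb Effective genome size in megabases (default 2800).
#' @return Mutations per megabase.
#' @export
mutation_burden <- function(n_mutations, genome_mb = 2800) {
  if (any(n_mutations < 0)) stop("mutation counts must be non-negative")
  n_mutations / genome_mb
}

#' Count CC>TT doublet substitutions per sample
#'
#' Counts adjacent SBS pairs (same sample and chromosome, positions p and
#' p+1) whose joint change is CC>TT on either strand, i.e. CC>TT or GG>AA
#' on the reference. Each pair is counted once.
#'
#' @param variants \code{variant_set}.
#' @return Named integer vector, one count per sample.
#' @export
count_cc_tt_doublets <- function(variants) {
  sbs <- variants[variants$kind == "SBS", , drop = FALSE]
  samples <- sort(unique(variants$sample))
  out <- stats::setNames(integer(length(samples)), samples)
  if (!nrow(sbs)) return(out)
  key <- paste(sbs$sample, sbs$chrom, sep = "\r")
  for (grp in split(seq_len(nrow(sbs)), key)) {
    d <- sbs[grp, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    idx <- match(d$pos + 1L, d$pos)
    pair <- which(!is.na(idx))
    for (i in pair) {
      j <- idx[i]
      fwd <- d$ref[i] == "C" && d$alt[i] == "T" && d$ref[j] == "C" && d$alt[j] == "T"
      rev <- d$ref[i] == "G" && d$alt[i] == "A" && d$ref[j] == "G" && d$alt[j] == "A"
      if (fwd || rev) out[d$sample[1]] <- out[d$sample[1]] + 1L
    }
  }
  out
}

#' Read or write a catalog TSV (MutationType column + one column per sample)
#' @param path File path.
#' @return Matrix with channel rownames.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_catalog
#' @param x Matrix with channel rownames.
#' @export
write_catalog <- function(x, path) {
  df <- data.frame(MutationType = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
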