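#' Construct a variant set
#'
#' A variant set is a data frame of somatic calls with one row per variant
#' and columns \code{chrom}, \code{pos} (1-based, position of the first REF
#' base as in VCF), \code{ref}, \code{alt}, \code{sample}, plus a derived
#' \code{kind} column (\code{SBS}, \code{INS}, \code{DEL} or \code{OTHER}).
#' Rows are sorted by (chrom, pos) and exact duplicates (same chrom, pos,
#' ref, alt, sample) are dropped. Optional annotation columns
#' (\code{strand_class}, \code{replication_class}, \code{region_class},
#' \code{mappability}) are preserved.
#'
#' @param df Data frame with at least chrom, pos, ref, alt, sample.
#' @param provenance Optional character tag recording the origin of the set.
#' @return Object of class \code{variant_set}.
#' @export
variant_set <- function(df, provenance = NA_character_) {
  req <- c("chrom", "pos", "ref", "alt", "sample")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$sample <- as.character(df$sample)
  if (nrow(df)) {
    if (any(df$pos < 1)) stop("variant positions must be >= 1")
    bad <- grepl("[^ACGT]", df$ref) | grepl("[^ACGT]", df$alt)
    if (any(bad))
      stop("alleles must be over {A,C,G,T}; offending row ", which(bad)[1])
  }
  df$kind <- variant_kind(df$ref, df$alt)
  key <- paste(df$chrom, df$pos, df$ref, df$alt, df$sample, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$ref, df$alt, df$sample), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("variant_set", "data.frame"), provenance = provenance)
}

variant_kind <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  kind <- rep("OTHER", length(ref))
  kind[nr == 1 & na == 1 & ref != alt] <- "SBS"
  ins <- na > nr & substr(alt, 1, nr) == ref & nr == 1
  del <- nr > na & substr(ref, 1, na) == alt & na == 1
  kind[ins] <- "INS"
  kind[del] <- "DEL"
  kind
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants, %d sample(s), %d contig(s)\n",
              nrow(x), length(unique(x$sample)), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read somatic variants from VCF or TSV
#'
#' Minimal VCF 4.x (CHROM POS ID REF ALT ...) is parsed; the sample id is
#' taken from a \code{SAMPLE=} INFO key, from the first genotype column name,
#' or from the \code{sample} argument. Multi-allelic records are split into
#' biallelic records; records with symbolic ALT alleles (\code{<DEL>} etc.)
#' are skipped and counted. TSV input must carry the variant_set columns.
#'
#' @param path File path.
#' @param format \code{"VCF"} or \code{"TSV"} (default guessed from extension).
#' @param sample Fallback sample id when the file does not name one.
#' @return \code{variant_set}; attribute \code{n_skipped} counts records
#'   dropped for symbolic or non-ACGT alleles.
#' @export
read_variants <- function(path, format = NULL, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "VCF" else "TSV"
  }
  format <- match.arg(format, c("VCF", "TSV"))
  if (format == "TSV") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(variant_set(df, provenance = path))
  }
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  sample_cols <- character(0)
  if (length(hdr)) {
    cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
    if (length(cols) > 9) sample_cols <- cols[-(1:9)]
  }
  if (!length(body)) {
    empty <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                        alt = character(0), sample = character(0))
    return(variant_set(empty, provenance = path))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 5))
    stop("malformed VCF record at line ",
         which(!startsWith(lines, "#") & nzchar(lines))[which(nf < 5)[1]])
  rows <- list(); skipped <- 0L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    info <- if (length(f) >= 8) f[8] else ""
    smp <- sample
    m <- regmatches(info, regexpr("SAMPLE=[^;]+", info))
    if (length(m)) smp <- sub("SAMPLE=", "", m)
    if (is.null(smp) && length(sample_cols)) smp <- sample_cols[1]
    if (is.null(smp)) smp <- tools::file_path_sans_ext(basename(path))
    for (alt in alts) {
      if (grepl("[^ACGTacgt]", alt) || grepl("[^ACGTacgt]", f[4])) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alt,
        sample = smp, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), sample = character(0))
  vs <- variant_set(df, provenance = path)
  attr(vs, "n_skipped") <- skipped
  vs
}

#' Write variants as minimal VCF or TSV
#'
#' @param variants \code{variant_set}.
#' @param path Output path.
#' @param format \code{"VCF"} or \code{"TSV"}.
#' @return \code{path}, invisibly.
#' @export
write_variants <- function(variants, path, format = c("VCF", "TSV")) {
  format <- match.arg(format)
  if (format == "TSV") {
    utils::write.table(as.data.frame(variants), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- if (nrow(variants)) sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tSAMPLE=%s",
                                      variants$chrom, variants$pos, variants$ref,
                                      variants$alt, variants$sample) else character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# Reference footprint of a call: the interval of reference bases the REF
# allele spans ([pos, pos + nchar(ref) - 1]).
variant_footprint <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos,
                              end = variants$pos + nchar(variants$ref) - 1L))
}

#' Consensus intersection of two variant sets
#'
#' Returns the records of \code{set_a} that have at least one overlap in
#' \code{set_b}, each emitted at most once (\code{bedtools intersect -u}
#' semantics). In \code{"positional"} mode overlap means the reference
#' footprints (\code{[pos, pos + nchar(ref) - 1]}) intersect, so SBS calls
#' require an identical position while indel calls match on footprint
#' intervals. \code{"exact"} mode additionally requires identical REF/ALT.
#'
#' @param set_a,set_b \code{variant_set} objects.
#' @param mode \code{"positional"} (default) or \code{"exact"}.
#' @return \code{variant_set} subset of \code{set_a}.
#' @export
consensus_intersect <- function(set_a, set_b, mode = c("positional", "exact")) {
  mode <- match.arg(mode)
  if (!nrow(set_a) || !nrow(set_b))
    return(variant_set(set_a[integer(0), , drop = FALSE]))
  if (mode == "exact") {
    key_a <- paste(set_a$chrom, set_a$pos, set_a$ref, set_a$alt)
    key_b <- paste(set_b$chrom, set_b$pos, set_b$ref, set_b$alt)
    keep <- key_a %in% key_b
  } else {
    hits <- GenomicRanges::findOverlaps(variant_footprint(set_a),
                                        variant_footprint(set_b))
    keep <- seq_len(nrow(set_a)) %in% S4Vectors::queryHits(hits)
  }
  out <- set_a[keep, , drop = FALSE]
  variant_set(out, provenance = attr(set_a, "provenance"))
}

#' Annotate variants with mappability scores
#'
#' @param variants \code{variant_set}.
#' @param track Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{score} (1-based inclusive intervals; use
#'   \code{bedgraph_to_track()} for 0-based half-open bedGraph input).
#' @param sentinel Value assigned to positions not covered by the track.
#' @return \code{variant_set} with a \code{mappability} column; attribute
#'   \code{n_uncovered} counts sentinel assignments.
#' @export
annotate_mappability <- function(variants, track, sentinel = NA_real_) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(track)))
  if (any(track$score < 0 | track$score > 1))
    stop("mappability scores must lie in [0, 1]")
  gr_track <- GenomicRanges::GRanges(track$chrom,
                                     IRanges::IRanges(track$start, track$end))
  self <- GenomicRanges::findOverlaps(gr_track, gr_track)
  self <- self[S4Vectors::queryHits(self) != S4Vectors::subjectHits(self)]
  if (length(self)) {
    qi <- S4Vectors::queryHits(self); si <- S4Vectors::subjectHits(self)
    if (any(track$score[qi] != track$score[si]))
      stop("overlapping track intervals with conflicting scores")
  }
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, variants$pos))
  hit <- GenomicRanges::findOverlaps(gr_var, gr_track, select = "first")
  score <- ifelse(is.na(hit), sentinel, track$score[hit])
  out <- as.data.frame(variants)
  out$mappability <- score
  res <- variant_set(out, provenance = attr(variants, "provenance"))
  attr(res, "n_uncovered") <- sum(is.na(hit))
  res
}

#' Convert a bedGraph-style table to the internal 1-based track convention
#' @param df Data frame with chrom, start, end, score in 0-based half-open
#'   coordinates.
#' @return Data frame with 1-based inclusive start/end.
#' @export
bedgraph_to_track <- function(df) {
  data.frame(chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
             score = df[[4]], stringsAsFactors = FALSE)
}

#' Annotate variants with genomic region class
#'
#' Assigns \code{region_class} by the precedence exon > UTR > intron >
#' intergenic: a position inside an exon interval is \code{"exon"}, else
#' inside a UTR interval \code{"UTR"}, else inside a gene body
#' \code{"intron"}, else \code{"intergenic"}.
#'
#' @param variants \code{variant_set}.
#' @param gene_model Data frame with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive) and \code{type} in \code{{"exon","UTR","gene"}}.
#' @return \code{variant_set} with \code{region_class} filled in.
#' @export
annotate_region <- function(variants, gene_model) {
  stopifnot(all(c("chrom", "start", "end", "type") %in% names(gene_model)))
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, variants$pos))
  cls <- rep("intergenic", nrow(variants))
  for (level in c("gene", "UTR", "exon")) {
    sub <- gene_model[gene_model$type == level, , drop = FALSE]
    if (!nrow(sub)) next
    gr <- GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$start, sub$end))
    inside <- GenomicRanges::countOverlaps(gr_var, gr) > 0
    cls[inside] <- if (level == "gene") "intron" else level
  }
  out <- as.data.frame(variants)
  out$region_class <- cls
  variant_set(out, provenance = attr(variants, "provenance"))
}

#' Load a GFF3 gene model into the interval table annotate_region expects
#'
#' Keeps gene, exon and UTR features (five_prime_UTR/three_prime_UTR are
#' mapped to "UTR").
#'
#' @param path GFF3 file path.
#' @return Data frame with chrom, start, end, type.
#' @export
read_gene_model <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 gene models")
  gr <- rtracklayer::import(path)
  ty <- as.character(gr$type)
  ty[ty %in% c("five_prime_UTR", "three_prime_UTR")] <- "UTR"
  keep <- ty %in% c("gene", "exon", "UTR")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[keep],
             start = GenomicRanges::start(gr)[keep],
             end = GenomicRanges::end(gr)[keep],
             type = ty[keep], stringsAsFactors = FALSE)
}

#' Per-class fraction table of region annotations
#' @param variants \code{variant_set} with \code{region_class}.
#' @return Data frame with columns region_class, n, fraction.
#' @export
region_fraction_table <- function(variants) {
  stopifnot("region_class" %in% names(variants))
  tab <- table(variants$region_class)
  data.frame(region_class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
}
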