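#' Reverse complement of a DNA string
#' @param x Character vector of sequences over A,C,G,T,N.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

# Deterministic child seed: mixes a parent seed with a stream index, keeping
# the result inside the 32-bit signed integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483587L) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Extract sequence context around a 1-based position from a reference store
# (named character vector, one element per contig).
ref_fetch <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference))
    stop("contig '", chrom, "' not present in reference")
  seqlen <- nchar(reference[[chrom]])
  if (start < 1 || end > seqlen) return(NA_character_)
  substr(reference[[chrom]], start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
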