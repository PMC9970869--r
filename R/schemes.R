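#' Channel schemes for mutation catalogs
#'
#' A channel scheme is an ordered set of mutation-type labels. Supported
#' schemes are \code{SBS96} (6 pyrimidine-centric substitution classes x 16
#' trinucleotide contexts), \code{SBS288} (SBS96 x transcriptional strand
#' class T/U/N), \code{SBS1536} (pentanucleotide context), \code{ID83}
#' (indels by length, base, adjacent repeat-unit count and microhomology
#' length) and \code{COMPOSITE} (SBS1536 followed by ID83, 1619 channels).
#'
#' @param name Scheme name, one of \code{"SBS96"}, \code{"SBS288"},
#'   \code{"SBS1536"}, \code{"ID83"}, \code{"COMPOSITE"}.
#' @return Character vector of channel labels in canonical order.
#' @examples
#' length(scheme_labels("SBS96"))  # 96
#' head(scheme_labels("ID83"))
#' @export
scheme_labels <- function(name) {
  name <- match.arg(name, c("SBS96", "SBS288", "SBS1536", "ID83", "COMPOSITE"))
  switch(name,
    SBS96     = sbs96_labels(),
    SBS288    = sbs288_labels(),
    SBS1536   = sbs1536_labels(),
    ID83      = id83_labels(),
    COMPOSITE = c(sbs1536_labels(), id83_labels())
  )
}

BASES <- c("A", "C", "G", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

sbs96_labels <- function() {
  out <- character(0)
  for (cls in SBS_CLASSES) {
    ref <- substr(cls, 1, 1)
    for (f5 in BASES) for (f3 in BASES) {
      out <- c(out, paste0(f5, "[", cls, "]", f3))
    }
  }
  out
}

sbs288_labels <- function() {
  base <- sbs96_labels()
  c(paste0("T:", base), paste0("U:", base), paste0("N:", base))
}

sbs1536_labels <- function() {
  pairs <- as.vector(t(outer(BASES, BASES, paste0)))
  out <- character(0)
  for (cls in SBS_CLASSES) {
    for (f5 in pairs) for (f3 in pairs) {
      out <- c(out, paste0(f5, "[", cls, "]", f3))
    }
  }
  out
}

id83_labels <- function() {
  lab <- character(0)
  # 1-bp deletions/insertions by pyrimidine base and homopolymer length
  for (ty in c("Del", "Ins")) for (b in c("C", "T")) {
    lab <- c(lab, paste0("1:", ty, ":", b, ":", 0:5))
  }
  # >1-bp deletions then insertions at repeat units
  for (ty in c("Del", "Ins")) for (L in 2:5) {
    lab <- c(lab, paste0(L, ":", ty, ":R:", 0:5))
  }
  # microhomology deletions: length-2 MH 1; length-3 MH 1-2; length-4 MH 1-3;
  # length-5+ MH 1-5
  for (L in 2:5) {
    cap <- if (L < 5) L - 1 else 5
    lab <- c(lab, paste0(L, ":Del:M:", seq_len(cap)))
  }
  lab
}

#' Number of channels in a scheme
#' @param name Scheme name.
#' @return Integer channel count.
#' @export
scheme_size <- function(name) length(scheme_labels(name))

#' Collapse a catalog or signature matrix between channel schemes
#'
#' Supported collapses: SBS288 to SBS96 (sum over strand classes), SBS1536 to
#' SBS96 (sum over outer flanking bases), and slicing COMPOSITE into its
#' SBS1536 or ID83 block. Mass is conserved; if the input columns were
#' probability-normalized the result is renormalized to column sum one.
#'
#' @param x Numeric matrix with channel labels as rownames.
#' @param from Scheme of \code{x}.
#' @param to Target scheme.
#' @return Matrix under the target scheme.
#' @export
collapse_channels <- function(x, from, to) {
  stopifnot(is.matrix(x))
  from <- match.arg(from, c("SBS288", "SBS1536", "COMPOSITE"))
  labs_from <- scheme_labels(from)
  if (!identical(rownames(x), labs_from)) {
    if (is.null(rownames(x)) || !all(labs_from %in% rownames(x)))
      stop("rownames of 'x' do not match scheme ", from)
    x <- x[labs_from, , drop = FALSE]
  }
  normalized <- all(abs(colSums(x) - 1) < 1e-6) && !all(x == 0)
  if (from == "COMPOSITE") {
    if (!to %in% c("SBS1536", "ID83")) stop("COMPOSITE collapses to SBS1536 or ID83")
    out <- x[scheme_labels(to), , drop = FALSE]
  } else if (from == "SBS288" && to == "SBS96") {
    key <- substr(rownames(x), 3, nchar(rownames(x)))
    out <- rowsum(x, group = key, reorder = FALSE)
    out <- out[sbs96_labels(), , drop = FALSE]
  } else if (from == "SBS1536" && to == "SBS96") {
    # AB[C>A]CD -> B[C>A]C : drop the outermost base on each side
    key <- paste0(substr(rownames(x), 2, 2), substr(rownames(x), 3, 7),
                  substr(rownames(x), 8, 8))
    out <- rowsum(x, group = key, reorder = FALSE)
    out <- out[sbs96_labels(), , drop = FALSE]
  } else {
    stop("unsupported scheme pair: ", from, " -> ", to)
  }
  if (normalized) {
    cs <- colSums(out)
    cs[cs == 0] <- 1
    out <- sweep(out, 2, cs, "/")
  }
  out
}
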