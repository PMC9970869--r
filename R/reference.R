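#' Synthetic reference signature catalog
#'
#' A deterministic, fully synthetic stand-in for a COSMIC-v3-style reference
#' catalog, for testing and simulation. Profiles are built from fixed-seed
#' gamma draws with channel-block emphases that echo the qualitative shape
#' of the eponymous processes (e.g. the SBS1-like signature concentrates on
#' N[C>T]G channels, the ID6-like signature on long microhomology
#' deletions), but the numeric values are NOT COSMIC estimates. Columns sum
#' to 1. Real COSMIC catalogs in the standard tab-separated format
#' (MutationType column plus one column per signature) can be loaded with
#' \code{\link{read_catalog}} and used anywhere this catalog is.
#'
#' @param scheme \code{"SBS96"} or \code{"ID83"}.
#' @return Channels x signatures probability matrix.
#' @export
synthetic_reference_catalog <- function(scheme = c("SBS96", "ID83")) {
  scheme <- match.arg(scheme)
  labs <- scheme_labels(scheme)
  profile <- function(idx, shape, boosts) {
    with_seed(990000L + idx, {
      v <- stats::rgamma(length(labs), shape = shape) + 1e-9
      for (b in boosts) v[grepl(b$pattern, labs)] <-
          v[grepl(b$pattern, labs)] * b$factor
      v / sum(v)
    })
  }
  if (scheme == "SBS96") {
    spec <- list(
      SBS1  = list(shape = 0.05, boosts = list(list(pattern = "\\[C>T\\]G", factor = 400))),
      SBS3  = list(shape = 0.7,  boosts = list(list(pattern = "\\[C>G\\]", factor = 5),
                                               list(pattern = "\\[C>A\\]", factor = 3))),
      SBS5  = list(shape = 1.2,  boosts = list(list(pattern = "\\[T>C\\]", factor = 3))),
      SBS7a = list(shape = 0.08, boosts = list(list(pattern = "^[CT]\\[C>T\\]", factor = 150))),
      SBS8  = list(shape = 0.4,  boosts = list(list(pattern = "\\[C>A\\]", factor = 8))),
      SBS13 = list(shape = 0.08, boosts = list(list(pattern = "^T\\[C>G\\]", factor = 200))),
      SBS18 = list(shape = 0.3,  boosts = list(list(pattern = "\\[C>A\\][AT]$", factor = 12))),
      SBS40 = list(shape = 2.5,  boosts = list())
    )
  } else {
    spec <- list(
      ID1 = list(shape = 0.05, boosts = list(list(pattern = "^1:Ins:T:[45]", factor = 400))),
      ID2 = list(shape = 0.05, boosts = list(list(pattern = "^1:Del:T:[45]", factor = 400))),
      ID5 = list(shape = 0.3,  boosts = list(list(pattern = "^1:Del:T:", factor = 10))),
      ID6 = list(shape = 0.08, boosts = list(list(pattern = "^5:Del:M:", factor = 120),
                                             list(pattern = "^[34]:Del:M:", factor = 30))),
      ID8 = list(shape = 0.15, boosts = list(list(pattern = "^5:Del:R:[01]", factor = 80),
                                             list(pattern = "^[34]:Del:R:0", factor = 20))),
      ID9 = list(shape = 0.3,  boosts = list(list(pattern = "^[25]:Del:R:", factor = 8)))
    )
  }
  S <- vapply(seq_along(spec), function(i)
    profile(i + 100L * (scheme == "ID83"), spec[[i]]$shape, spec[[i]]$boosts),
    numeric(length(labs)))
  dimnames(S) <- list(labs, names(spec))
  S
}
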