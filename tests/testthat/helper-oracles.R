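# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package:
# everything works on character vectors with explicit loops, or by
# exhaustive enumeration.

# ---- indel channel oracle (character-vector scanning) ----------------------

oracle_classify_indel <- function(contig, pos, ref, alt) {
  # contig may be supplied pre-split (character vector) to amortize strsplit
  ch <- if (length(contig) > 1L) contig else strsplit(contig, "")[[1]]
  is_del <- nchar(ref) > nchar(alt)
  dseq <- if (is_del) strsplit(substring(ref, 2), "")[[1]] else
    strsplit(substring(alt, 2), "")[[1]]
  L <- length(dseq)
  left_end <- pos
  right_start <- if (is_del) pos + L + 1L else pos + 1L
  size <- min(L, 5L)
  slice_eq <- function(a, b, x) {
    if (a < 1 || b > length(ch)) return(FALSE)
    all(ch[a:b] == x)
  }
  if (L == 1L) {
    n <- 0L
    p <- left_end
    while (p >= 1 && ch[p] == dseq) { n <- n + 1L; p <- p - 1L }
    p <- right_start
    while (p <= length(ch) && ch[p] == dseq) { n <- n + 1L; p <- p + 1L }
    b <- if (dseq %in% c("A", "G")) c(A = "T", G = "C")[[dseq]] else dseq
    return(paste0("1:", if (is_del) "Del" else "Ins", ":", b, ":", min(n, 5L)))
  }
  n <- 0L
  j <- 0L
  while (slice_eq(right_start + j * L, right_start + (j + 1L) * L - 1L, dseq)) {
    n <- n + 1L; j <- j + 1L
  }
  j <- 0L
  while (slice_eq(left_end - (j + 1L) * L + 1L, left_end - j * L, dseq)) {
    n <- n + 1L; j <- j + 1L
  }
  ty <- if (is_del) "Del" else "Ins"
  if (is_del && n == 0L) {
    mh <- 0L
    for (m in seq_len(L - 1L)) {  # prefix of deleted seq vs right flank
      if (slice_eq(right_start, right_start + m - 1L, dseq[1:m])) mh <- max(mh, m)
    }
    for (m in seq_len(L - 1L)) {  # suffix vs left flank
      if (slice_eq(left_end - m + 1L, left_end, dseq[(L - m + 1L):L]))
        mh <- max(mh, m)
    }
    if (mh >= 1L) {
      cap <- if (size < 5L) size - 1L else 5L
      return(paste0(size, ":Del:M:", min(mh, cap)))
    }
  }
  paste0(size, ":", ty, ":R:", min(n, 5L))
}

# ---- SBS channel oracle (complement tables, no shared helpers) -------------

oracle_classify_sbs96 <- function(f5, ref, alt, f3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("G", "A")) {
    tmp <- comp[[f3]]
    f3 <- comp[[f5]]; f5 <- tmp
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  paste0(f5, "[", ref, ">", alt, "]", f3)
}

# ---- statistics oracles ----------------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

oracle_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# projected-gradient NNLS for small instances
oracle_nnls <- function(A, b, iters = 200000L) {
  A <- as.matrix(A)
  x <- rep(0, ncol(A))
  t <- 1 / (2 * max(eigen(crossprod(A), only.values = TRUE)$values))
  for (i in seq_len(iters)) {
    x <- pmax(0, x - t * as.numeric(crossprod(A, A %*% x - b)))
  }
  x
}

# ---- shared small fixtures -------------------------------------------------

make_test_reference <- function(n = 50000L, seed = 42L, gc = 0.42) {
  make_reference_sequence(n, gc_fraction = gc, seed = seed)
}

cosine_of <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
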