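test_that("reference sequences honor length, composition and determinism", {
  s <- make_reference_sequence(10, 0.5, seed = 1)
  expect_equal(nchar(s), 10)
  expect_true(grepl("^[ACGT]+$", s))
  big <- make_reference_sequence(1e6, 0.4, seed = 7)
  gc <- sum(strsplit(big, "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.4), 0.01)             # binomial concentration
  expect_identical(make_reference_sequence(1000, 0.3, seed = 9),
                   make_reference_sequence(1000, 0.3, seed = 9))
  expect_error(make_reference_sequence(0, 0.5), "length")
  expect_error(make_reference_sequence(10, 1.2), "gc_fraction")
})

test_that("planted SBS variants carry the requested context", {
  seqc <- make_test_reference(20000L)
  pl <- plant_variants(seqc, c("A[C>T]G" = 5L), seed = 3)
  v <- pl$variants
  expect_equal(nrow(v), 5)
  expect_true(all(v$ref == "C" & v$alt == "T"))
  ctx <- substr(rep(pl$sequence[["synth1"]], 5), v$pos - 1, v$pos + 1)
  expect_true(all(ctx == "ACG"))
})

test_that("planted microhomology deletions verify under brute-force scan", {
  seqc <- make_test_reference(30000L)
  pl <- plant_variants(seqc, c("5:Del:M:2" = 3L), seed = 5)
  v <- pl$variants
  expect_true(all(nchar(v$ref) - 1 >= 5))
  contig <- pl$sequence[["synth1"]]
  for (i in 1:3) {
    expect_identical(oracle_classify_indel(contig, v$pos[i], v$ref[i], v$alt[i]),
                     "5:Del:M:2")
  }
})

test_that("planted single-T insertions sit next to zero T bases", {
  seqc <- make_test_reference(20000L)
  pl <- plant_variants(seqc, c("1:Ins:T:0" = 2L), seed = 6)
  v <- pl$variants
  contig <- pl$sequence[["synth1"]]
  for (i in 1:2) {
    expect_false(substr(contig, v$pos[i] + 1, v$pos[i] + 1) == "T")
    expect_identical(oracle_classify_indel(contig, v$pos[i], v$ref[i], v$alt[i]),
                     "1:Ins:T:0")
  }
})

test_that("unsatisfiable plantings fail loudly", {
  expect_error(plant_variants(strrep("A", 100), c("A[C>T]G" = 5L)),
               "too short")
})

test_that("cohort catalogs are Poisson around the signature mixture", {
  s <- matrix(rep(1 / 96, 96), dimnames = list(scheme_labels("SBS96"), "sig1"))
  sums <- vapply(1:200, function(seed) {
    co <- simulate_catalog_cohort(s, n_samples = 1, seed = seed,
                                  exposures = matrix(1000))
    sum(co$catalog)
  }, 0)
  # mean of 200 Poisson(1000) draws: se = sqrt(1000/200) ~ 2.24, allow 5 sigma
  expect_lt(abs(mean(sums) - 1000), 5 * sqrt(1000 / 200))
  expect_gt(stats::var(sums), 0)
})

test_that("zero exposures give all-zero catalogs and seeds reproduce bit-exactly", {
  s <- synthetic_signatures(2, seed = 1)
  co0 <- simulate_catalog_cohort(s, 3, seed = 5, exposures = matrix(0, 2, 3))
  expect_true(all(co0$catalog == 0))
  a <- simulate_catalog_cohort(s, 4, seed = 11)
  b <- simulate_catalog_cohort(s, 4, seed = 11)
  expect_identical(unclass(a$catalog), unclass(b$catalog))
  expect_identical(a$exposures, b$exposures)
})

test_that("catalog means converge to S A over many seeds", {
  s <- synthetic_signatures(2, seed = 3)
  E <- matrix(c(400, 800), 2, 1)
  lambda <- s %*% E
  acc <- matrix(0, 96, 1)
  for (seed in 1:150) {
    acc <- acc + simulate_catalog_cohort(s, 1, seed = seed, exposures = E)$catalog
  }
  avg <- acc / 150
  # per-channel z-scores against Poisson standard errors
  se <- sqrt(pmax(lambda, 1e-9) / 150)
  expect_lt(max(abs(avg - lambda) / pmax(se, 0.05)), 6)
})

test_that("negative exposures are rejected", {
  s <- synthetic_signatures(2, seed = 1)
  expect_error(simulate_catalog_cohort(s, 2, exposures = matrix(-1, 2, 2)),
               "negative")
})

test_that("clock covariates track truth exposure and effects multiply means", {
  s <- synthetic_signatures(3, seed = 2)
  co <- simulate_catalog_cohort(s, 200, seed = 9,
                                exposure_model = list(mean = 500, sdlog = 0.5,
                                                      presence = 1))
  # noise-free clock: age is a monotone map of clock exposure
  co1 <- simulate_covariates(co, clock_signatures = "SigT1", age_noise_sd = 0,
                             seed = 1)
  rho <- stats::cor(co1$covariates$age, co1$exposures["SigT1", ],
                    method = "spearman")
  expect_equal(rho, 1)
  # multiplier 3 on SigT2 for status=1: mean exposure ratio near 3
  co2 <- simulate_covariates(co, effect_spec = list(signature = "SigT2",
                                                    multiplier = 3), seed = 2)
  st <- co2$covariates$status
  ratio <- mean(co2$exposures["SigT2", st == 1]) /
    mean(co2$exposures["SigT2", st == 0])
  expect_lt(abs(ratio - 3) / 3, 0.35)        # sample-mean check at n = 200
  # multiplier 1 plants nothing
  co3 <- simulate_covariates(co, effect_spec = list(signature = "SigT2",
                                                    multiplier = 1), seed = 3)
  expect_identical(co3$exposures, co$exposures)
  expect_error(simulate_covariates(co, clock_signatures = "nope"), "unknown")
})

test_that("sv counts correlate with the chosen signature at the planted strength", {
  s <- synthetic_signatures(3, seed = 2)
  co <- simulate_catalog_cohort(s, 300, seed = 10,
                                exposure_model = list(presence = 1))
  co <- simulate_covariates(co, sv_spec = list(signature = "SigT3", rho = 0.7),
                            seed = 4)
  r <- stats::cor(co$covariates$sv_count, co$exposures["SigT3", ],
                  method = "spearman")
  expect_gt(r, 0.5)
})

test_that("cohorts write as plain-text tables", {
  s <- synthetic_signatures(2, seed = 1)
  co <- simulate_catalog_cohort(s, 3, seed = 1)
  d <- tempfile()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "catalog.tsv")))
  back <- read_catalog(file.path(d, "catalog.tsv"))
  expect_equal(dim(back), dim(co$catalog))
  expect_true(all(back == unclass(co$catalog)))
})

test_that("fasta round-trips through the sequence store", {
  seqs <- c(chrA = "ACGTACGTAA", chrB = strrep("ACGT", 40))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back[order(names(back))], seqs[order(names(seqs))])
})
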