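test_that("BH adjustment matches the closed form and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher exact matches enumeration on all small tables", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)  # zero margin
  set.seed(2)
  for (i in 1:60) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Wilcoxon matches exact enumeration on small tie-free samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(3)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000L, nx + ny)       # distinct values: no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon(x, y),
                 tolerance = 1e-9)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("age correlation handles exact, monotone and constant exposures", {
  ages <- c(1, 3, 5, 9, 14, 17)
  E <- rbind(linear = 2 * ages, cubic = ages^3, flat = rep(4, 6))
  res <- age_correlation(E, ages)
  expect_equal(res$spearman_r[res$signature == "linear"], 1)
  expect_equal(res$pearson_r[res$signature == "linear"], 1)
  expect_equal(res$spearman_r[res$signature == "cubic"], 1)
  expect_lt(res$pearson_r[res$signature == "cubic"], 1)
  expect_true(is.na(res$spearman_r[res$signature == "flat"]))
  expect_error(age_correlation(E[, 1:2, drop = FALSE], ages[1:2]), ">= 3")
})

test_that("age correlation controls type-I error under the null", {
  set.seed(4)
  n <- 60
  E <- matrix(rlnorm(200 * n), 200, n,
              dimnames = list(paste0("s", 1:200), NULL))
  ages <- runif(n, 1, 18)
  res <- age_correlation(E, ages)
  fp <- mean(res$spearman_fdr < 0.05)
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("covariate association applies the eligibility rule", {
  set.seed(5)
  n <- 40
  cov <- data.frame(sample = paste0("t", 1:n),
                    age = runif(n, 1, 18),
                    status = rbinom(n, 1, 0.5),
                    cancer_type = sample(paste0("CT", 1:4), n, TRUE))
  E <- matrix(rlnorm(2 * n), 2, n, dimnames = list(c("common", "rare"), NULL))
  E["rare", -(1:4)] <- 0                     # present in only 4 tumors
  res <- covariate_association(E, cov)
  expect_false(res$eligible[res$signature == "rare"])
  expect_true(res$eligible[res$signature == "common"])
  expect_true(is.na(res$p[res$signature == "rare"]))
})

test_that("planted status effects are detected with positive coefficients", {
  S <- synthetic_signatures(4, seed = 61)
  detected <- vapply(1:10, function(run) {
    co <- simulate_catalog_cohort(S, 200, seed = 100 + run,
                                  exposure_model = list(mean = 600, sdlog = 0.5,
                                                        presence = 1))
    co <- simulate_covariates(co, effect_spec = list(signature = "SigT2",
                                                     multiplier = 3),
                              seed = 200 + run)
    res <- covariate_association(co$exposures, co$covariates)
    res$significant[res$signature == "SigT2"]
  }, TRUE)
  expect_gte(mean(detected), 0.9)
})

test_that("covariate association is calibrated under the null", {
  S <- synthetic_signatures(8, seed = 62)
  fps <- unlist(lapply(1:10, function(run) {
    co <- simulate_catalog_cohort(S, 120, seed = 300 + run,
                                  exposure_model = list(presence = 1))
    co <- simulate_covariates(co, seed = 400 + run)   # no planted effect
    res <- covariate_association(co$exposures, co$covariates)
    res$significant[res$eligible]
  }))
  expect_lte(mean(fps), 0.05 + 3 * sqrt(0.05 * 0.95 / length(fps)))
})

test_that("instability correlation follows the joint p and r rule", {
  sv <- c(1, 4, 9, 16, 25, 36, 49, 64)
  E <- rbind(exact = sv, flat = rep(2, 8))
  res <- instability_correlation(E, sv)
  expect_equal(res$r[res$signature == "exact"], 1)
  expect_true(res$significant[res$signature == "exact"])
  expect_false(res$significant[res$signature == "flat"])
  # strong p but weak r is not significant
  set.seed(6)
  n <- 2000
  x <- rnorm(n)
  y <- 0.15 * x + rnorm(n)
  E2 <- rbind(weak = y - min(y))
  res2 <- instability_correlation(E2, rank(x), method = "pearson")
  expect_lt(res2$p[1], 0.05)
  expect_false(res2$significant[1])
})

test_that("strand asymmetry flags planted bias and controls the null", {
  mk_variants <- function(n, p_trans, seed) {
    set.seed(seed)
    data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
               ref = sample(c("C", "T"), n, TRUE), alt = "A",
               sample = "s", kind = "SBS",
               strand_class = ifelse(runif(n) < p_trans, "transcribed",
                                     "untranscribed"))
  }
  # all mutations of one signature on one strand
  v <- mk_variants(60, 1, 7)
  res <- strand_asymmetry_test(v, rep("SBS5", 60), n_sim = 100, seed = 1)
  expect_true(all(res$asymmetric))
  # planted 2:1 excess
  v2 <- mk_variants(600, 2 / 3, 8)
  sig2 <- rep(c("SBSa", "SBSb"), each = 300)
  res2 <- strand_asymmetry_test(v2, sig2, n_sim = 100, seed = 2)
  expect_gt(mean(res2$asymmetric), 0)
  # symmetric null across many signature cells
  v3 <- mk_variants(5000, 0.5, 9)
  sig3 <- sample(paste0("S", 1:25), 5000, TRUE)
  res3 <- strand_asymmetry_test(v3, sig3, n_sim = 100, seed = 3)
  expect_lte(mean(res3$asymmetric), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res3)))
  # no labelled mutations: empty result
  v4 <- mk_variants(10, 0.5, 10); v4$strand_class <- "nontranscribed"
  expect_equal(nrow(strand_asymmetry_test(v4, rep("x", 10))), 0)
})

test_that("MH-deletion proportions are exact channel arithmetic", {
  id <- stats::setNames(numeric(83), scheme_labels("ID83"))
  id["5:Del:M:2"] <- 70
  expect_equal(mh_deletion_proportion(id)$mh_fraction, 1)
  id2 <- id; id2["5:Del:M:2"] <- 30; id2["1:Del:C:2"] <- 70
  expect_equal(mh_deletion_proportion(id2)$mh_fraction, 0.30)
  expect_equal(mh_deletion_proportion(id2)$long_mh_fraction, 0.30)
  id3 <- stats::setNames(numeric(83), scheme_labels("ID83"))
  id3["2:Del:R:1"] <- 10
  expect_equal(mh_deletion_proportion(id3)$mh_fraction, 0)
  id4 <- stats::setNames(numeric(83), scheme_labels("ID83"))
  expect_true(is.na(mh_deletion_proportion(id4)$mh_fraction))
})

test_that("IDN features count long nonrepeat insertions", {
  id <- stats::setNames(numeric(83), scheme_labels("ID83"))
  id["5:Ins:R:0"] <- 10
  id["1:Ins:T:3"] <- 5
  f <- idn_features(id)
  expect_equal(f$idn_count, 10)
  expect_equal(f$long_count, 10)
  expect_equal(f$idn_fraction, 10 / 15)
  id2 <- stats::setNames(numeric(83), scheme_labels("ID83"))
  id2["3:Ins:R:2"] <- 8                       # repeat insertions only
  expect_equal(idn_features(id2)$idn_count, 0)
  expect_equal(idn_features(id2, max_repeat = 2)$idn_count, 8)
})

test_that("indel feature summaries are invariant to variant order", {
  seqc <- make_test_reference(60000L, seed = 13)
  spec <- c("5:Ins:R:0" = 4L, "2:Ins:R:0" = 3L, "1:Ins:T:2" = 5L,
            "3:Del:M:1" = 2L, "1:Del:C:0" = 6L)
  pl <- plant_variants(seqc, spec, seed = 14)
  cat_id <- build_catalog(pl$variants, pl$sequence, "ID83")
  f <- idn_features(cat_id[, 1])
  expect_equal(f$idn_count, 7)
  expect_equal(f$long_count, 4)
  expect_equal(mh_deletion_proportion(cat_id[, 1])$mh_fraction, 2 / 8)
})

test_that("exposure co-occurrence finds the planted shared factor", {
  set.seed(11)
  n <- 80
  latent <- rlnorm(n)
  sbs <- rbind(SBS1 = latent * 100 + rlnorm(n), SBSx = rlnorm(n, 3))
  id <- rbind(ID1 = latent * 40 + rlnorm(n), IDy = rlnorm(n, 2))
  colnames(sbs) <- colnames(id) <- paste0("t", 1:n)
  res <- exposure_cooccurrence(sbs, id)
  top <- res[which.max(res$r), ]
  expect_equal(paste(top$sbs, top$id), "SBS1 ID1")
  expect_lt(top$fdr, 0.05)
  # identical exposures give r = 1
  res2 <- exposure_cooccurrence(sbs, sbs)
  expect_equal(res2$r[res2$sbs == "SBS1" & res2$id == "SBS1"], 1)
  expect_error(exposure_cooccurrence(sbs, id[, 1:2]), ">= 3")
})

test_that("maximum-posterior assignment picks the dominant signature", {
  S <- cbind(a = c(0.9, 0.1), b = c(0.1, 0.9))
  rownames(S) <- c("ch1", "ch2")
  E <- cbind(s1 = c(100, 1), s2 = c(1, 100))
  rownames(E) <- c("a", "b")
  out <- assign_mutations(c("ch1", "ch2", "ch2"), c("s1", "s1", "s2"), S, E)
  # s1's exposure outweighs the ch2 channel lean; s2 flips it
  expect_equal(out, c("a", "a", "b"))
})
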