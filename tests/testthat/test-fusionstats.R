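test_that("diploid-genome arithmetic follows the 6 pg convention", {
  expect_equal(genomes_from_mass(0.006), 1)            # 6 pg -> 1 genome
  expect_equal(genomes_from_mass(192 * 12.5), 400000)  # pooled replicates
  expect_equal(genomes_from_mass(50), 8333.333, tolerance = 1e-6)
  expect_error(genomes_from_mass(0), "positive")
})

test_that("fusion frequency is a simple, scale-invariant quotient", {
  expect_equal(fusion_frequency(0, 1000)$frequency, 0)
  f <- fusion_frequency(3, genomes_from_mass(50))
  expect_equal(f$frequency, 3.6e-4, tolerance = 1e-3)
  expect_equal(expected_event_count(2.13e-3, 400000), 852)
  # scale invariance
  f1 <- fusion_frequency(7, 12345)$frequency
  f2 <- fusion_frequency(7 * 13, 12345 * 13)$frequency
  expect_equal(f1, f2)
  expect_error(fusion_frequency(-1, 10), "negative")
  expect_error(fusion_frequency(1, 0), "positive")
})

test_that("inter:intra ratios behave at the edges", {
  expect_equal(inter_intra_ratio(100, 50), 2)
  expect_equal(inter_intra_ratio(50, 50), 1)
  expect_warning(r <- inter_intra_ratio(10, 0), "undefined")
  expect_true(is.na(r))
})

test_that("a library with twice the inter molecules doubles the read ratio", {
  rs <- recovery_refset(30, seed = 61)
  # matched amplicon lengths so read counts scale with molecule counts
  cfg <- sim_config(seed = 17, n_inter = 20, n_intra = 10, coverage = 20,
                    inter_length_range = c(3200, 4300))
  lib <- simulate_fusion_library(rs, cfg)
  reads <- generate_reads(lib, cfg)
  res <- run_fusion_pipeline(reads, rs, resolve = FALSE)
  ratio <- res$summary$inter_intra_read_ratio
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})

test_that("binned profiles conserve counts and classify chromatids", {
  bp <- bin_profile(c(50, 150, 151), bin_width = 100)
  expect_identical(bp$counts, c(1L, 2L))
  # permutation invariance and conservation
  set.seed(62)
  pos <- sample(1:3300, 500, replace = TRUE)
  p1 <- bin_profile(pos, 100, ref_length = 3337)
  p2 <- bin_profile(sample(pos), 100, ref_length = 3337)
  expect_identical(p1$counts, p2$counts)
  expect_identical(sum(p1$counts), 500L)
  expect_error(bin_profile(c(10, 4000), 100, ref_length = 3337), "range")

  rs <- small_refset(seed = 63)
  ref <- rs$subtelomeres[[1]]
  expect_identical(classify_chromatid(500, ref), "short")
  expect_identical(classify_chromatid(2500, ref), "long")
  expect_identical(classify_chromatid(1500, ref), "intermediate")
})

test_that("gene-overlap chi-square matches its closed form and stats::chisq.test", {
  genes <- data.frame(ref = "g", start = c(1001, 5001), end = c(2000, 6000))
  # all junctions inside genes
  jc <- data.frame(ref = "g", pos = seq(1010, 1990, length.out = 50))
  tst <- gene_overlap_test(jc, genes, expected_fraction = 0.418)
  n <- 50; e <- 0.418
  # with every junction in-gene the 1-df Pearson statistic reduces to
  # n (1 - e) / e
  closed <- n * (1 - e) / e
  expect_equal(tst$statistic, closed, tolerance = 1e-12)
  ref_t <- stats::chisq.test(c(50, 0), p = c(e, 1 - e), correct = FALSE)
  expect_lt(abs(tst$statistic - unname(ref_t$statistic)), 1e-8)
  expect_lt(abs(tst$p_value - ref_t$p.value), 1e-8)
  # observed exactly at expectation: statistic 0, p 1
  jc2 <- data.frame(ref = "g", pos = c(1001:1418, 9001:9582))
  tst2 <- gene_overlap_test(jc2, genes, expected_fraction = 0.418)
  expect_equal(tst2$statistic, 0, tolerance = 1e-12)
  expect_equal(tst2$p_value, 1)
  expect_equal(tst2$groups$observed_fraction, 0.418)
  expect_error(gene_overlap_test(jc, genes[0, ]), "empty")
})

test_that("feature proximity permutation test behaves at saturation and planting", {
  ref_len <- c(chrA = 50000)
  # features tiling the whole reference: fold 1, p near 1
  tiles <- data.frame(ref = "chrA", start = seq(1, 49901, by = 100),
                      end = seq(100, 50000, by = 100))
  set.seed(68)
  jx <- data.frame(ref = "chrA", pos = sample(1000:49000, 30))
  sat <- feature_proximity_test(jx, tiles, ref_len, window = 100,
                                n_random = 200, seed = 5)
  expect_equal(sat$groups$fold_change, 1)
  expect_gte(sat$p_value, 0.99)
  # junctions planted exactly on sparse features
  sparse <- data.frame(ref = "chrA", start = c(5000, 20000, 40000),
                       end = c(5010, 20010, 40010))
  planted <- data.frame(ref = "chrA", pos = c(5005, 20005, 40005,
                                              5001, 20001, 40001))
  hot <- feature_proximity_test(planted, sparse, ref_len, window = 100,
                                n_random = 200, seed = 5)
  expect_equal(hot$p_value, 1 / 201)
  expect_gt(hot$groups$fold_change, 10)
  # determinism under a fixed seed; p bounded by the permutation count
  hot2 <- feature_proximity_test(planted, sparse, ref_len, window = 100,
                                 n_random = 200, seed = 5)
  expect_identical(hot$p_value, hot2$p_value)
  expect_gte(hot$p_value, 1 / 201)
  expect_lte(sat$p_value, 1)
})

test_that("junction-proximal GC content matches a direct character count", {
  refs <- c(a = strrep("GC", 2000), b = strrep("AT", 2000))
  j <- list(ref_a = "a", bp_a = 1000L, ref_b = "a", bp_b = 2000L)
  expect_equal(gc_content_window(j, refs), 1)
  j2 <- list(ref_a = "b", bp_a = 1000L, ref_b = "b", bp_b = 2000L)
  expect_equal(gc_content_window(j2, refs), 0)
  refs2 <- c(m = strrep("ATGC", 2000))
  j3 <- list(ref_a = "m", bp_a = 2000L, ref_b = "m", bp_b = 4000L)
  # inclusive +/-500 windows hold 1001 bases, so the repeating 4-mer is 0.5
  # only to within one base per window
  expect_equal(gc_content_window(j3, refs2), 0.5, tolerance = 1e-3)
  # counting oracle on random junctions
  set.seed(64)
  rnd <- paste(sample(c("A", "C", "G", "T"), 9000, replace = TRUE),
               collapse = "")
  refs3 <- c(r = rnd)
  for (i in 1:20) {
    ba <- sample(600:8400, 1); bb <- sample(600:8400, 1)
    jj <- list(ref_a = "r", bp_a = ba, ref_b = "r", bp_b = bb)
    win <- paste0(substr(rnd, ba - 500, ba + 500),
                  substr(rnd, bb - 500, bb + 500))
    chars <- strsplit(win, "")[[1]]
    expect_equal(gc_content_window(jj, refs3),
                 sum(chars %in% c("G", "C")) / length(chars))
  }
})

test_that("the Welch t computation reproduces stats::t.test to 1e-12", {
  set.seed(65)
  x <- rnorm(23, 1, 2); y <- rnorm(31, 0.4, 0.7)
  mine <- welch_t(x, y, tails = "two")
  ref <- stats::t.test(x, y, var.equal = FALSE)
  expect_lt(abs(mine$statistic - unname(ref$statistic)), 1e-12)
  expect_lt(abs(mine$p_value - ref$p.value), 1e-12)
  expect_lt(abs(mine$groups$df - unname(ref$parameter)), 1e-10)
  one <- welch_t(x, y, tails = "one", alternative = "greater")
  ref1 <- stats::t.test(x, y, var.equal = FALSE, alternative = "greater")
  expect_lt(abs(one$p_value - ref1$p.value), 1e-12)
  # two-tailed p = 2 * min(one-tailed p, 1 - one-tailed p)
  expect_equal(mine$p_value, 2 * min(one$p_value, 1 - one$p_value),
               tolerance = 1e-12)
  # identical groups: t = 0, two-tailed p = 1
  z <- c(1, 2, 3, 4)
  same <- welch_t(z, z, tails = "two")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("strand-specific error rates are detected by the rate comparison", {
  # read-level plumbing: a small library with elevated centromeric error
  rs <- small_refset(seed = 66)
  cfg <- sim_config(seed = 18, n_inter = 0, n_intra = 6, coverage = 30,
                    error_rate_leading = 0.002, error_rate_lagging = 0.02)
  lib <- simulate_fusion_library(rs, cfg)
  reads <- generate_reads(lib, cfg)
  aln <- align_reads(reads, rs)
  ref <- rs$subtelomeres[[1]]
  # segregate by mapped position: short (centromeric) vs long (telomeric)
  side <- classify_chromatid((aln$pos + aln$end) / 2, ref)
  short_rates <- per_molecule_mismatch(aln[side == "short", ])
  long_rates <- per_molecule_mismatch(aln[side == "long", ])
  expect_gt(mean(short_rates$rate), mean(long_rates$rate))
  tst <- mismatch_rate_compare(short_rates, long_rates, tails = "one")
  expect_lt(tst$p_value, 0.05)

  # identical groups: t = 0, two-tailed p = 1
  same <- mismatch_rate_compare(c(.01, .02, .03), c(.01, .02, .03),
                                tails = "two")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # power at the designed effect size (4x rate), 100 molecules per group:
  # per-molecule rates are binomial draws over the aligned bases
  set.seed(67)
  hits <- vapply(1:100, function(r) {
    shr <- rbinom(100, 5000, 0.008) / 5000
    lng <- rbinom(100, 5000, 0.002) / 5000
    mismatch_rate_compare(shr, lng, tails = "one")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
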