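test_that("a fixed seed reproduces amplicons, truth and FASTQ byte-for-byte", {
  rs <- small_refset(seed = 21)
  cfg <- sim_config(seed = 7, n_inter = 3, n_intra = 3, coverage = 10)
  lib1 <- simulate_fusion_library(rs, cfg)
  lib2 <- simulate_fusion_library(rs, cfg)
  expect_identical(lib1, lib2)
  f1a <- tempfile(); f1b <- tempfile(); f2a <- tempfile(); f2b <- tempfile()
  generate_reads(lib1, cfg, f1a, f1b)
  generate_reads(lib2, cfg, f2a, f2b)
  expect_identical(unname(tools::md5sum(f1a)), unname(tools::md5sum(f2a)))
  expect_identical(unname(tools::md5sum(f1b)), unname(tools::md5sum(f2b)))
})

test_that("a fold-back at the cut site has zero resection on both chromatids", {
  rs <- small_refset(seed = 22)
  cut <- rs$subtelomeres[[1]]$cut_site
  cfg <- sim_config(seed = 1)
  sim <- simulate_intra_fusion(rs, cfg, breakpoints = c(cut, cut))
  S <- rs$subtelomeres[[1]]$sequence
  h <- junction_homology(S, cut, "+", S, cut, "-")
  # the recorded truth is the left-aligned placement of the same junction
  expect_identical(sim$truth$bp_a, cut - h$k_left)
  expect_identical(sim$truth$bp_b, cut + h$k_left)
  expect_identical(sim$truth$resection_a + sim$truth$resection_b, 0L)
  expect_identical(nchar(sim$amplicon), 2L * cut)
})

test_that("requested microhomology is realized as shared junction sequence", {
  rs <- small_refset(seed = 23)
  cfg <- sim_config(seed = 5, p_insertion = 0,
                    microhomology_prob = c("3" = 1))
  sim <- simulate_intra_fusion(rs, cfg)
  tr <- sim$truth
  expect_identical(tr$microhomology, 3L)
  S <- rs$subtelomeres[[1]]$sequence
  # string oracle on the emitted amplicon: the 3 nt after bp_a on the fused
  # strand equal the 3 nt the short chromatid provides past the junction
  fl <- intra_flanks(S, tr$bp_a, tr$bp_b)
  expect_identical(count_breakpoint_placements(fl$junction, fl$flank_a,
                                               fl$flank_b), 4L)
  revcomp <- function(x) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
  expect_identical(substr(S, tr$bp_a + 1, tr$bp_a + 3),
                   revcomp(substr(S, tr$bp_b - 2, tr$bp_b)))
})

test_that("intra draws pair a short (<1 kb) with a long (>2 kb) chromatid", {
  rs <- small_refset(seed = 24)
  cfg <- sim_config(seed = 9)
  set.seed(cfg$seed)
  ref <- rs$subtelomeres[[1]]
  draws <- lapply(1:60, function(i)
    simulate_intra_fusion(rs, cfg, molecule_id = paste0("m", i))$truth)
  draws <- do.call(rbind, draws)
  cls_a <- classify_chromatid(draws$bp_a, ref)
  cls_b <- classify_chromatid(draws$bp_b, ref)
  expect_gte(mean(cls_a == "long" & cls_b == "short"), 0.9)
  expect_true(all(draws$amplicon_length >= 1000 &
                  draws$amplicon_length <= 20000))
})

test_that("inter amplicons record partner locus, strand and class correctly", {
  rs <- small_refset(seed = 25)
  cfg <- sim_config(seed = 3, p_insertion = 0)
  set.seed(3)
  revcomp <- function(x) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
  for (i in 1:10) {
    sim <- simulate_inter_fusion(rs, cfg)
    tr <- sim$truth
    G <- rs$genomic_contigs[[tr$ref_b]]
    S <- rs$subtelomeres[[tr$ref_a]]$sequence
    expect_identical(substr(sim$amplicon, 1, tr$bp_a),
                     substr(S, 1, tr$bp_a))
    tail_seq <- substr(sim$amplicon, tr$bp_a + 1, nchar(sim$amplicon))
    seg_len <- nchar(tail_seq)
    if (tr$strand_b == "+") {
      expect_identical(tail_seq, substr(G, tr$bp_b, tr$bp_b + seg_len - 1))
    } else {
      expect_identical(tail_seq,
                       revcomp(substr(G, tr$bp_b - seg_len + 1, tr$bp_b)))
    }
    expect_true(tr$amplicon_length >= 1000 && tr$amplicon_length <= 20000)
  }
})

test_that("simulated insertions carry their designed class", {
  rs <- small_refset(seed = 26)
  cfg_t <- sim_config(seed = 13, p_insertion = 1, p_templated = 1,
                      insertion_len_range = c(4, 10))
  cfg_u <- sim_config(seed = 14, p_insertion = 1, p_templated = 0,
                      insertion_len_range = c(4, 10))
  set.seed(13)
  refs <- ref_sequences(rs)
  for (i in 1:5) {
    tr <- simulate_intra_fusion(rs, cfg_t)$truth
    expect_identical(tr$insertion_class, "templated")
    # the template is recoverable by direct substring search
    win <- 1000
    src <- refs[[tr$template_ref]]
    expect_true(tr$template_pos >= 1)
    hit_fwd <- grepl(tr$insertion_seq,
                     substr(src, tr$template_pos, tr$template_pos +
                              nchar(tr$insertion_seq) - 1), fixed = TRUE)
    revcomp <- function(x)
      rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
    hit_rev <- substr(src, tr$template_pos, tr$template_pos +
                        nchar(tr$insertion_seq) - 1) ==
      revcomp(tr$insertion_seq)
    expect_true(hit_fwd || hit_rev)
  }
  set.seed(14)
  for (i in 1:5) {
    tr <- simulate_intra_fusion(rs, cfg_u)$truth
    expect_identical(tr$insertion_class, "untemplated")
    # exhaustive screen: the insertion occurs in neither +/-1 kb flank
    for (side in c("a", "b")) {
      bp <- tr[[paste0("bp_", side)]]
      S <- refs[[tr[[paste0("ref_", side)]]]]
      win <- substr(S, max(1, bp - 1000), min(nchar(S), bp + 1000))
      revcomp <- function(x)
        rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
      expect_false(grepl(tr$insertion_seq, win, fixed = TRUE))
      expect_false(grepl(revcomp(tr$insertion_seq), win, fixed = TRUE))
    }
  }
})

test_that("read counts, purity and error rates follow the generator model", {
  rs <- small_refset(seed = 27)
  cfg <- sim_config(seed = 2, n_inter = 0, n_intra = 2, coverage = 30)
  lib <- simulate_fusion_library(rs, cfg)
  reads <- generate_reads(lib, cfg)
  # pair count per amplicon follows round(coverage * L / (2 * read_length))
  for (i in seq_along(lib$amplicons)) {
    L <- nchar(lib$amplicons[[i]])
    expected_pairs <- max(1, round(30 * L / (2 * 100)))
    got <- sum(reads$molecule_id == lib$truth$molecule_id[i]) / 2
    expect_identical(as.integer(got), as.integer(expected_pairs))
  }
  # with zero error every read is an exact substring of its amplicon
  revcomp <- function(x) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
  idx <- sample(nrow(reads), 50)
  for (i in idx) {
    amp <- lib$amplicons[[reads$molecule_id[i]]]
    sub <- substr(amp, reads$amp_start[i], reads$amp_end[i])
    expect_identical(reads$seq[i],
                     if (reads$amp_strand[i] == "+") sub else revcomp(sub))
  }
  # substitution errors: same fragments, nonzero rate; mismatch fraction
  # within 3 binomial SDs of the configured rate
  cfg_err <- cfg
  cfg_err$error_rate_leading <- 0.01
  cfg_err$error_rate_lagging <- 0.01
  reads_err <- generate_reads(lib, cfg_err)
  expect_identical(reads$qname, reads_err$qname)
  # mismatches against the true amplicon substring measure the error rate
  revcomp2 <- function(x) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
  mism <- 0L; n_bases <- 0L
  for (i in seq_len(nrow(reads_err))) {
    amp <- lib$amplicons[[reads_err$molecule_id[i]]]
    truth_seq <- substr(amp, reads_err$amp_start[i], reads_err$amp_end[i])
    if (reads_err$amp_strand[i] == "-") truth_seq <- revcomp2(truth_seq)
    mism <- mism + sum(charToRaw(truth_seq) != charToRaw(reads_err$seq[i]))
    n_bases <- n_bases + nchar(truth_seq)
  }
  p_hat <- mism / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(p_hat - 0.01), 3 * se)
})

test_that("every emitted junction is internally consistent with its truth row", {
  rs <- recovery_refset(12, seed = 28)
  cfg <- sim_config(seed = 6, n_inter = 6, n_intra = 6)
  lib <- simulate_fusion_library(rs, cfg)
  refs <- ref_sequences(rs)
  for (i in seq_len(nrow(lib$truth))) {
    tr <- lib$truth[i, ]
    h <- junction_homology(refs[[tr$ref_a]], tr$bp_a, tr$strand_a,
                           refs[[tr$ref_b]], tr$bp_b, tr$strand_b)
    if (tr$insertion_class == "none") {
      expect_identical(h$microhomology, tr$microhomology)
      expect_identical(h$k_left, 0L)  # truth is left-aligned
    } else {
      expect_identical(tr$microhomology, 0L)
      expect_true(nchar(tr$insertion_seq) >= 1 &&
                  nchar(tr$insertion_seq) < 50)
    }
  }
})

test_that("truth tables round-trip and enumerate molecules uniquely", {
  rs <- small_refset(seed = 29)
  cfg <- sim_config(seed = 4, n_inter = 2, n_intra = 2)
  lib <- simulate_fusion_library(rs, cfg)
  path <- tempfile(fileext = ".tsv")
  write_truth_table(lib$truth, path)
  back <- read_truth_table(path)
  expect_identical(back$molecule_id, lib$truth$molecule_id)
  expect_identical(back$insertion_seq, lib$truth$insertion_seq)
  expect_identical(back$bp_a, lib$truth$bp_a)
  expect_false(anyDuplicated(back$molecule_id) > 0)

  # empty truth: header-only file
  write_truth_table(NULL, path)
  expect_identical(length(readLines(path)), 1L)
})
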