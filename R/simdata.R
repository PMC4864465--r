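#' Simulation configuration for fusion amplicons and reads
#'
#' Bundles every tunable of the amplicon/read generator.  With a fixed `seed`
#' the generator output is byte-identical between runs.
#'
#' @param seed Integer RNG seed.
#' @param n_inter,n_intra Numbers of inter-/intra-chromosomal molecules.
#' @param read_length Read length in bp.
#' @param mean_insert,sd_insert Fragment (insert) size model in bp.
#' @param coverage Target fold coverage per amplicon.
#' @param error_rate_leading,error_rate_lagging Per-base substitution rates
#'   applied to long-chromatid-derived (telomeric) and short-side
#'   (centromeric) bases of intra molecules; `error_rate_leading` applies
#'   uniformly elsewhere.  Emulates the reduced proofreading of lagging-strand
#'   synthesis.
#' @param microhomology_prob Named numeric vector: probability of each
#'   microhomology length (names "0","1",...) at a non-insertion junction.
#' @param p_insertion Probability that a junction carries an insertion
#'   (mutually exclusive with microhomology).
#' @param p_templated Probability an insertion is templated.
#' @param insertion_len_range Length range for insertions (bp, < 50).
#' @param long_window Breakpoint window for the long (telomeric) chromatid,
#'   relative to landmarks: `c(cut_site - 50, telomere_start + 200)`.
#'   Given as offsets `c(offset_from_cut, offset_past_telomere_start)`.
#' @param short_window Absolute breakpoint window for the short (centromeric)
#'   chromatid, default `c(primer_pos + 200, 1000)` given as
#'   `c(offset_from_primer, absolute_max)`.
#' @param amplicon_range Admissible amplicon lengths in bp (default
#'   1,000-20,000).
#' @param inter_length_range Target total-length range for inter-chromosomal
#'   amplicons (defaults to `amplicon_range`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_inter = 10L, n_intra = 10L,
                       read_length = 100L, mean_insert = 300L,
                       sd_insert = 30L, coverage = 30,
                       error_rate_leading = 0, error_rate_lagging = 0,
                       microhomology_prob = c("0" = 0.28, "1" = 0.20,
                                              "2" = 0.16, "3" = 0.12,
                                              "4" = 0.09, "5" = 0.06,
                                              "6" = 0.04, "7" = 0.03,
                                              "8" = 0.02),
                       p_insertion = 0.15, p_templated = 0.6,
                       insertion_len_range = c(1L, 12L),
                       long_window = c(-50L, 200L),
                       short_window = c(200L, 1000L),
                       amplicon_range = c(1000L, 20000L),
                       inter_length_range = NULL) {
  stopifnot(error_rate_leading >= 0, error_rate_leading < 1,
            error_rate_lagging >= 0, error_rate_lagging < 1,
            coverage > 0, read_length > 0,
            p_insertion >= 0, p_insertion <= 1)
  if (is.null(inter_length_range)) inter_length_range <- amplicon_range
  structure(list(seed = as.integer(seed), n_inter = as.integer(n_inter),
                 n_intra = as.integer(n_intra),
                 read_length = as.integer(read_length),
                 mean_insert = mean_insert, sd_insert = sd_insert,
                 coverage = coverage,
                 error_rate_leading = error_rate_leading,
                 error_rate_lagging = error_rate_lagging,
                 microhomology_prob = microhomology_prob / sum(microhomology_prob),
                 p_insertion = p_insertion, p_templated = p_templated,
                 insertion_len_range = as.integer(insertion_len_range),
                 long_window = as.integer(long_window),
                 short_window = as.integer(short_window),
                 amplicon_range = as.integer(amplicon_range),
                 inter_length_range = as.integer(inter_length_range)),
            class = "sim_config")
}

.empty_truth <- function() {
  data.frame(molecule_id = character(), fusion_class = character(),
             ref_a = character(), bp_a = integer(), strand_a = character(),
             ref_b = character(), bp_b = integer(), strand_b = character(),
             microhomology = integer(), insertion_seq = character(),
             insertion_class = character(), template_ref = character(),
             template_pos = integer(), amplicon_length = integer(),
             resection_a = integer(), resection_b = integer(),
             stringsAsFactors = FALSE)
}

.truth_row <- function(molecule_id, fusion_class, ref_a, bp_a, strand_a,
                       ref_b, bp_b, strand_b, microhomology, insertion_seq,
                       insertion_class, template_ref, template_pos,
                       amplicon_length, resection_a, resection_b) {
  data.frame(molecule_id = molecule_id, fusion_class = fusion_class,
             ref_a = ref_a, bp_a = as.integer(bp_a), strand_a = strand_a,
             ref_b = ref_b, bp_b = as.integer(bp_b), strand_b = strand_b,
             microhomology = as.integer(microhomology),
             insertion_seq = insertion_seq, insertion_class = insertion_class,
             template_ref = template_ref,
             template_pos = as.integer(template_pos),
             amplicon_length = as.integer(amplicon_length),
             resection_a = as.integer(resection_a),
             resection_b = as.integer(resection_b),
             stringsAsFactors = FALSE)
}

.long_window_abs <- function(ref, cfg) {
  lo <- ref_landmark(ref) + cfg$long_window[1]
  hi <- min(ref$telomere_start + cfg$long_window[2], nchar(ref$sequence) - 1L)
  c(max(ref$primer_pos + 1L, lo), hi)
}

.short_window_abs <- function(ref, cfg) {
  c(ref$primer_pos + cfg$short_window[1], cfg$short_window[2])
}

## draw a junction category: microhomology length (>= 0) or insertion (-1)
.draw_category <- function(cfg) {
  if (stats::runif(1) < cfg$p_insertion) return(-1L)
  as.integer(sample(names(cfg$microhomology_prob), 1L,
                    prob = cfg$microhomology_prob))
}

## enumerate breakpoint pairs (b1 in w1, b2 in w2 of the same subtelomere)
## whose realized junction ambiguity is exactly m with k_left = 0
.intra_pairs_with_mh <- function(S, w1, w2, m) {
  b1s <- seq.int(w1[1], w1[2])
  b2s <- seq.int(w2[1], w2[2])
  if (m == 0L) {
    g <- expand.grid(b1 = b1s, b2 = b2s)
  } else {
    key1 <- substring(S, b1s + 1L, b1s + m)
    key2r <- .revcomp(substring(S, b2s - m + 1L, b2s))
    g <- merge(data.frame(b1 = b1s, key = key1),
               data.frame(b2 = b2s, key = key2r), by = "key")
    if (!nrow(g)) return(g)
  }
  ## k_right exactly m: the (m+1)-th extension base must differ
  ext_a <- substring(S, g$b1 + m + 1L, g$b1 + m + 1L)
  ret_b <- .comp_base(substring(S, g$b2 - m, g$b2 - m))
  ok_r <- ext_a != ret_b & nzchar(ext_a) & nzchar(ret_b)
  ## k_left = 0: last A base must differ from B's outward extension base
  a_last <- substring(S, g$b1, g$b1)
  b_ext <- .comp_base(substring(S, g$b2 + 1L, g$b2 + 1L))
  ok_l <- a_last != b_ext & nzchar(b_ext)
  g[ok_r & ok_l, c("b1", "b2"), drop = FALSE]
}

## sample an insertion honouring boundary canonicalization: the first inserted
## base must not extend side A and the last must not extend side B, so that
## (bp_a, ins, bp_b) is the unique consistent description of the junction
.sample_insertion <- function(cfg, refs, ref_a, bp_a, ref_b, bp_b, strand_b,
                              search_window = 1000L, max_try = 200L) {
  S_a <- refs[[ref_a]]; S_b <- refs[[ref_b]]
  a_ext <- .side_a_ext_base(S_a, bp_a, "+", 1L)
  b_ext <- .side_b_ext_base(S_b, bp_b, strand_b, 1L)
  b_first <- .side_b_base(S_b, bp_b, strand_b, 1L)
  a_last <- .side_a_base(S_a, bp_a, "+", 1L)
  templated <- stats::runif(1) < cfg$p_templated
  lr <- cfg$insertion_len_range
  sides <- data.frame(ref = c(ref_a, ref_b), bp = c(bp_a, bp_b),
                      stringsAsFactors = FALSE)
  for (i in seq_len(max_try)) {
    if (templated) {
      len <- sample(seq.int(max(2L, lr[1]), max(2L, lr[2])), 1L)
      src_side <- sample(1:2, 1L)
      src_seq <- refs[[sides$ref[src_side]]]
      lo <- max(1L, sides$bp[src_side] - search_window)
      hi <- min(nchar(src_seq), sides$bp[src_side] + search_window) - len + 1L
      if (hi <= lo) next
      st <- sample(seq.int(lo, hi), 1L)
      ins <- substr(src_seq, st, st + len - 1L)
      if (stats::runif(1) < 0.5) ins <- .revcomp(ins)
      tmpl_ref <- sides$ref[src_side]; tmpl_pos <- st
    } else {
      len <- sample(seq.int(lr[1], lr[2]), 1L)
      ins <- .random_dna(len)
      tmpl_ref <- NA_character_; tmpl_pos <- NA_integer_
    }
    if (grepl("[^ACGT]", ins)) next
    f <- substr(ins, 1L, 1L); l <- substr(ins, nchar(ins), nchar(ins))
    ## boundary canonicalization; also keep the junction itself unambiguous
    if (identical(f, a_ext) || identical(l, b_ext)) next
    if (identical(f, b_first) && nchar(ins) == 1L) {
      ## single base equal to B's first base is indistinguishable from a
      ## breakpoint shift; reject
      next
    }
    cls <- classify_insertion(ins, sides, refs, search_window = search_window)
    if (templated && cls$ins_class != "templated") next
    if (!templated && cls$ins_class != "untemplated") next
    return(list(sequence = ins,
                ins_class = cls$ins_class,
                template_ref = if (templated) cls$template_ref else NA_character_,
                template_pos = if (templated) cls$template_pos else NA_integer_))
  }
  NULL
}

#' Simulate one head-to-head intra-chromosomal fusion amplicon
#'
#' Builds an amplicon joining two sister-chromatid copies of one subtelomere
#' head-to-head: the long (telomeric) chromatid `S[primer..b1]` followed by
#' the reverse complement of the short (centromeric) chromatid
#' `S[primer..b2]`, with optional junction microhomology or insertion.
#' Breakpoints are drawn from a bimodal architecture (long near the landmark,
#' short within the first kilobase) unless given explicitly.  Truth records
#' the left-aligned canonical breakpoints.
#'
#' @param refset A `reference_set`.
#' @param cfg A [sim_config()].
#' @param subtel Subtelomere reference name (default: first).
#' @param molecule_id Identifier for the truth record.
#' @param breakpoints Optional `c(b1, b2)` explicit breakpoints; the realized
#'   junction ambiguity is computed and recorded as truth.
#' @param max_try Resampling limit when a requested junction category is
#'   unrealizable at sampled breakpoints.
#' @return List with `amplicon` (character) and `truth` (one-row data.frame).
#' @export
simulate_intra_fusion <- function(refset, cfg, subtel = NULL,
                                  molecule_id = "mol1", breakpoints = NULL,
                                  max_try = 100L) {
  if (is.null(subtel)) subtel <- names(refset$subtelomeres)[1]
  ref <- refset$subtelomeres[[subtel]]
  S <- ref$sequence
  refs <- ref_sequences(refset)
  w1 <- .long_window_abs(ref, cfg)
  w2 <- .short_window_abs(ref, cfg)
  if (nchar(S) < w1[1]) stop("subtelomere shorter than the long-chromatid minimum")
  ins <- NULL; m <- 0L
  if (!is.null(breakpoints)) {
    b1 <- as.integer(breakpoints[1]); b2 <- as.integer(breakpoints[2])
    h <- junction_homology(S, b1, "+", S, b2, "-")
    ## record the left-aligned canonical placement as truth
    b1 <- b1 - h$k_left; b2 <- b2 + h$k_left
    m <- h$microhomology
  } else {
    found <- FALSE
    for (attempt in seq_len(max_try)) {
      cat_m <- .draw_category(cfg)
      if (cat_m >= 0L) {
        cand <- .intra_pairs_with_mh(S, w1, w2, cat_m)
        if (!nrow(cand)) next
        i <- sample.int(nrow(cand), 1L)
        b1 <- cand$b1[i]; b2 <- cand$b2[i]; m <- cat_m
        found <- TRUE
        break
      } else {
        b1 <- sample(seq.int(w1[1], w1[2]), 1L)
        b2 <- sample(seq.int(w2[1], w2[2]), 1L)
        ## an insertion junction must also be blunt at the breakpoints
        if (junction_homology(S, b1, "+", S, b2, "-")$microhomology != 0L)
          next
        ins <- .sample_insertion(cfg, refs, subtel, b1, subtel, b2, "-")
        if (is.null(ins)) next
        m <- 0L
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("requested junction category unrealizable after ", max_try,
           " attempts")
  }
  ins_seq <- if (is.null(ins)) "" else ins$sequence
  amplicon <- paste0(substr(S, ref$primer_pos, b1), ins_seq,
                     .revcomp(substr(S, ref$primer_pos, b2)))
  landmark <- ref_landmark(ref)
  truth <- .truth_row(
    molecule_id, "intra", subtel, b1, "+", subtel, b2, "-", m,
    ins_seq,
    if (is.null(ins)) "none" else ins$ins_class,
    if (is.null(ins)) NA_character_ else ins$template_ref,
    if (is.null(ins)) NA_integer_ else ins$template_pos,
    nchar(amplicon), landmark - b1, landmark - b2)
  list(amplicon = amplicon, truth = truth)
}

#' Simulate one telomere-genomic inter-chromosomal fusion amplicon
#'
#' Joins a subtelomeric segment `S[primer..b1]` to a genomic segment from a
#' decoy contig (either strand), with optional junction microhomology or
#' insertion.  The amplicon 3' end is truncated at a sampled total length
#' within `cfg$inter_length_range`.
#'
#' @inheritParams simulate_intra_fusion
#' @param contig Genomic contig name (default: sampled).
#' @return List with `amplicon` and `truth`.
#' @export
simulate_inter_fusion <- function(refset, cfg, subtel = NULL,
                                  molecule_id = "mol1", contig = NULL,
                                  max_try = 100L) {
  if (length(refset$genomic_contigs) == 0)
    stop("reference set has no genomic contig")
  if (is.null(subtel)) subtel <- names(refset$subtelomeres)[1]
  ref <- refset$subtelomeres[[subtel]]
  S <- ref$sequence
  refs <- ref_sequences(refset)
  w1 <- .long_window_abs(ref, cfg)
  done <- FALSE
  for (attempt in seq_len(max_try)) {
    cname <- if (is.null(contig)) sample(names(refset$genomic_contigs), 1L)
             else contig
    G <- refset$genomic_contigs[[cname]]
    b1 <- sample(seq.int(w1[1], w1[2]), 1L)
    strand_b <- sample(c("+", "-"), 1L)
    cat_m <- .draw_category(cfg)
    ins <- NULL; m <- 0L
    ## target total length; segment length follows
    lo <- max(cfg$inter_length_range[1], b1 + 200L)
    hi <- min(cfg$inter_length_range[2], cfg$amplicon_range[2])
    if (hi <= lo) next
    total <- sample(seq.int(lo, hi), 1L)
    if (cat_m >= 1L) {
      key <- substr(S, b1 + 1L, b1 + cat_m)
      if (grepl("[^ACGT]", key) || nchar(key) < cat_m) next
      pat <- if (strand_b == "+") key else .revcomp(key)
      hits <- as.integer(gregexpr(pat, G, fixed = TRUE)[[1]])
      if (hits[1] == -1L) next
      ## breakpoint = first retained base on the fused strand
      cand <- if (strand_b == "+") hits else hits + cat_m - 1L
      cand <- sample(cand)
      c_b <- NA_integer_
      for (cc in cand) {
        h <- junction_homology(S, b1, "+", G, cc, strand_b)
        if (h$k_left == 0L && h$k_right == cat_m) { c_b <- cc; break }
      }
      if (is.na(c_b)) next
      m <- cat_m
    } else if (cat_m == 0L) {
      c_b <- sample.int(nchar(G), 1L)
      h <- junction_homology(S, b1, "+", G, c_b, strand_b)
      if (h$microhomology != 0L) next
    } else {
      c_b <- sample.int(nchar(G), 1L)
      h <- junction_homology(S, b1, "+", G, c_b, strand_b)
      if (h$microhomology != 0L) next
      ins <- .sample_insertion(cfg, refs, subtel, b1, cname, c_b, strand_b)
      if (is.null(ins)) next
    }
    ins_seq <- if (is.null(ins)) "" else ins$sequence
    seg_len <- total - (b1 - ref$primer_pos + 1L) - nchar(ins_seq)
    if (seg_len < 100L) next
    if (strand_b == "+") {
      if (c_b + seg_len - 1L > nchar(G)) next
      seg <- substr(G, c_b, c_b + seg_len - 1L)
    } else {
      if (c_b - seg_len + 1L < 1L) next
      seg <- .revcomp(substr(G, c_b - seg_len + 1L, c_b))
    }
    amplicon <- paste0(substr(S, ref$primer_pos, b1), ins_seq, seg)
    done <- TRUE
    break
  }
  if (!done)
    stop("could not realize an inter-chromosomal amplicon after ", max_try,
         " attempts (no genomic contig long enough?)")
  landmark <- ref_landmark(ref)
  truth <- .truth_row(
    molecule_id, "inter", subtel, b1, "+", cname, c_b, strand_b, m,
    ins_seq,
    if (is.null(ins)) "none" else ins$ins_class,
    if (is.null(ins)) NA_character_ else ins$template_ref,
    if (is.null(ins)) NA_integer_ else ins$template_pos,
    nchar(amplicon), landmark - b1, NA_integer_)
  list(amplicon = amplicon, truth = truth)
}

#' Simulate a library of fusion amplicons with ground truth
#'
#' Generates `cfg$n_inter` inter- and `cfg$n_intra` intra-chromosomal fusion
#' molecules.  When the reference set has at least as many subtelomeres as
#' molecules, each molecule is assigned its own subtelomeric end (a
#' multiplexed family of distinct ends, which keeps every truth molecule
#' uniquely mappable); otherwise subtelomeres are recycled.
#'
#' @param refset A `reference_set`.
#' @param cfg A [sim_config()]; `cfg$seed` seeds the RNG.
#' @return List with `amplicons` (named character vector) and `truth`
#'   (data.frame, one row per molecule).
#' @export
simulate_fusion_library <- function(refset, cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_inter + cfg$n_intra
  subs <- names(refset$subtelomeres)
  assign_sub <- if (length(subs) >= n) subs[seq_len(n)]
                else rep_len(subs, n)
  classes <- c(rep("inter", cfg$n_inter), rep("intra", cfg$n_intra))
  amplicons <- character(n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("mol%04d", i)
    sim <- if (classes[i] == "inter")
      simulate_inter_fusion(refset, cfg, subtel = assign_sub[i],
                            molecule_id = id)
    else
      simulate_intra_fusion(refset, cfg, subtel = assign_sub[i],
                            molecule_id = id)
    amplicons[i] <- sim$amplicon
    truths[[i]] <- sim$truth
  }
  names(amplicons) <- sprintf("mol%04d", seq_len(n))
  truth <- do.call(rbind, truths)
  bad <- truth$amplicon_length < cfg$amplicon_range[1] |
         truth$amplicon_length > cfg$amplicon_range[2]
  if (any(bad))
    warning(sum(bad), " amplicon(s) outside the configured length range")
  list(amplicons = amplicons, truth = truth)
}

.mutate_bases <- function(chars, idx) {
  if (!length(idx)) return(chars)
  chars[idx] <- vapply(chars[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
    USE.NAMES = FALSE)
  chars
}

#' Generate paired-end reads from simulated amplicons
#'
#' Samples inward-facing read pairs to the target coverage: per amplicon the
#' pair count is `round(coverage * length / (2 * read_length))`.  Fragment
#' lengths are normal (truncated to `[read_length, amplicon length]`).
#' Substitution errors are applied per base at `error_rate_leading` on bases
#' deriving from the long (telomeric) chromatid of intra molecules and
#' `error_rate_lagging` on short-side (centromeric) bases; non-intra
#' molecules use `error_rate_leading` throughout.
#'
#' @param library Output of [simulate_fusion_library()].
#' @param cfg A [sim_config()]; reads are seeded from `cfg$seed + 1`.
#' @param fastq1,fastq2 Optional output FASTQ paths for mates 1 and 2.
#' @return data.frame with one row per read: `qname`, `mate`, `seq`,
#'   `molecule_id`, `amp_start`, `amp_end`, `amp_strand`.
#' @export
generate_reads <- function(library, cfg, fastq1 = NULL, fastq2 = NULL) {
  set.seed(cfg$seed + 1L)
  rl <- cfg$read_length
  out <- vector("list", length(library$amplicons))
  for (i in seq_along(library$amplicons)) {
    amp <- library$amplicons[[i]]
    tr <- library$truth[i, ]
    L <- nchar(amp)
    if (rl > L) stop("read_length exceeds amplicon length for ",
                     tr$molecule_id)
    n_pairs <- max(1L, round(cfg$coverage * L / (2 * rl)))
    flen <- pmin(pmax(round(stats::rnorm(n_pairs, cfg$mean_insert,
                                         cfg$sd_insert)), rl), L)
    fstart <- vapply(flen, function(fl)
      sample.int(L - fl + 1L, 1L), integer(1))
    fend <- fstart + flen - 1L
    r1 <- substring(amp, fstart, fstart + rl - 1L)
    r2 <- .revcomp(substring(amp, fend - rl + 1L, fend))
    if (cfg$error_rate_leading > 0 || cfg$error_rate_lagging > 0) {
      is_intra <- tr$fusion_class == "intra"
      ## amplicon coordinate of the last long-chromatid (plus insertion) base;
      ## the primer origin is coordinate 1 by convention
      boundary <- if (is_intra) tr$bp_a + nchar(tr$insertion_seq) else L + 1L
      for (p in seq_len(n_pairs)) {
        ## mate 1: amplicon positions fstart..fstart+rl-1 (forward)
        pos1 <- fstart[p]:(fstart[p] + rl - 1L)
        rate1 <- ifelse(pos1 <= boundary, cfg$error_rate_leading,
                        cfg$error_rate_lagging)
        idx1 <- which(stats::runif(rl) < rate1)
        if (length(idx1)) {
          ch <- strsplit(r1[p], "")[[1]]
          r1[p] <- paste(.mutate_bases(ch, idx1), collapse = "")
        }
        ## mate 2: read bases run from fend downwards on the amplicon
        pos2 <- fend[p]:(fend[p] - rl + 1L)
        rate2 <- ifelse(pos2 <= boundary, cfg$error_rate_leading,
                        cfg$error_rate_lagging)
        idx2 <- which(stats::runif(rl) < rate2)
        if (length(idx2)) {
          ch <- strsplit(r2[p], "")[[1]]
          r2[p] <- paste(.mutate_bases(ch, idx2), collapse = "")
        }
      }
    }
    qn <- sprintf("%s_frag%05d", tr$molecule_id, seq_len(n_pairs))
    out[[i]] <- data.frame(
      qname = rep(qn, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = c(r1, r2),
      molecule_id = tr$molecule_id,
      amp_start = c(fstart, fend - rl + 1L),
      amp_end = c(fstart + rl - 1L, fend),
      amp_strand = rep(c("+", "-"), each = n_pairs),
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  if (!is.null(fastq1)) {
    write_fastq(reads[reads$mate == 1L, ], fastq1, suffix = "/1")
    write_fastq(reads[reads$mate == 2L, ], fastq2, suffix = "/2")
  }
  reads
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `qname` and `seq` columns.
#' @param path Output path.
#' @param suffix Read-name suffix (e.g. "/1").
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, suffix = "") {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$qname, suffix),
                           reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the simulator truth table
#'
#' One TSV row per molecule with all ground-truth fields.
#' @param truth Truth data.frame from [simulate_fusion_library()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  if (is.null(truth) || nrow(truth) == 0) truth <- .empty_truth()
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(insertion_seq = "character"))
  df$insertion_seq[is.na(df$insertion_seq)] <- ""
  df
}
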