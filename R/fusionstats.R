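## Fusion population statistics ---------------------------------------------

#' Diploid-genome equivalents from input DNA mass
#'
#' One diploid human genome approximates 6 pg of DNA, so
#' `genomes = mass_ng * 1000 / pg_per_genome`.
#'
#' @param mass_ng Input DNA mass in nanograms (> 0).
#' @param pg_per_genome Picograms per diploid genome (default 6).
#' @return Diploid-genome equivalents (numeric).
#' @export
genomes_from_mass <- function(mass_ng, pg_per_genome = 6) {
  if (any(mass_ng <= 0)) stop("mass must be positive")
  mass_ng * 1000 / pg_per_genome
}

#' Fusion frequency per diploid genome
#'
#' The number of resolved nonconstitutive fusion events divided by the number
#' of input DNA molecules expressed in diploid genomes.
#'
#' @param event_count Number of unique fusion events (>= 0).
#' @param genomes Diploid-genome equivalents (> 0).
#' @return List of class `frequency_estimate`: `event_count`, `genomes`,
#'   `frequency`.
#' @export
fusion_frequency <- function(event_count, genomes) {
  if (any(event_count < 0)) stop("negative event count")
  if (any(genomes <= 0)) stop("genomes must be positive")
  structure(list(event_count = event_count, genomes = genomes,
                 frequency = event_count / genomes),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("%d event(s) / %s diploid genomes = %.3g per diploid genome\n",
              x$event_count, format(x$genomes, big.mark = ","), x$frequency))
  invisible(x)
}

#' Expected event count from a fusion frequency
#'
#' @param frequency Events per diploid genome.
#' @param genomes Diploid-genome equivalents.
#' @return `frequency * genomes`.
#' @export
expected_event_count <- function(frequency, genomes) frequency * genomes

#' Ratio of inter- to intra-chromosomal fusion reads
#'
#' @param inter_reads,intra_reads Read (or linkage) counts.
#' @return Ratio; `NA` with a warning when the denominator is zero.
#' @export
inter_intra_ratio <- function(inter_reads, intra_reads) {
  if (intra_reads == 0) {
    warning("intra read count is zero; ratio undefined")
    return(NA_real_)
  }
  inter_reads / intra_reads
}

#' Bin positions along a reference
#'
#' Counts positions (read starts or junction coordinates) in consecutive
#' fixed-width bins; total counts are conserved.
#'
#' @param positions 1-based coordinates.
#' @param bin_width Bin width in bp (default 100).
#' @param ref_length Optional reference length fixing the number of bins.
#' @return List of class `bin_profile`: `bin_width`, `breaks` (bin start
#'   coordinates), `counts`.
#' @export
bin_profile <- function(positions, bin_width = 100L, ref_length = NULL) {
  stopifnot(bin_width > 0)
  if (!is.null(ref_length) && any(positions > ref_length | positions < 1))
    stop("position out of range")
  n_bins <- if (is.null(ref_length)) ceiling(max(positions) / bin_width)
            else ceiling(ref_length / bin_width)
  bin <- (as.integer(positions) - 1L) %/% as.integer(bin_width) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_width = as.integer(bin_width),
                 breaks = (seq_len(n_bins) - 1L) * as.integer(bin_width) + 1L,
                 counts = counts),
            class = "bin_profile")
}

#' Number of occupied modes in a binned profile
#'
#' Counts runs of occupied bins separated by at least `min_gap` empty bins --
#' a simple detector for the bimodal (short/long chromatid) architecture of
#' head-to-head fusion profiles.
#'
#' @param profile A [bin_profile()].
#' @param min_gap Minimum empty-bin run separating modes (default 3).
#' @return Integer mode count.
#' @export
profile_modes <- function(profile, min_gap = 3L) {
  occ <- profile$counts > 0
  r <- rle(occ)
  ## merge occupied runs separated by short gaps
  modes <- 0L; open <- FALSE
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      if (!open) { modes <- modes + 1L; open <- TRUE }
    } else if (r$lengths[i] >= min_gap) {
      open <- FALSE
    }
  }
  modes
}

#' Chromatid class from a breakpoint position
#'
#' Distance from the primer origin classifies the fused chromatid: short
#' (< 1 kb), long (> 2 kb), else intermediate.
#'
#' @param bp Breakpoint coordinate(s).
#' @param ref A `subtelomere_reference`.
#' @param short_max,long_min Class thresholds in bp (defaults 1000 / 2000).
#' @return Character vector in {"short", "long", "intermediate"}.
#' @export
classify_chromatid <- function(bp, ref, short_max = 1000L, long_min = 2000L) {
  d <- as.integer(bp) - ref$primer_pos
  ifelse(d < short_max, "short", ifelse(d > long_min, "long", "intermediate"))
}

.test_result <- function(statistic, p_value, tails, method, groups = NULL) {
  structure(list(statistic = statistic, p_value = p_value, tails = tails,
                 method = method, groups = groups),
            class = "fusion_test")
}

#' @export
print.fusion_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, %s-tailed p = %.4g\n",
              x$method, x$statistic, x$tails, x$p_value))
  invisible(x)
}

#' Chi-square test of junction coincidence with genes
#'
#' Compares the observed fraction of junctions falling inside (merged) gene
#' intervals with an expected genome-wide gene-content fraction using a
#' 1-degree-of-freedom chi-square without continuity correction:
#' `X^2 = (obs_in - n e)^2 / (n e) + (obs_out - n (1 - e))^2 / (n (1 - e))`.
#'
#' @param junction_coords data.frame with `ref` and `pos` columns.
#' @param gene_intervals data.frame with `ref`, `start`, `end` (1-based,
#'   inclusive) or a `GRanges`.
#' @param expected_fraction Genome-wide gene-content estimate (default 0.418).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A `fusion_test` with `observed_fraction` in `groups`.
#' @export
gene_overlap_test <- function(junction_coords, gene_intervals,
                              expected_fraction = 0.418, correct = FALSE) {
  n <- nrow(junction_coords)
  stopifnot(n >= 1)
  gr <- .as_feature_ranges(gene_intervals)
  if (length(gr) == 0) stop("empty interval set")
  gr <- GenomicRanges::reduce(gr)
  jr <- GenomicRanges::GRanges(junction_coords$ref,
                               IRanges::IRanges(junction_coords$pos,
                                                junction_coords$pos))
  in_gene <- GenomicRanges::countOverlaps(jr, gr) > 0
  obs_in <- sum(in_gene); obs_out <- n - obs_in
  e_in <- n * expected_fraction; e_out <- n * (1 - expected_fraction)
  adj <- if (correct) 0.5 else 0
  stat <- (max(0, abs(obs_in - e_in) - adj))^2 / e_in +
          (max(0, abs(obs_out - e_out) - adj))^2 / e_out
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  .test_result(stat, p, "two", "chi-square gene overlap (1 df)",
               groups = list(n = n, observed_fraction = obs_in / n,
                             expected_fraction = expected_fraction))
}

.as_feature_ranges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$ref, IRanges::IRanges(x$start, x$end))
}

#' Permutation test of junction proximity to genomic features
#'
#' Observed statistic: fraction of junctions with at least one feature within
#' `window` bp.  The null distribution is built from `n_random` uniformly
#' placed position sets of equal size over the same reference space
#' (excluding N gaps).  Empirical p is `(1 + #null >= obs)/(n_random + 1)`
#' for enrichment ("greater") or the mirrored form for depletion ("less").
#'
#' @param junctions data.frame with `ref`, `pos`.
#' @param features data.frame with `ref`, `start`, `end` or a `GRanges`.
#' @param ref_lengths Named vector of reference lengths defining the sampling
#'   space (alternatively a named character vector of sequences).
#' @param window Proximity half-width in bp.
#' @param n_random Number of null position sets (>= 100).
#' @param seed RNG seed (required: permutation p-values are reported with
#'   their seed).
#' @param alternative "greater" (enrichment, default) or "less".
#' @return A `fusion_test`; `groups` holds `observed`, `null_mean`,
#'   `fold_change`, `n_random`, `seed`.
#' @export
feature_proximity_test <- function(junctions, features, ref_lengths,
                                   window = 500L, n_random = 1000L,
                                   seed = 1L, alternative = "greater") {
  stopifnot(window > 0, n_random >= 100)
  if (is.character(ref_lengths))  # sequences given: use their lengths
    ref_lengths <- setNames(nchar(ref_lengths), names(ref_lengths))
  fr <- .as_feature_ranges(features)
  if (length(fr) == 0) stop("empty feature set")
  fr <- GenomicRanges::reduce(fr)
  prox_frac <- function(ref, pos) {
    jr <- GenomicRanges::GRanges(ref, IRanges::IRanges(pos - window,
                                                       pos + window))
    mean(GenomicRanges::countOverlaps(jr, fr) > 0)
  }
  obs <- prox_frac(junctions$ref, junctions$pos)
  n <- nrow(junctions)
  set.seed(seed)
  tot <- sum(ref_lengths)
  cum <- cumsum(ref_lengths)
  null <- vapply(seq_len(n_random), function(i) {
    u <- sample.int(tot, n, replace = TRUE)
    ri <- findInterval(u - 1L, c(0L, cum))
    pos <- u - c(0L, cum)[ri]
    prox_frac(names(ref_lengths)[ri], pos)
  }, numeric(1))
  p <- if (alternative == "greater") (1 + sum(null >= obs)) / (n_random + 1)
       else (1 + sum(null <= obs)) / (n_random + 1)
  fold <- if (mean(null) > 0) obs / mean(null) else Inf
  .test_result(obs, p, "one",
               sprintf("permutation feature proximity (+/-%d bp)", window),
               groups = list(observed = obs, null_mean = mean(null),
                             fold_change = fold, n_random = n_random,
                             seed = seed, alternative = alternative))
}

#' GC content of junction-proximal sequence
#'
#' (G+C)/(A+C+G+T) over the concatenated windows of `half_window` bp either
#' side of both breakpoints (truncated at reference ends); N bases are
#' excluded from the denominator.
#'
#' @param junction List/row with `ref_a`, `bp_a`, `ref_b`, `bp_b`.
#' @param refs Named character vector of reference sequences.
#' @param half_window Half-width in bp (default 500).
#' @return GC fraction.
#' @export
gc_content_window <- function(junction, refs, half_window = 500L) {
  grab <- function(refname, bp) {
    s <- refs[[refname]]
    if (bp - half_window < 1L || bp + half_window > nchar(s))
      warning("window truncated at reference end")
    .window_seq(s, bp - half_window, bp + half_window)
  }
  seqs <- paste0(grab(junction$ref_a, junction$bp_a),
                 grab(junction$ref_b, junction$bp_b))
  counts <- table(strsplit(seqs, "")[[1]])
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) stop("all-N window")
  as.numeric(gc / acgt)
}

#' Welch unequal-variance t statistic
#'
#' Computed from the closed form
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples (length >= 2 each).
#' @param tails "one" or "two".
#' @param alternative For one-tailed tests: "greater" (mean(x) > mean(y)) or
#'   "less".
#' @return A `fusion_test` with per-group summaries.
#' @export
welch_t <- function(x, y, tails = c("two", "one"), alternative = "greater") {
  tails <- match.arg(tails)
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    tstat <- 0
    df <- nx + ny - 2
  } else {
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  p_two <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_one <- if (alternative == "greater")
    stats::pt(tstat, df, lower.tail = FALSE)
  else stats::pt(tstat, df, lower.tail = TRUE)
  .test_result(tstat, if (tails == "two") p_two else p_one, tails,
               "Welch unequal-variance t-test",
               groups = list(df = df,
                             x = list(n = nx, mean = mean(x), var = vx),
                             y = list(n = ny, mean = mean(y), var = vy),
                             alternative = alternative))
}

#' Per-molecule mismatch rates from an alignment table
#'
#' Nonreference substitutions divided by aligned bases, aggregated per
#' molecule.  Positions inside `variant_mask` (data.frame `ref`, `start`,
#' `end`) are excluded from both numerator and denominator only when a mask
#' is supplied and a read lies wholly within it; the mask models known
#' constitutive variants.
#'
#' @param alignments Alignment table (needs `nm`, `qstart`, `qend`,
#'   `molecule_id` or `qname` prefixed by molecule).
#' @param molecule_of Optional function mapping `qname` to molecule id
#'   (default: strip everything from the last underscore).
#' @return data.frame `molecule_id`, `mismatches`, `aligned`, `rate`.
#' @export
per_molecule_mismatch <- function(alignments, molecule_of = NULL) {
  if (is.null(molecule_of))
    molecule_of <- function(q) sub("_[^_]*$", "", q)
  mol <- if (!is.null(alignments$molecule_id)) alignments$molecule_id
         else molecule_of(alignments$qname)
  aligned <- alignments$qend - alignments$qstart + 1L
  agg <- stats::aggregate(cbind(mismatches = alignments$nm,
                                aligned = aligned),
                          by = list(molecule_id = mol), FUN = sum)
  agg$rate <- agg$mismatches / agg$aligned
  agg
}

#' Compare mismatch rates between short- and long-side reads
#'
#' Welch t-test on per-molecule mismatch rates of reads segregated into
#' short (centromeric) and long (telomeric) chromatid components -- the
#' signature of differential polymerase fidelity between the fusing
#' chromatids.  One-tailed by default with the alternative that centromeric
#' (short-side) rates are higher.
#'
#' @param short_rates,long_rates data.frames from [per_molecule_mismatch()]
#'   (or numeric vectors of per-molecule rates).
#' @param tails "one" or "two".
#' @return A `fusion_test`.
#' @export
mismatch_rate_compare <- function(short_rates, long_rates, tails = "one") {
  xs <- if (is.data.frame(short_rates)) short_rates$rate else short_rates
  yl <- if (is.data.frame(long_rates)) long_rates$rate else long_rates
  if (is.data.frame(short_rates) && any(short_rates$aligned == 0))
    stop("group with zero aligned bases")
  if (length(xs) < 2 || length(yl) < 2)
    stop("each group needs >= 2 molecules")
  welch_t(xs, yl, tails = tails, alternative = "greater")
}
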