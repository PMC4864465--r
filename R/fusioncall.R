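## Discordant-pair fusion calling -------------------------------------------

.pair_table <- function(alignments) {
  m1 <- alignments[alignments$mate == 1L, ]
  m2 <- alignments[alignments$mate == 2L, ]
  pairs <- merge(m1, m2, by = "qname", suffixes = c("_1", "_2"))
  attr(pairs, "n_orphan") <- (nrow(m1) - nrow(pairs)) + (nrow(m2) - nrow(pairs))
  pairs
}

.classify_wide <- function(pairs, refset, insert_bounds) {
  sub1 <- is_subtelomere(refset, pairs$ref_1)
  sub2 <- is_subtelomere(refset, pairs$ref_2)
  known <- (sub1 | pairs$ref_1 %in% names(refset$genomic_contigs)) &
           (sub2 | pairs$ref_2 %in% names(refset$genomic_contigs))
  if (!all(known))
    stop("alignment reference name absent from the reference set")
  same_ref <- pairs$ref_1 == pairs$ref_2
  opp <- pairs$strand_1 != pairs$strand_2
  lo <- pmin(pairs$pos_1, pairs$pos_2)
  hi <- pmax(pairs$end_1, pairs$end_2)
  frag <- hi - lo + 1L
  left_plus <- ifelse(pairs$pos_1 <= pairs$pos_2, pairs$strand_1,
                      pairs$strand_2) == "+"
  concordant <- same_ref & opp & left_plus &
    frag >= insert_bounds[1] & frag <= insert_bounds[2]
  intra <- !concordant & same_ref & sub1 & sub2 &
    pairs$strand_1 == pairs$strand_2
  inter <- !concordant & !intra & (sub1 != sub2)
  cls <- rep("ambiguous", nrow(pairs))
  cls[concordant] <- "concordant"
  cls[intra] <- "intra"
  cls[inter] <- "inter"
  cls
}

#' Classify a read pair against the expected library geometry
#'
#' A pair is `concordant` when both mates map to one reference on opposing
#' strands, inward facing, with an inferred fragment within `insert_bounds`;
#' `intra` when both mates map to a single subtelomeric reference in the same
#' orientation (the head-to-head sister-chromatid signature); `inter` when
#' exactly one mate maps to a subtelomeric reference and the other to a
#' genomic contig; otherwise `ambiguous`.
#'
#' @param pair List with `mate1` and `mate2`, each a list/row with `ref`,
#'   `pos`, `end`, `strand` (and optionally `mapq`).
#' @param refset A `reference_set`.
#' @param insert_bounds Length-2 numeric `(min, max)` fragment bounds.
#' @return One of "concordant", "intra", "inter", "ambiguous".
#' @export
classify_pair <- function(pair, refset, insert_bounds) {
  m1 <- pair$mate1; m2 <- pair$mate2
  if (is.null(m1$ref) || is.null(m2$ref) ||
      is.na(m1$ref) || is.na(m2$ref)) return("ambiguous")
  wide <- data.frame(ref_1 = m1$ref, pos_1 = m1$pos, end_1 = m1$end,
                     strand_1 = m1$strand,
                     ref_2 = m2$ref, pos_2 = m2$pos, end_2 = m2$end,
                     strand_2 = m2$strand, stringsAsFactors = FALSE)
  .classify_wide(wide, refset, insert_bounds)
}

#' Estimate concordant insert-size bounds
#'
#' Fragment sizes of same-reference, opposing-strand, inward-facing pairs;
#' bounds are mean +/- `n_sd` standard deviations.
#'
#' @param alignments Alignment table from [align_reads()]/[read_alignments()].
#' @param n_sd Number of SDs (default 4).
#' @param fallback Bounds used when fewer than 10 proper pairs are found.
#' @return Numeric `(min, max)` with attributes `mean` and `sd`.
#' @export
estimate_insert_bounds <- function(alignments, n_sd = 4,
                                   fallback = c(50, 1500)) {
  pairs <- .pair_table(alignments)
  same <- pairs$ref_1 == pairs$ref_2 & pairs$strand_1 != pairs$strand_2
  lo <- pmin(pairs$pos_1, pairs$pos_2)
  hi <- pmax(pairs$end_1, pairs$end_2)
  left_plus <- ifelse(pairs$pos_1 <= pairs$pos_2, pairs$strand_1,
                      pairs$strand_2) == "+"
  frag <- (hi - lo + 1L)[same & left_plus]
  frag <- frag[frag < 10 * stats::median(frag)]
  if (length(frag) < 10) {
    out <- fallback
    attr(out, "mean") <- mean(fallback); attr(out, "sd") <- NA_real_
    return(out)
  }
  m <- mean(frag); s <- stats::sd(frag)
  out <- c(max(0, m - n_sd * s), m + n_sd * s)
  attr(out, "mean") <- m; attr(out, "sd") <- s
  out
}

#' Extract fusion linkages from paired alignments
#'
#' Collates mates by read name, classifies every pair, and emits one linkage
#' per non-concordant, non-ambiguous pair.  For intra linkages side A is the
#' telomeric (larger-coordinate) mate; for inter linkages side A is the
#' subtelomeric mate.  The class partition over all pairs is attached as
#' `attr(, "partition")`.
#'
#' @param alignments Alignment table.
#' @param refset A `reference_set`.
#' @param insert_bounds Optional fragment bounds; estimated from the data
#'   when `NULL`.
#' @return data.frame of linkages (one row per discordant pair).
#' @export
detect_linkages <- function(alignments, refset, insert_bounds = NULL) {
  if (is.null(insert_bounds))
    insert_bounds <- estimate_insert_bounds(alignments)
  pairs <- .pair_table(alignments)
  n_orphan <- attr(pairs, "n_orphan")
  cls <- .classify_wide(pairs, refset, insert_bounds)
  partition <- c(concordant = sum(cls == "concordant"),
                 intra = sum(cls == "intra"),
                 inter = sum(cls == "inter"),
                 ambiguous = sum(cls == "ambiguous"),
                 orphan = n_orphan)
  keep <- cls %in% c("intra", "inter")
  pairs <- pairs[keep, , drop = FALSE]
  cls <- cls[keep]
  ## side assignment
  a_is_1 <- ifelse(cls == "inter",
                   is_subtelomere(refset, pairs$ref_1),
                   pairs$pos_1 >= pairs$pos_2)
  pick <- function(f1, f2) ifelse(a_is_1, f1, f2)
  out <- data.frame(
    qname = pairs$qname, link_class = cls,
    ref_a = pick(pairs$ref_1, pairs$ref_2),
    pos_a = pick(pairs$pos_1, pairs$pos_2),
    end_a = pick(pairs$end_1, pairs$end_2),
    strand_a = pick(pairs$strand_1, pairs$strand_2),
    mapq_a = pick(pairs$mapq_1, pairs$mapq_2),
    ref_b = pick(pairs$ref_2, pairs$ref_1),
    pos_b = pick(pairs$pos_2, pairs$pos_1),
    end_b = pick(pairs$end_2, pairs$end_1),
    strand_b = pick(pairs$strand_2, pairs$strand_1),
    mapq_b = pick(pairs$mapq_2, pairs$mapq_1),
    stringsAsFactors = FALSE)
  out$mid_a <- (out$pos_a + out$end_a) / 2
  out$mid_b <- (out$pos_b + out$end_b) / 2
  rownames(out) <- NULL
  attr(out, "partition") <- partition
  attr(out, "insert_bounds") <- insert_bounds
  out
}

#' Filter linkages on mapping quality
#'
#' Retains linkages whose mates both reach `min_mapq`.  The mapping-quality
#' floor defaults to 1, which drops multi-mapping (MAPQ 0) placements such as
#' reads lying wholly within telomere repeat arrays.
#'
#' @param linkages Linkage table from [detect_linkages()].
#' @param min_mapq Minimum mapping quality (>= 0).
#' @return Filtered linkage table with `n_retained`/`n_dropped` attributes.
#' @export
mapq_filter <- function(linkages, min_mapq = 1L) {
  stopifnot(min_mapq >= 0L)
  keep <- linkages$mapq_a >= min_mapq & linkages$mapq_b >= min_mapq
  out <- linkages[keep, , drop = FALSE]
  attr(out, "partition") <- attr(linkages, "partition")
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  message(sprintf("mapq_filter: retained %d, dropped %d (min_mapq=%d)",
                  sum(keep), sum(!keep), min_mapq))
  out
}

.union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  list(find = find, union = union)
}

#' Cluster fusion linkages into events
#'
#' Single-linkage clustering within each (class, reference pair) stratum: two
#' linkages join when both side footprints (mate midpoints) lie within
#' `window` bp.  The partition is independent of input order.
#'
#' @param linkages Linkage table.
#' @param window Clustering window in bp (default 500).
#' @return data.frame of events with per-side footprints and a `qnames`
#'   list-column; the input linkages with an `event_id` column are attached
#'   as `attr(, "linkages")`.
#' @export
cluster_linkages <- function(linkages, window = 500) {
  stopifnot(window > 0)
  n <- nrow(linkages)
  if (n == 0L) {
    ev <- data.frame(event_id = character(), link_class = character(),
                     ref_a = character(), ref_b = character(),
                     n_support = integer(), a_min = integer(),
                     a_max = integer(), b_min = integer(), b_max = integer(),
                     stringsAsFactors = FALSE)
    ev$qnames <- list()
    return(ev)
  }
  ## canonical order makes clustering order-independent
  ord <- order(linkages$link_class, linkages$ref_a, linkages$ref_b,
               linkages$mid_a, linkages$mid_b, linkages$qname)
  lk <- linkages[ord, , drop = FALSE]
  uf <- .union_find(n)
  strata <- paste(lk$link_class, lk$ref_a, lk$ref_b, sep = "\r")
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) next
    mids_a <- lk$mid_a[idx]; mids_b <- lk$mid_b[idx]
    j0 <- 1L
    for (i in seq_along(idx)[-1L]) {
      while (mids_a[i] - mids_a[j0] > window) j0 <- j0 + 1L
      for (j in j0:(i - 1L)) {
        if (abs(mids_b[i] - mids_b[j]) <= window)
          uf$union(idx[i], idx[j])
      }
    }
  }
  comp <- vapply(seq_len(n), uf$find, integer(1))
  comp_ids <- sort(unique(comp))
  ev_list <- lapply(seq_along(comp_ids), function(ei) {
    rows <- lk[comp == comp_ids[ei], , drop = FALSE]
    data.frame(event_id = sprintf("ev%04d", ei),
               link_class = rows$link_class[1],
               ref_a = rows$ref_a[1], ref_b = rows$ref_b[1],
               n_support = nrow(rows),
               a_min = min(rows$pos_a), a_max = max(rows$end_a),
               b_min = min(rows$pos_b), b_max = max(rows$end_b),
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, ev_list)
  events$qnames <- lapply(seq_along(comp_ids), function(ei)
    lk$qname[comp == comp_ids[ei]])
  lk$event_id <- events$event_id[match(comp, comp_ids)]
  attr(events, "linkages") <- lk
  events
}

#' Validate unique mapping of an event by exhaustive re-alignment
#'
#' Re-aligns supporting reads locally (match +1, mismatch -1, gap -2) against
#' every reference on both strands; a read maps uniquely when its best-hit
#' score exceeds the best score on any other reference by at least `margin`.
#' The event is `unique` when a majority of re-aligned reads are unique.
#'
#' @param event One event row from [cluster_linkages()].
#' @param alignments Alignment table holding the read sequences.
#' @param refset A `reference_set`.
#' @param margin Score margin (default 5).
#' @param max_reads Supporting reads re-aligned per event (default 10).
#' @return "unique" or "ambiguous".
#' @export
validate_uniqueness <- function(event, alignments, refset, margin = 5,
                                max_reads = 10L) {
  qn <- event$qnames[[1]]
  rows <- alignments[alignments$qname %in% qn, , drop = FALSE]
  if (nrow(rows) == 0L) stop("event has no retrievable read sequences")
  rows <- utils::head(rows, max_reads)
  refs <- ref_sequences(refset)
  subjects <- Biostrings::DNAStringSet(c(refs, setNames(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(refs))),
    paste0(names(refs), "_rc"))))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  votes <- vapply(seq_len(nrow(rows)), function(i) {
    pat <- Biostrings::DNAString(rows$seq[i])
    sc <- vapply(seq_along(subjects), function(s)
      Biostrings::pairwiseAlignment(pat, subjects[[s]], type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = 0, gapExtension = 2,
                                    scoreOnly = TRUE), numeric(1))
    ## best per underlying reference (forward or reverse)
    per_ref <- pmax(sc[seq_along(refs)],
                    sc[seq_along(refs) + length(refs)])
    top <- sort(per_ref, decreasing = TRUE)
    length(per_ref) == 1L || (top[1] - top[2]) >= margin
  }, logical(1))
  if (mean(votes) > 0.5) "unique" else "ambiguous"
}
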