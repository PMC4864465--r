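## Junction model -----------------------------------------------------------
##
## A fusion junction joins two "sides".  Side A is described by the reference
## base-pair retained at the junction (its breakpoint) with retained sequence
## running INTO the junction; side B by the first reference base retained
## AFTER the junction with retained sequence running AWAY from it.  Strand
## "+" means retained bases follow the reference forward strand; "-" means
## they are the reverse complement.  All coordinates 1-based inclusive.

.char_at <- function(seq, i) substr(seq, i, i)

.common_prefix_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

.common_suffix_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

## i-th fused-strand base contributed by side A counting backwards from the
## junction (i = 1 is the breakpoint base); NA outside the reference
.side_a_base <- function(seq, bp, strand, i) {
  pos <- if (strand == "+") bp - i + 1L else bp + i - 1L
  if (pos < 1L || pos > nchar(seq)) return(NA_character_)
  b <- .char_at(seq, pos)
  if (strand == "+") b else .comp_base(b)
}

## i-th fused-strand base side A would contribute if extended past its
## breakpoint (i = 1 is the first base beyond)
.side_a_ext_base <- function(seq, bp, strand, i) {
  pos <- if (strand == "+") bp + i else bp - i
  if (pos < 1L || pos > nchar(seq)) return(NA_character_)
  b <- .char_at(seq, pos)
  if (strand == "+") b else .comp_base(b)
}

## i-th retained fused-strand base of side B (i = 1 is the first base after
## the junction)
.side_b_base <- function(seq, bp, strand, i) {
  pos <- if (strand == "+") bp + i - 1L else bp - i + 1L
  if (pos < 1L || pos > nchar(seq)) return(NA_character_)
  b <- .char_at(seq, pos)
  if (strand == "+") b else .comp_base(b)
}

## i-th fused-strand base side B would contribute if it took over fused
## positions before the junction (i = 1 immediately before)
.side_b_ext_base <- function(seq, bp, strand, i) {
  pos <- if (strand == "+") bp - i else bp + i
  if (pos < 1L || pos > nchar(seq)) return(NA_character_)
  b <- .char_at(seq, pos)
  if (strand == "+") b else .comp_base(b)
}

#' Junction breakpoint ambiguity from reference sequences
#'
#' For a junction described by two breakpoints, counts how far the junction
#' can slide right (`k_right`: side A extends while side B yields identical
#' bases) and left (`k_left`), purely from the two reference sequences.  The
#' summed value `k_left + k_right` is the junction microhomology, equal to the
#' number of consistent breakpoint placements minus one.
#'
#' @param seq_a,seq_b Reference sequences (character).
#' @param bp_a,bp_b 1-based breakpoints (side A: last retained base; side B:
#'   first retained base).
#' @param strand_a,strand_b `"+"` or `"-"` fused-strand orientations.
#' @param max_k Scan limit per direction.
#' @return List with `k_left`, `k_right`, `microhomology`.
#' @export
junction_homology <- function(seq_a, bp_a, strand_a, seq_b, bp_b, strand_b,
                              max_k = 75L) {
  k_right <- 0L
  for (i in seq_len(max_k)) {
    x <- .side_a_ext_base(seq_a, bp_a, strand_a, i)
    y <- .side_b_base(seq_b, bp_b, strand_b, i)
    if (is.na(x) || is.na(y) || x != y) break
    k_right <- i
  }
  k_left <- 0L
  for (i in seq_len(max_k)) {
    x <- .side_a_base(seq_a, bp_a, strand_a, i)
    y <- .side_b_ext_base(seq_b, bp_b, strand_b, i)
    if (is.na(x) || is.na(y) || x != y) break
    k_left <- i
  }
  list(k_left = k_left, k_right = k_right,
       microhomology = k_left + k_right)
}

#' Microhomology at a resolved junction
#'
#' Scores the sequence overlap shared by the two fusion partners at the
#' junction.  `flank_a` is the side-A fused-strand reference sequence aligned
#' to the start of `junction_seq` and extended at least 50 nt beyond the
#' breakpoint; `flank_b` is the side-B fused-strand reference sequence aligned
#' to the end of `junction_seq` and extended at least 50 nt before its
#' breakpoint.  With `p` the longest common prefix of the junction with
#' `flank_a` and `s` the longest common suffix with `flank_b`, the
#' microhomology is `max(0, p + s - length)`, i.e. the number of consistent
#' breakpoint placements minus one.
#'
#' @param junction_seq Fused-strand sequence spanning the junction.
#' @param flank_a,flank_b Extended reference flanks (see Details).
#' @return Integer microhomology count (>= 0).
#' @export
compute_microhomology <- function(junction_seq, flank_a, flank_b) {
  len <- nchar(junction_seq)
  if (nchar(flank_a) < len || nchar(flank_b) < len)
    warning("flank shorter than junction window; truncating")
  p <- .common_prefix_len(junction_seq, flank_a)
  s <- .common_suffix_len(junction_seq, flank_b)
  max(0L, p + s - len)
}

#' Brute-force enumeration of consistent breakpoint placements
#'
#' Independent characterization of junction ambiguity: every split position
#' `j` in `0..length(junction_seq)` is tested directly -- the placement is
#' consistent iff the first `j` junction bases equal the first `j` bases of
#' `flank_a` and the remaining bases equal the trailing bases of `flank_b`.
#' For junctions without an insertion the count equals
#' `compute_microhomology() + 1`.
#'
#' @inheritParams compute_microhomology
#' @return Number of consistent placements (>= 0).
#' @export
count_breakpoint_placements <- function(junction_seq, flank_a, flank_b) {
  len <- nchar(junction_seq)
  nb <- nchar(flank_b)
  count <- 0L
  for (j in 0:len) {
    ok_a <- j == 0L ||
      (nchar(flank_a) >= j &&
       substr(junction_seq, 1L, j) == substr(flank_a, 1L, j))
    keep <- len - j
    ok_b <- keep == 0L ||
      (nb >= keep &&
       substr(junction_seq, j + 1L, len) == substr(flank_b, nb - keep + 1L, nb))
    if (ok_a && ok_b) count <- count + 1L
  }
  count
}

#' Detect a junction insertion
#'
#' The maximal central run of junction bases explained by neither extended
#' flank is the insertion.  Calls of 50 nt or more are rejected as unresolved
#' complex events (`NULL` with attribute `complex = TRUE`).
#'
#' @inheritParams compute_microhomology
#' @param max_len Maximum insertion call length (default 49).
#' @return `NULL` (no insertion) or a list with `sequence`, `offset` (bases
#'   of `junction_seq` preceding the insertion) and `complex` (TRUE when the
#'   unexplained run reaches `max_len`, in which case `sequence` is `NA`).
#' @export
detect_insertion <- function(junction_seq, flank_a, flank_b, max_len = 49L) {
  len <- nchar(junction_seq)
  p <- .common_prefix_len(junction_seq, flank_a)
  s <- .common_suffix_len(junction_seq, flank_b)
  if (p + s >= len) return(NULL)
  ins <- substr(junction_seq, p + 1L, len - s)
  if (nchar(ins) > max_len)
    return(list(sequence = NA_character_, offset = p, complex = TRUE))
  list(sequence = ins, offset = p, complex = FALSE)
}

.window_seq <- function(seq, lo, hi) {
  substr(seq, max(1L, lo), min(nchar(seq), hi))
}

#' Classify a junction insertion as templated or untemplated
#'
#' An insertion is templated when it can be copied from sequence near either
#' breakpoint: the entire insertion (length >= 2; 1-nt insertions are
#' untemplated by definition) must occur exactly within `search_window` bp of
#' either breakpoint on either strand.  `min_match` relaxes this to a partial
#' longest-match threshold.  The template locus reported is the match nearest
#' a breakpoint.
#'
#' @param ins_seq Insertion sequence (1-49 nt).
#' @param sides data.frame with columns `ref`, `bp` (one row per junction
#'   side); `ref` names index into `refs`.
#' @param refs Named character vector of reference sequences.
#' @param search_window Flank half-width in bp (default 1000).
#' @param min_match Minimum exact match length for a templated call; default
#'   `NULL` requires the full insertion.
#' @return List with `ins_class` ("templated"/"untemplated"), and for
#'   templated calls `template_ref`, `template_pos` (1-based start of the
#'   match on the reference forward strand), `template_strand`, `match_len`.
#' @export
classify_insertion <- function(ins_seq, sides, refs, search_window = 1000L,
                               min_match = NULL) {
  len <- nchar(ins_seq)
  stopifnot(len >= 1L)
  if (len < 2L)
    return(list(ins_class = "untemplated"))
  need <- if (is.null(min_match)) len else max(2L, as.integer(min_match))
  best <- NULL
  for (L in seq(len, need, by = -1L)) {
    pats <- unique(vapply(seq_len(len - L + 1L),
                          function(i) substr(ins_seq, i, i + L - 1L),
                          character(1)))
    hits <- list()
    for (si in seq_len(nrow(sides))) {
      refname <- sides$ref[si]
      seq <- refs[[refname]]
      lo <- sides$bp[si] - search_window
      win <- .window_seq(seq, lo, sides$bp[si] + search_window)
      off <- max(1L, lo) - 1L
      for (pat in pats) {
        for (strand in c("+", "-")) {
          q <- if (strand == "+") pat else .revcomp(pat)
          m <- gregexpr(q, win, fixed = TRUE)[[1]]
          if (m[1] != -1L) {
            for (st in as.integer(m)) {
              pos <- st + off
              hits[[length(hits) + 1L]] <- list(
                ref = refname, pos = pos, strand = strand, match_len = L,
                dist = abs(pos - sides$bp[si]))
            }
          }
        }
      }
    }
    if (length(hits)) {
      d <- vapply(hits, `[[`, numeric(1), "dist")
      best <- hits[[which.min(d)]]
      break
    }
  }
  if (is.null(best)) return(list(ins_class = "untemplated"))
  list(ins_class = "templated", template_ref = best$ref,
       template_pos = best$pos, template_strand = best$strand,
       match_len = best$match_len)
}

#' Resection of a breakpoint from its reference landmark
#'
#' Resection is the distance from the landmark (the cut site when set, else
#' the telomere-repeat start) to a breakpoint lying centromeric of it; zero at
#' the landmark.  Breakpoints telomeric of the landmark are flagged rather
#' than given a negative value, and those at or beyond the telomere-repeat
#' start are additionally flagged as lying within the telomere repeats.
#'
#' @param bp 1-based breakpoint coordinate(s).
#' @param ref A `subtelomere_reference`.
#' @return data.frame with `resection` (bp, `NA` when telomeric of the
#'   landmark), `telomeric` and `within_telomere` flags.
#' @export
compute_resection <- function(bp, ref) {
  stopifnot(inherits(ref, "subtelomere_reference"))
  landmark <- ref_landmark(ref)
  telomeric <- bp > landmark
  data.frame(
    resection = ifelse(telomeric, NA_integer_, landmark - as.integer(bp)),
    telomeric = telomeric,
    within_telomere = bp >= ref$telomere_start)
}

#' Is a breakpoint within the nuclease footprint window?
#'
#' @param bp 1-based breakpoint coordinate(s).
#' @param ref A `subtelomere_reference` with `cut_site` set.
#' @param window Half-width in bp (default 25, inclusive).
#' @return Logical vector: `|bp - cut_site| <= window`.
#' @export
talen_footprint <- function(bp, ref, window = 25L) {
  stopifnot(inherits(ref, "subtelomere_reference"))
  if (is.na(ref$cut_site)) stop("reference has no cut_site")
  abs(as.integer(bp) - ref$cut_site) <= window
}

## Canonical junction orientation -------------------------------------------

.flip_strand <- function(s) ifelse(s == "+", "-", "+")

## reverse the fused-strand orientation of a junction description
.flip_junction <- function(j) {
  list(ref_a = j$ref_b, bp_a = j$bp_b, strand_a = .flip_strand(j$strand_b),
       ref_b = j$ref_a, bp_b = j$bp_a, strand_b = .flip_strand(j$strand_a),
       ins = if (is.null(j$ins) || !nzchar(j$ins)) j$ins else .revcomp(j$ins))
}

## canonical orientation: a subtelomeric side comes first on the forward
## strand; head-to-head intra junctions put the telomeric (larger-coordinate)
## breakpoint first
.canonical_junction <- function(j, refset) {
  a_sub <- is_subtelomere(refset, j$ref_a)
  b_sub <- is_subtelomere(refset, j$ref_b)
  if (a_sub && b_sub) {
    if (j$strand_a == "-" || (j$strand_a == "+" && j$strand_b == "-" &&
                              j$bp_a < j$bp_b))
      j <- .flip_junction(j)
  } else if (b_sub && !a_sub) {
    j <- .flip_junction(j)
  } else if (a_sub && j$strand_a == "-") {
    j <- .flip_junction(j)
  }
  j
}

## slide a junction without insertion to its left-aligned placement
.left_align_junction <- function(j, refs, max_k = 75L) {
  if (!is.null(j$ins) && nzchar(j$ins)) return(j)
  seq_a <- refs[[j$ref_a]]; seq_b <- refs[[j$ref_b]]
  for (i in seq_len(max_k)) {
    x <- .side_a_base(seq_a, j$bp_a, j$strand_a, 1L)
    y <- .side_b_ext_base(seq_b, j$bp_b, j$strand_b, 1L)
    if (is.na(x) || is.na(y) || x != y) break
    j$bp_a <- j$bp_a + ifelse(j$strand_a == "+", -1L, 1L)
    j$bp_b <- j$bp_b + ifelse(j$strand_b == "+", -1L, 1L)
  }
  j
}

## Soft-clip junction resolution --------------------------------------------

.parse_clips <- function(cigar) {
  left <- rep(0L, length(cigar))
  m <- regexpr("^\\d+(?=S)", cigar, perl = TRUE)
  left[m > 0] <- as.integer(regmatches(cigar, m))
  right <- rep(0L, length(cigar))
  m <- regexpr("\\d+(?=S$)", cigar, perl = TRUE)
  right[m > 0] <- as.integer(regmatches(cigar, m))
  data.frame(left = left, right = right)
}

## one junction-candidate description from a clipped read: the read is
## oriented so its aligned block comes first (side A) and the clip last
.read_junction_candidate <- function(row, side, index, refset, min_clip) {
  if (side == "right") {
    J <- substr(row$seq, row$qstart, row$read_len)
    clip_len <- row$read_len - row$qend
    a0 <- row$pos; da <- +1L; strand_a <- "+"
  } else {
    ro <- .revcomp(row$seq)
    J <- substr(ro, row$read_len - row$qend + 1L, row$read_len)
    clip_len <- row$qstart - 1L
    a0 <- row$end; da <- -1L; strand_a <- "-"
  }
  lenJ <- nchar(J)
  if (clip_len < min_clip) return(NULL)
  ref_a_seq <- index$refs[[row$ref]]
  ## A-side prefix walk along the fused strand
  refwin_a <- if (da > 0L)
    substr(ref_a_seq, a0, min(nchar(ref_a_seq), a0 + lenJ - 1L))
  else
    .revcomp(substr(ref_a_seq, max(1L, a0 - lenJ + 1L), a0))
  p <- .common_prefix_len(J, refwin_a)
  if (p < 1L) return(NULL)
  ## B-side anchor: junction-distal end of the clip
  ka <- min(20L, clip_len)
  anchor <- substr(J, lenJ - ka + 1L, lenJ)
  hits <- .find_exact_hits(index, anchor)
  ## highly repetitive anchors (e.g. telomere repeat arrays) cannot place
  ## the partner uniquely
  if (nrow(hits) == 0L || nrow(hits) > 50L) return(NULL)
  hits <- hits[order(hits$ref, hits$start, hits$strand), , drop = FALSE]
  best <- NULL; n_best <- 0L
  for (h in seq_len(nrow(hits))) {
    ref_b <- hits$ref[h]
    seq_b <- index$refs[[ref_b]]
    if (hits$strand[h] == "+") {
      h_end_ref <- hits$start[h] + ka - 1L
      refwin_b <- substr(seq_b, max(1L, h_end_ref - lenJ + 1L), h_end_ref)
    } else {
      g_start <- hits$start[h]
      refwin_b <- .revcomp(substr(seq_b, g_start,
                                  min(nchar(seq_b), g_start + lenJ - 1L)))
    }
    s <- .common_suffix_len(J, refwin_b)
    if (is.null(best) || s > best$s) {
      best <- list(h = h, s = s); n_best <- 1L
    } else if (s == best$s) {
      n_best <- n_best + 1L
    }
  }
  ## tied best placements (e.g. clips wholly within telomere repeat arrays)
  ## cannot place the partner breakpoint uniquely
  if (n_best > 1L) return(NULL)
  s <- best$s
  h <- best$h
  if (s < ka || s >= lenJ) return(NULL)
  ref_b <- hits$ref[h]
  strand_b <- hits$strand[h]
  if (p + s >= lenJ) {
    j0 <- lenJ - s
    ins <- ""
    bp_a <- a0 + da * (j0 - 1L)
    first_b <- j0 + 1L
  } else {
    ins <- substr(J, p + 1L, lenJ - s)
    if (nchar(ins) >= 50L) return(NULL)  # complex event; junction not called
    bp_a <- a0 + da * (p - 1L)
    first_b <- lenJ - s + 1L
  }
  t_anchor <- lenJ - ka + 1L
  bp_b <- if (strand_b == "+") hits$start[h] + (first_b - t_anchor)
          else (hits$start[h] + ka - 1L) - (first_b - t_anchor)
  j <- list(ref_a = row$ref, bp_a = as.integer(bp_a), strand_a = strand_a,
            ref_b = ref_b, bp_b = as.integer(bp_b), strand_b = strand_b,
            ins = ins)
  j <- .canonical_junction(j, refset)
  j <- .left_align_junction(j, index$refs)
  j$s_support <- s
  split_at <- if (nzchar(ins)) p else lenJ - s
  jseq <- substr(J, max(1L, split_at - 59L),
                 min(lenJ, split_at + nchar(ins) + 60L))
  ## junction_seq follows the canonical fused-strand orientation
  flipped <- !identical(j$ref_a, row$ref) || j$strand_a != strand_a ||
    (identical(j$ref_a, j$ref_b) && strand_a == "-")
  if (!identical(j$ref_a, row$ref) || j$strand_a != strand_a)
    jseq <- .revcomp(jseq)
  j$junction_seq <- jseq
  j
}

#' Resolve a fusion junction at base-pair resolution
#'
#' Uses soft-clipped supporting reads: the aligned block fixes one side of
#' the junction, the clipped segment is placed on the partner reference by
#' exact anchor matching, and the exact extent of agreement with both
#' references determines the breakpoints, microhomology and any insertion.
#' Per-read candidates are canonicalized (subtelomeric side first; for
#' head-to-head junctions the telomeric breakpoint first), left-aligned
#' within any microhomology tract, and combined by majority vote with ties
#' broken toward the smaller (left-aligned) coordinate.
#'
#' @param event One event row from [cluster_linkages()].
#' @param alignments Alignment table.
#' @param refset A `reference_set`.
#' @param index Optional prebuilt `alignment_index`.
#' @param min_clip Minimum soft-clip length supporting a junction (default 10).
#' @param max_support Clipped reads examined per event (default 12).
#' @param min_votes Minimum number of clipped reads agreeing on the same
#'   junction description (default 2); singleton descriptions are too easily
#'   produced by clips that barely cross the junction.
#' @return A list of class `fusion_junction` (breakpoints, strands,
#'   `microhomology`, `insertion_seq`, `junction_seq`, `n_votes`), or `NULL`
#'   when no soft-clipped support resolves the junction.
#' @export
resolve_breakpoints <- function(event, alignments, refset, index = NULL,
                                min_clip = 10L, max_support = 12L,
                                min_votes = 2L) {
  if (is.null(index)) index <- build_alignment_index(refset)
  rows <- alignments[alignments$qname %in% event$qnames[[1]], , drop = FALSE]
  ## junction votes require uniquely anchored reads; multi-mapping blocks
  ## (MAPQ 0, e.g. within telomere repeats) cannot fix side A
  rows <- rows[rows$mapq >= 1L, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  clips <- .parse_clips(rows$cigar)
  cand_rows <- which(clips$left >= min_clip | clips$right >= min_clip)
  ## longest clips carry the most junction information
  cand_rows <- cand_rows[order(-pmax(clips$left[cand_rows],
                                     clips$right[cand_rows]))]
  cand_rows <- utils::head(cand_rows, max_support)
  cands <- list()
  for (i in cand_rows) {
    row <- rows[i, ]
    for (side in c("left", "right")) {
      if (clips[[side]][i] < min_clip) next
      cj <- .read_junction_candidate(row, side, index, refset, min_clip)
      if (!is.null(cj)) cands[[length(cands) + 1L]] <- cj
    }
  }
  if (!length(cands)) return(NULL)
  keys <- vapply(cands, function(j)
    paste(j$ref_a, j$bp_a, j$strand_a, j$ref_b, j$bp_b, j$strand_b, j$ins,
          sep = "|"), character(1))
  ## a junction description is trustworthy only when at least one vote
  ## placed the partner side across a full-length anchor: very short clips
  ## can match decoy loci exactly and vote consistently for them
  s_max <- vapply(cands, function(j) j$s_support, numeric(1))
  solid <- vapply(split(s_max, keys), max, numeric(1))
  keys_ok <- names(solid)[solid >= 20]
  keep <- keys %in% keys_ok
  if (!any(keep)) return(NULL)
  cands <- cands[keep]; keys <- keys[keep]
  tab <- table(keys)
  if (max(tab) < min_votes) return(NULL)
  top <- names(tab)[tab == max(tab)]
  ## ties toward the left-aligned (smallest) coordinates
  if (length(top) > 1L) {
    ord <- order(vapply(top, function(kk) {
      f <- strsplit(kk, "|", fixed = TRUE)[[1]]
      as.integer(f[2]) * 1e6 + as.integer(f[5])
    }, numeric(1)))
    top <- top[ord]
  }
  pick <- cands[[which(keys == top[1])[1]]]
  h <- junction_homology(index$refs[[pick$ref_a]], pick$bp_a, pick$strand_a,
                         index$refs[[pick$ref_b]], pick$bp_b, pick$strand_b)
  structure(list(event_id = event$event_id, link_class = event$link_class,
                 ref_a = pick$ref_a, bp_a = pick$bp_a, strand_a = pick$strand_a,
                 ref_b = pick$ref_b, bp_b = pick$bp_b, strand_b = pick$strand_b,
                 microhomology = if (nzchar(pick$ins)) 0L else h$microhomology,
                 insertion_seq = pick$ins,
                 junction_seq = pick$junction_seq,
                 n_votes = as.integer(max(tab))),
            class = "fusion_junction")
}

#' Annotate events with resolved junctions and mutational features
#'
#' Runs [resolve_breakpoints()] on every event and scores each resolved
#' junction: insertion classification (templated/untemplated), per-side
#' resection from the landmark, telomere-repeat flags and nuclease footprint
#' proximity.
#'
#' @param events Event table from [cluster_linkages()].
#' @param alignments Alignment table.
#' @param refset A `reference_set`.
#' @param index Optional prebuilt `alignment_index`.
#' @param search_window Template search half-width (bp) around each
#'   breakpoint for insertion classification.
#' @param footprint_window Cut-site proximity half-width in bp (default 25).
#' @param ... Passed to [resolve_breakpoints()].
#' @return data.frame with one row per event (unresolved events carry NA
#'   breakpoints and `resolved = FALSE`).
#' @export
annotate_junctions <- function(events, alignments, refset, index = NULL,
                               search_window = 1000L, footprint_window = 25L,
                               ...) {
  if (is.null(index)) index <- build_alignment_index(refset)
  refs <- index$refs
  side_stats <- function(ref_name, bp) {
    if (!is.na(bp) && is_subtelomere(refset, ref_name)) {
      ref <- refset$subtelomeres[[ref_name]]
      rs <- compute_resection(bp, ref)
      fp <- if (!is.na(ref$cut_site))
        talen_footprint(bp, ref, footprint_window) else NA
      list(resection = rs$resection, telomeric = rs$telomeric,
           within_telomere = rs$within_telomere, footprint = fp)
    } else {
      list(resection = NA_integer_, telomeric = NA, within_telomere = NA,
           footprint = NA)
    }
  }
  out <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    jn <- resolve_breakpoints(ev, alignments, refset, index = index, ...)
    if (is.null(jn)) {
      return(data.frame(
        event_id = ev$event_id, link_class = ev$link_class, resolved = FALSE,
        ref_a = ev$ref_a, bp_a = NA_integer_, strand_a = NA_character_,
        ref_b = ev$ref_b, bp_b = NA_integer_, strand_b = NA_character_,
        microhomology = NA_integer_, insertion_seq = NA_character_,
        insertion_class = NA_character_, template_ref = NA_character_,
        template_pos = NA_integer_, junction_seq = NA_character_,
        n_votes = 0L, n_support = ev$n_support,
        resection_a = NA_integer_, telomeric_a = NA, within_telomere_a = NA,
        footprint_a = NA, resection_b = NA_integer_, telomeric_b = NA,
        within_telomere_b = NA, footprint_b = NA, stringsAsFactors = FALSE))
    }
    ins_class <- "none"; tmpl_ref <- NA_character_; tmpl_pos <- NA_integer_
    if (nzchar(jn$insertion_seq)) {
      sides <- data.frame(ref = c(jn$ref_a, jn$ref_b),
                          bp = c(jn$bp_a, jn$bp_b), stringsAsFactors = FALSE)
      cl <- classify_insertion(jn$insertion_seq, sides, refs,
                               search_window = search_window)
      ins_class <- cl$ins_class
      if (ins_class == "templated") {
        tmpl_ref <- cl$template_ref; tmpl_pos <- cl$template_pos
      }
    }
    sa <- side_stats(jn$ref_a, jn$bp_a)
    sb <- side_stats(jn$ref_b, jn$bp_b)
    data.frame(
      event_id = ev$event_id, link_class = ev$link_class, resolved = TRUE,
      ref_a = jn$ref_a, bp_a = jn$bp_a, strand_a = jn$strand_a,
      ref_b = jn$ref_b, bp_b = jn$bp_b, strand_b = jn$strand_b,
      microhomology = jn$microhomology, insertion_seq = jn$insertion_seq,
      insertion_class = ins_class, template_ref = tmpl_ref,
      template_pos = tmpl_pos, junction_seq = jn$junction_seq,
      n_votes = jn$n_votes, n_support = ev$n_support,
      resection_a = sa$resection, telomeric_a = sa$telomeric,
      within_telomere_a = sa$within_telomere, footprint_a = sa$footprint,
      resection_b = sb$resection, telomeric_b = sb$telomeric,
      within_telomere_b = sb$within_telomere, footprint_b = sb$footprint,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
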