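#' @importFrom methods is
#' @importFrom stats rnorm runif setNames sd var
#' @importFrom utils read.delim write.table head tail
NULL

TELOMERE_UNIT <- "TTAGGG"

## default decoy telomere-variant repeat units; configurable everywhere they
## are used -- the set only shapes decoy sequence context
DEFAULT_VARIANT_UNITS <- c("TTAGGG", "TGAGGG", "TCAGGG", "TTGGGG")

.valid_dna <- function(x) grepl("^[ACGTN]*$", x)

.revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

.comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Construct a subtelomeric reference with landmark coordinates
#'
#' A subtelomeric reference is one sequence oriented from the fusion
#' amplification primer towards the telomere: subtelomeric DNA first, then the
#' telomere repeat array.  Three landmarks anchor all downstream coordinate
#' arithmetic: the primer 5' end (`primer_pos`, conventionally 1), the first
#' base of the telomere repeat array (`telomere_start`), and optionally the
#' position of the base immediately 5' of a nuclease-cleaved phosphodiester
#' bond (`cut_site`).  All coordinates are 1-based inclusive.
#'
#' @param name Reference identifier.
#' @param sequence DNA string (A/C/G/T/N), primer-to-telomere orientation.
#' @param primer_pos 1-based coordinate of the primer 5' end (default 1).
#' @param telomere_start 1-based coordinate of the first telomere-repeat base.
#'   If `NULL`, located with [locate_telomere_repeat_start()].
#' @param cut_site Optional 1-based coordinate of the double-strand-break
#'   position; must lie strictly between `primer_pos` and `telomere_start`.
#' @param family Optional group label for homologous reference families.
#' @return An object of class `subtelomere_reference`.
#' @export
subtelomere_reference <- function(name, sequence, primer_pos = 1L,
                                  telomere_start = NULL, cut_site = NULL,
                                  family = NA_character_) {
  stopifnot(is.character(name), nchar(name) > 0)
  sequence <- toupper(as.character(sequence))
  if (!.valid_dna(sequence) || nchar(sequence) == 0)
    stop("sequence must be a non-empty string over {A,C,G,T,N}")
  if (is.null(telomere_start)) {
    telomere_start <- locate_telomere_repeat_start(sequence, min_units = 1L)
    if (is.na(telomere_start))
      stop("no telomere repeat array found and telomere_start not given")
  }
  primer_pos <- as.integer(primer_pos)
  telomere_start <- as.integer(telomere_start)
  if (!(1L <= primer_pos && primer_pos < telomere_start &&
        telomere_start <= nchar(sequence)))
    stop("require 1 <= primer_pos < telomere_start <= length(sequence)")
  if (substr(sequence, telomere_start, telomere_start + 5L) != TELOMERE_UNIT)
    stop("telomere_start..end must begin with at least one full TTAGGG unit")
  if (!is.null(cut_site) && !is.na(cut_site)) {
    cut_site <- as.integer(cut_site)
    if (!(primer_pos < cut_site && cut_site < telomere_start))
      stop("cut_site must lie strictly between primer_pos and telomere_start")
  } else {
    cut_site <- NA_integer_
  }
  structure(list(name = name, sequence = sequence, primer_pos = primer_pos,
                 telomere_start = telomere_start, cut_site = cut_site,
                 family = family),
            class = "subtelomere_reference")
}

#' @export
print.subtelomere_reference <- function(x, ...) {
  cat(sprintf("<subtelomere_reference> %s: %d bp, primer %d, telomere_start %d, cut_site %s%s\n",
              x$name, nchar(x$sequence), x$primer_pos, x$telomere_start,
              ifelse(is.na(x$cut_site), "unset", x$cut_site),
              ifelse(is.na(x$family), "", paste0(", family ", x$family))))
  invisible(x)
}

#' Locate the start of the telomere repeat array
#'
#' Returns the smallest 1-based position `i` such that the sequence from `i`
#' begins with at least `min_units` consecutive TTAGGG units, or `NA_integer_`
#' when no such position exists.
#'
#' @param sequence DNA string.
#' @param min_units Minimum number of consecutive repeat units (>= 1).
#' @param unit Repeat unit (default TTAGGG).
#' @return 1-based coordinate or `NA_integer_`.
#' @export
locate_telomere_repeat_start <- function(sequence, min_units = 3L,
                                         unit = TELOMERE_UNIT) {
  stopifnot(min_units >= 1L)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0) stop("empty sequence")
  pat <- strrep(unit, min_units)
  hit <- regexpr(pat, sequence, fixed = TRUE)
  if (hit[1] == -1L) NA_integer_ else as.integer(hit[1])
}

#' Assemble a validated reference set
#'
#' A reference set bundles the subtelomeric references against which fusion
#' amplicon reads are aligned with optional decoy genomic contigs (partner
#' space for inter-chromosomal fusions) and a list of telomere-variant repeat
#' hexamers used as decoy context by the sequence generators.
#'
#' @param subtelomeres List of [subtelomere_reference()] objects.
#' @param genomic_contigs Named character vector of contig DNA strings.
#' @param variant_repeat_units Character vector of hexamer repeat units.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(subtelomeres, genomic_contigs = character(),
                          variant_repeat_units = DEFAULT_VARIANT_UNITS) {
  stopifnot(length(subtelomeres) >= 1)
  if (!all(vapply(subtelomeres, inherits, logical(1), "subtelomere_reference")))
    stop("subtelomeres must be subtelomere_reference objects")
  sub_names <- vapply(subtelomeres, `[[`, character(1), "name")
  contig_names <- names(genomic_contigs)
  if (length(genomic_contigs)) {
    if (is.null(contig_names) || any(contig_names == ""))
      stop("genomic_contigs must be a named character vector")
    genomic_contigs <- setNames(toupper(as.character(genomic_contigs)),
                                contig_names)
    if (!all(.valid_dna(genomic_contigs)))
      stop("genomic contigs contain non-DNA characters")
  }
  all_names <- c(sub_names, contig_names)
  if (anyDuplicated(all_names))
    stop("duplicate reference names: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  if (length(variant_repeat_units) &&
      any(nchar(variant_repeat_units) != 6L))
    stop("variant_repeat_units must be hexamers")
  names(subtelomeres) <- sub_names
  structure(list(subtelomeres = subtelomeres,
                 genomic_contigs = genomic_contigs,
                 variant_repeat_units = variant_repeat_units),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d subtelomere(s), %d genomic contig(s)\n",
              length(x$subtelomeres), length(x$genomic_contigs)))
  invisible(x)
}

#' Build a reference set from a configuration list
#'
#' The configuration mirrors the on-disk metadata layout: a list of
#' subtelomere descriptions (each with a `sequence` or generation parameters
#' understood by [synth_subtelomere()]), optional `genomic_contigs`, and an
#' optional `variant_repeat_units` vector.
#'
#' @param config List with elements `subtelomeres` (list of lists),
#'   `genomic_contigs` (named character, optional) and `variant_repeat_units`
#'   (optional).
#' @return A `reference_set`.
#' @export
build_reference_set <- function(config) {
  stopifnot(is.list(config), length(config$subtelomeres) >= 1)
  subs <- lapply(config$subtelomeres, function(sc) {
    if (is.null(sc$sequence)) {
      gen <- do.call(synth_subtelomere, sc[setdiff(names(sc), "name")])
      sc$sequence <- gen$sequence
      sc$telomere_start <- gen$telomere_start
      if (is.null(sc$cut_site)) sc$cut_site <- gen$cut_site
    }
    subtelomere_reference(
      name = sc$name, sequence = sc$sequence,
      primer_pos = if (is.null(sc$primer_pos)) 1L else sc$primer_pos,
      telomere_start = sc$telomere_start,
      cut_site = sc$cut_site,
      family = if (is.null(sc$family)) NA_character_ else sc$family)
  })
  reference_set(
    subtelomeres = subs,
    genomic_contigs = if (is.null(config$genomic_contigs)) character()
                      else config$genomic_contigs,
    variant_repeat_units = if (is.null(config$variant_repeat_units))
      DEFAULT_VARIANT_UNITS else config$variant_repeat_units)
}

.random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic subtelomeric sequence
#'
#' Emits a random subtelomeric segment followed by a pure telomere repeat
#' array, with the cleavage site placed `cut_offset` bases centromeric of the
#' repeat start (the geometry of a subtelomere-targeted nuclease).  Uses the
#' session RNG; seed upstream for reproducibility.
#'
#' @param telomere_start 1-based coordinate of the first repeat base
#'   (default 3038, i.e. a 3037-bp subtelomeric segment).
#' @param n_units Number of TTAGGG units appended (default 50).
#' @param cut_offset Distance (bp) from the cut site to `telomere_start`
#'   (default 14); `NA` for no cut site.
#' @param gc GC fraction of the random subtelomeric segment.
#' @return List with `sequence`, `telomere_start`, `cut_site`.
#' @export
synth_subtelomere <- function(telomere_start = 3038L, n_units = 50L,
                              cut_offset = 14L, gc = 0.5) {
  stopifnot(telomere_start >= 3L, n_units >= 1L)
  sub <- .random_dna(telomere_start - 1L, gc = gc)
  seq <- paste0(sub, strrep(TELOMERE_UNIT, n_units))
  cut <- if (is.na(cut_offset)) NA_integer_
         else as.integer(telomere_start - cut_offset)
  list(sequence = seq, telomere_start = as.integer(telomere_start),
       cut_site = cut)
}

#' Generate a synthetic reference set
#'
#' Builds `n_subtel` independent synthetic subtelomeric references (all with
#' the same landmark geometry) plus `n_contigs` random genomic contigs, the
#' partner space for simulated inter-chromosomal fusions.
#'
#' @param n_subtel Number of subtelomeric references.
#' @param n_contigs Number of genomic contigs.
#' @param contig_length Length of each contig (bp).
#' @param seed Optional RNG seed.
#' @param ... Passed to [synth_subtelomere()].
#' @return A `reference_set`.
#' @export
synth_reference_set <- function(n_subtel = 1L, n_contigs = 2L,
                                contig_length = 100000L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  subs <- lapply(seq_len(n_subtel), function(i) {
    g <- synth_subtelomere(...)
    subtelomere_reference(name = sprintf("subtel%03d", i),
                          sequence = g$sequence,
                          telomere_start = g$telomere_start,
                          cut_site = g$cut_site)
  })
  contigs <- character()
  if (n_contigs > 0) {
    contigs <- setNames(
      vapply(seq_len(n_contigs), function(i) .random_dna(contig_length),
             character(1)),
      sprintf("contig%02d", seq_len(n_contigs)))
  }
  reference_set(subs, genomic_contigs = contigs)
}

#' Generate a family of homologous subtelomeric references
#'
#' Seeds one template subtelomere and derives `n` family members by random
#' substitution at rate `1 - identity`, sharing a family label.  Emulates a
#' family of closely related telomeric ends captured by a single primer.
#'
#' @param n Number of members.
#' @param identity Target pairwise identity between members (0..1); each
#'   member is mutated at half the divergence rate so that member-to-member
#'   identity, not member-to-template identity, matches the target.
#' @param family Family label.
#' @param ... Passed to [synth_subtelomere()].
#' @return List of `subtelomere_reference` objects.
#' @export
synth_subtelomere_family <- function(n = 3L, identity = 0.99,
                                     family = "famA", ...) {
  g <- synth_subtelomere(...)
  template <- g$sequence
  sub_len <- g$telomere_start - 1L
  lapply(seq_len(n), function(i) {
    seqc <- strsplit(template, "")[[1]]
    ## mutate the subtelomeric segment only; repeats stay canonical
    n_mut <- round((1 - identity) / 2 * sub_len)
    if (n_mut > 0) {
      at <- sample.int(sub_len, n_mut)
      seqc[at] <- vapply(seqc[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    subtelomere_reference(name = sprintf("%s_m%d", family, i),
                          sequence = paste(seqc, collapse = ""),
                          telomere_start = g$telomere_start,
                          cut_site = g$cut_site, family = family)
  })
}

#' All reference sequences of a set as a named character vector
#' @param refset A `reference_set`.
#' @return Named character vector (subtelomeres first, then contigs).
#' @export
ref_sequences <- function(refset) {
  stopifnot(inherits(refset, "reference_set"))
  subs <- vapply(refset$subtelomeres, `[[`, character(1), "sequence")
  c(subs, refset$genomic_contigs)
}

#' Is a reference name a subtelomeric reference?
#' @param refset A `reference_set`.
#' @param name Reference name(s).
#' @return Logical vector.
#' @export
is_subtelomere <- function(refset, name) {
  name %in% names(refset$subtelomeres)
}

#' Landmark coordinate used for resection arithmetic
#'
#' The cut site when set, otherwise the telomere-repeat start.
#' @param ref A `subtelomere_reference`.
#' @return 1-based coordinate.
#' @export
ref_landmark <- function(ref) {
  stopifnot(inherits(ref, "subtelomere_reference"))
  if (!is.na(ref$cut_site)) ref$cut_site else ref$telomere_start
}

#' Write a reference set to FASTA plus a metadata sidecar
#'
#' The FASTA holds every sequence (subtelomeres and contigs) for an external
#' aligner; the TSV sidecar records the landmark coordinates
#' (name, primer_pos, telomere_start, cut_site, family).
#'
#' @param refset A `reference_set`.
#' @param fasta,metadata Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_set <- function(refset, fasta, metadata) {
  stopifnot(inherits(refset, "reference_set"))
  seqs <- Biostrings::DNAStringSet(ref_sequences(refset))
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- data.frame(
    name = vapply(refset$subtelomeres, `[[`, character(1), "name"),
    primer_pos = vapply(refset$subtelomeres, `[[`, integer(1), "primer_pos"),
    telomere_start = vapply(refset$subtelomeres, `[[`, integer(1),
                            "telomere_start"),
    cut_site = vapply(refset$subtelomeres, `[[`, integer(1), "cut_site"),
    family = vapply(refset$subtelomeres, `[[`, character(1), "family"),
    stringsAsFactors = FALSE)
  attr_units <- paste(refset$variant_repeat_units, collapse = ",")
  con <- file(metadata, "w")
  on.exit(close(con))
  writeLines(sprintf("#variant_repeat_units=%s", attr_units), con)
  suppressWarnings(write.table(meta, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(c(fasta = fasta, metadata = metadata))
}

#' Re-load a reference set written by [write_reference_set()]
#' @param fasta,metadata Paths written by [write_reference_set()].
#' @return A `reference_set` identical to the one written.
#' @export
read_reference_set <- function(fasta, metadata) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  lines <- readLines(metadata)
  units <- DEFAULT_VARIANT_UNITS
  hdr <- grep("^#variant_repeat_units=", lines, value = TRUE)
  if (length(hdr)) {
    u <- sub("^#variant_repeat_units=", "", hdr[1])
    units <- if (nzchar(u)) strsplit(u, ",")[[1]] else character()
  }
  meta <- read.delim(text = lines[!startsWith(lines, "#")],
                     stringsAsFactors = FALSE)
  seqv <- setNames(as.character(seqs), names(seqs))
  subs <- lapply(seq_len(nrow(meta)), function(i) {
    subtelomere_reference(
      name = meta$name[i], sequence = seqv[[meta$name[i]]],
      primer_pos = meta$primer_pos[i],
      telomere_start = meta$telomere_start[i],
      cut_site = if (is.na(meta$cut_site[i])) NULL else meta$cut_site[i],
      family = as.character(meta$family[i]))
  })
  contigs <- seqv[setdiff(names(seqv), meta$name)]
  reference_set(subs, genomic_contigs = contigs, variant_repeat_units = units)
}
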