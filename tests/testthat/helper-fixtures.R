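# Shared fixtures built in code; everything is seeded.

# small single-subtelomere reference set with the canonical landmark
# geometry (telomere_start 3038, cut_site 3024) plus two genomic contigs
small_refset <- function(seed = 101, n_contigs = 2, contig_length = 20000) {
  synth_reference_set(n_subtel = 1, n_contigs = n_contigs,
                      contig_length = contig_length, seed = seed)
}

# reference set sized for round-trip recovery: one subtelomere per molecule
recovery_refset <- function(n_molecules, seed = 99, n_contigs = 4,
                            contig_length = 60000) {
  synth_reference_set(n_subtel = n_molecules, n_contigs = n_contigs,
                      contig_length = contig_length, seed = seed)
}

# plant an exact microhomology tract of length m at breakpoints (b1, b2) of
# a subtelomere sequence: the m bases after b1 become the reverse complement
# of the m bases ending at b2, with the flanking bases forced to break any
# longer overlap.  Returns the modified reference_set.
plant_microhomology <- function(refset, m, b1, b2) {
  ref <- refset$subtelomeres[[1]]
  ch <- strsplit(ref$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (m > 0) {
    tract <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    ch[(b1 + 1):(b1 + m)] <- tract
    ch[(b2 - m + 1):b2] <- rev(unname(comp[tract]))
  }
  # break extension on both sides of the tract
  block <- function(i, forbidden) {
    ch[i] <<- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1)
  }
  block(b1 + m + 1, comp[ch[b2 - m]])       # k_right stops at m
  block(b1, comp[ch[b2 + 1]])               # k_left = 0
  refset$subtelomeres[[1]] <- subtelomere_reference(
    name = ref$name, sequence = paste(ch, collapse = ""),
    primer_pos = ref$primer_pos, telomere_start = ref$telomere_start,
    cut_site = ref$cut_site, family = ref$family)
  refset
}

# fused-strand flanks for a head-to-head intra junction at (b1, b2), aligned
# to a junction window of ctx bases each side
intra_flanks <- function(S, b1, b2, ctx = 60) {
  revcomp <- function(x)
    rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
  list(
    junction = paste0(substr(S, b1 - ctx + 1, b1),
                      revcomp(substr(S, b2 - ctx + 1, b2))),
    flank_a = substr(S, b1 - ctx + 1, b1 + ctx),
    flank_b = revcomp(substr(S, b2 - ctx + 1, b2 + ctx)))
}

# one-row mate description for classify_pair()
mate <- function(ref, pos, end, strand, mapq = 60) {
  list(ref = ref, pos = pos, end = end, strand = strand, mapq = mapq)
}

# minimal linkage row for clustering tests
linkage_row <- function(qname, class, ref_a, mid_a, ref_b, mid_b,
                        mapq = 60) {
  data.frame(qname = qname, link_class = class,
             ref_a = ref_a, pos_a = mid_a - 50, end_a = mid_a + 49,
             strand_a = "+", mapq_a = mapq,
             ref_b = ref_b, pos_b = mid_b - 50, end_b = mid_b + 49,
             strand_b = "+", mapq_b = mapq,
             mid_a = mid_a, mid_b = mid_b, stringsAsFactors = FALSE)
}
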