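# Small in-code fixtures shared across tests.

# Flanks verified free of GATA/AC runs and of full-motif junction copies.
FLANK_L <- "TTCGTCCGGAAGCTTGCAAGGTCCGTTCGGATCGTGGTCT"
FLANK_R <- "CGGTTAGCCTAGGCTTAGCGTTCGAATCGGCTTAGGCTAG"

# One-cluster toy locus: flankL(40) + (GATA)10 + flankR(40); SNVs at 4, 12
# (left flank) and 86 (right flank).
toy_locus <- function(name = "toy", ref_copies = 10L,
                      snv_positions = c(4L, 12L, 86L)) {
  locus_def(name, "GATA", snv_positions = snv_positions, min_repeats = 3L,
            reference = paste0(FLANK_L, strrep("GATA", ref_copies), FLANK_R))
}

toy_allele_seq <- function(copies, profile = NULL, locus = toy_locus())
  build_allele_sequence(locus, copies, profile)

# Minimal cohort builder: `calls` is a list of lists
# list(pop, L1 = c(a,b), L2 = c(a,b), ...)
make_cohort <- function(calls) {
  rows <- lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    row <- list(individual_id = sprintf("i%03d", i),
                population = cl$pop %||% "P1")
    for (loc in setdiff(names(cl), "pop")) {
      row[[paste0(loc, "_a1")]] <- cl[[loc]][1]
      row[[paste0(loc, "_a2")]] <- cl[[loc]][2]
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic allele records without sequences (for genotype-level tests):
# spec entries are list(locus, label, profile, motifs, copies)
make_allele_set <- function(specs) {
  recs <- list()
  for (s in specs) {
    recs[[paste(s$locus, s$label, sep = "|")]] <- structure(
      list(locus = s$locus, label = s$label, species = "test", seq = NULL,
           clusters = data.frame(motif = s$motifs,
                                 copies = as.integer(s$copies),
                                 offset = seq_along(s$motifs),
                                 stringsAsFactors = FALSE),
           snv_profile = s$profile,
           signature = paste(sprintf("%s:%d", s$motifs, s$copies),
                             collapse = "+"),
           origin = "unassigned"),
      class = "allele_record")
  }
  structure(recs, class = "allele_set")
}
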