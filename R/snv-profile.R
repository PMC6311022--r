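#' Extract the flanking SNV profile of an allele sequence
#'
#' Repeat clusters are hard-masked (removed) from both the allele and the
#' locus reference before alignment, so differences in repeat copy number can
#' never shift flank coordinates. The masked sequences are aligned with an
#' end-gap-free global alignment and the base aligned to each configured SNV
#' position of the reference is read off; a position deleted in the allele
#' yields the gap state \code{"-"}, which is a legal profile state.
#'
#' @param seq allele sequence (uppercase A/C/G/T, N allowed).
#' @param locus a \code{\link{locus_def}} with \code{snv_positions} set.
#' @param reference reference sequence; defaults to \code{locus$reference}.
#' @param min_identity minimum percent identity of the flank alignment
#'   (default 70); below it the allele is reported unalignable.
#' @return profile string over \code{A/C/G/T/-}, one character per SNV
#'   position.
#' @export
extract_snv_profile <- function(seq, locus, reference = locus$reference,
                                min_identity = 70) {
  if (is.null(reference)) stopf("locus %s has no reference sequence", locus$name)
  if (!length(locus$snv_positions)) return("")
  mref <- mask_clusters(reference, locus)
  mseq <- mask_clusters(seq, locus)
  # map each reference SNV coordinate into masked-reference coordinates
  pos1 <- locus$snv_positions + 1L # 1-based
  inside <- mref$in_cluster[pos1]
  if (any(inside))
    stopf("locus %s: snv_position(s) %s fall inside a reference repeat cluster",
          locus$name,
          paste(locus$snv_positions[inside], collapse = ","))
  mpos <- pos1 - mref$removed_before[pos1]
  al <- Biostrings::pairwiseAlignment(mseq$masked, mref$masked,
                                      type = "overlap")
  identity <- suppressWarnings(Biostrings::pid(al))
  if (!is.finite(identity) || identity < min_identity)
    stopf("locus %s: allele flanks unalignable to reference (%.1f%% identity < %g%%)",
          locus$name, if (is.finite(identity)) identity else 0, min_identity)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  # the aligned subject is clipped to the aligned region; walking its non-gap
  # characters (offset by the region start) recovers masked-ref coordinates
  ref_idx <- Biostrings::start(Biostrings::subject(al)) - 1L +
    cumsum(sub != "-")
  states <- vapply(mpos, function(p) {
    col <- which(ref_idx == p & sub != "-")
    if (!length(col)) return("-")
    ch <- pat[col[1]]
    if (ch %in% c("A", "C", "G", "T")) ch else "-"
  }, character(1))
  paste(states, collapse = "")
}

# Remove cluster spans from a sequence; returns the masked string plus
# per-position bookkeeping on the original coordinates.
mask_clusters <- function(seq, locus) {
  cl <- parse_repeat_structure(seq, locus)
  n <- nchar(seq)
  in_cluster <- rep(FALSE, n)
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      from <- cl$offset[i] + 1L
      to <- cl$offset[i] + nchar(cl$motif[i]) * cl$copies[i]
      in_cluster[from:to] <- TRUE
    }
  }
  chars <- strsplit(seq, "")[[1]]
  list(masked = paste(chars[!in_cluster], collapse = ""),
       in_cluster = in_cluster,
       removed_before = cumsum(in_cluster),
       clusters = cl)
}
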