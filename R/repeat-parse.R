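#' Canonical rotation class of a repeat motif
#'
#' Reduces a motif to its primitive unit (so \code{"ATAT"} becomes
#' \code{"AT"}) and returns the lexicographically smallest rotation, a
#' spelling-independent identifier of the motif's rotation class (all of
#' \code{"GATA"}, \code{"ATAG"}, \code{"TAGA"}, \code{"AGAT"} map to
#' \code{"AGAT"}). Used to recognize equivalent motif configurations;
#' cluster scanning and reporting keep the configured spelling, which for
#' published loci is the name of the cluster (e.g. \code{(GATA)n}).
#'
#' @param motif nucleotide string over A/C/G/T.
#' @return canonical rotation string.
#' @export
canonical_motif <- function(motif) {
  motif <- primitive_motif(motif)
  k <- nchar(motif)
  rots <- vapply(seq_len(k) - 1L, function(i)
    paste0(substr(motif, i + 1L, k), substr(motif, 1L, i)), character(1))
  min(rots)
}

# Primitive unit of a motif: "GAGA" -> "GA"; validates the alphabet.
primitive_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  if (grepl("[^ACGT]", motif)) stopf("motif must be over A/C/G/T: %s", motif)
  k <- nchar(motif)
  for (d in seq_len(k)) {
    if (k %% d == 0L) {
      unit <- substr(motif, 1L, d)
      if (strrep(unit, k / d) == motif) return(unit)
    }
  }
  motif
}

#' Decompose a sequence into microsatellite repeat clusters
#'
#' Scans for maximal tandem runs of each configured motif and reports runs
#' with at least \code{min_repeats} copies, left to right. Runs are anchored
#' on the configured motif spelling: a pure repeat region that is phase
#' shifted relative to it is counted from its first full copy (so
#' \code{"CCACACACACACA"} carries an \code{(AC)5} cluster, not a
#' \code{(CA)6} one). When runs of different motifs overlap, the longer run
#' (in nucleotides) is kept and the conflict is reported via
#' \code{message()}.
#'
#' @param seq nucleotide string, uppercase A/C/G/T (N allowed outside
#'   clusters).
#' @param locus a \code{\link{locus_def}} (its \code{motifs} and
#'   \code{min_repeats} are used).
#' @return data frame with columns \code{motif}, \code{copies} and
#'   \code{offset} (0-based start in \code{seq}), ordered by offset. Zero rows
#'   when no run qualifies.
#' @examples
#' loc <- locus_def("L", c("GATA", "AC"), min_repeats = 2)
#' parse_repeat_structure("TTGATAGATAGATAGATAGATACCACACACACACATT", loc)
#' @export
parse_repeat_structure <- function(seq, locus) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stopf("empty sequence")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stopf("invalid character '%s' at position %d (0-based %d)",
          substr(seq, bad, bad), bad, bad - 1L)
  rows <- list()
  for (m in locus$motifs) {
    k <- nchar(m)
    hits <- gregexpr(sprintf("(?:%s)+", m), seq)[[1]]
    if (hits[1] == -1L) next
    len <- attr(hits, "match.length")
    copies <- len %/% k
    keep <- copies >= locus$min_repeats
    if (!any(keep)) next
    rows[[m]] <- data.frame(motif = m, copies = copies[keep],
                            offset = hits[keep] - 1L,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(motif = character(), copies = integer(),
                      offset = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$offset), , drop = FALSE]
  # resolve overlaps between runs of different motifs: keep the longer span
  span <- nchar(out$motif) * out$copies
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (out$offset[i] < out$offset[prev] + span[prev]) {
      drop_i <- span[i] <= span[prev]
      message(sprintf(
        "overlapping runs of %s and %s at offsets %d/%d; keeping the longer",
        out$motif[prev], out$motif[i], out$offset[prev], out$offset[i]))
      if (drop_i) keep[i] <- FALSE else keep[prev] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$copies <- as.integer(out$copies)
  out$offset <- as.integer(out$offset)
  out
}

# Signature string for a cluster set, e.g. "GATA:10+AC:6".
cluster_signature <- function(clusters) {
  if (!nrow(clusters)) return("")
  paste(sprintf("%s:%d", clusters$motif, clusters$copies), collapse = "+")
}
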