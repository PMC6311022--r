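#' Decompose one allele sequence into an allele record
#'
#' @param seq nucleotide string.
#' @param locus a \code{\link{locus_def}}.
#' @param label allele name (opaque string, e.g. \code{"2"} or \code{"arm2"}).
#' @param species species tag carried in the input (informational; the
#'   inferred parental origin lives in \code{origin}).
#' @return object of class \code{allele_record}: list with \code{locus},
#'   \code{label}, \code{species}, \code{clusters} (data frame, sorted by
#'   offset), \code{snv_profile}, \code{signature} and \code{origin}
#'   (initially \code{"unassigned"}).
#' @export
allele_record <- function(seq, locus, label, species = NA_character_) {
  clusters <- parse_repeat_structure(seq, locus)
  profile <- if (length(locus$snv_positions) && !is.null(locus$reference))
    extract_snv_profile(seq, locus) else ""
  structure(
    list(locus = locus$name, label = as.character(label), species = species,
         seq = seq, clusters = clusters, snv_profile = profile,
         signature = cluster_signature(clusters), origin = "unassigned"),
    class = "allele_record"
  )
}

#' @export
print.allele_record <- function(x, ...) {
  cat(sprintf("<allele %s|%s> profile %s; clusters %s; origin %s\n",
              x$locus, x$label,
              if (nzchar(x$snv_profile)) x$snv_profile else "(none)",
              if (nzchar(x$signature)) x$signature else "(none)", x$origin))
  invisible(x)
}

#' Read allele sequences from FASTA into an allele set
#'
#' Headers follow the convention \code{>locus|species|allele_label}. Each
#' sequence is decomposed into repeat clusters and a flanking SNV profile
#' against the locus reference.
#'
#' @param path FASTA file.
#' @param loci a \code{locus_set} (from \code{\link{read_locus_config}}).
#' @return an \code{allele_set}: named list of \code{allele_record}s keyed
#'   \code{"locus|label"}, with the \code{locus_set} attached as attribute
#'   \code{"loci"}.
#' @export
read_alleles_fasta <- function(path, loci) {
  ss <- Biostrings::readDNAStringSet(path)
  recs <- list()
  for (i in seq_along(ss)) {
    parts <- strsplit(names(ss)[i], "|", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stopf("FASTA header '%s' is not 'locus|species|label'", names(ss)[i])
    loc <- parts[1]
    if (is.null(loci[[loc]]))
      stopf("FASTA references unknown locus '%s'", loc)
    rec <- allele_record(as.character(ss[[i]]), loci[[loc]],
                         label = parts[3], species = parts[2])
    recs[[allele_key(loc, parts[3])]] <- rec
  }
  structure(recs, class = "allele_set", loci = loci)
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("<allele set> %d alleles across %d loci\n", length(x),
              length(unique(vapply(x, `[[`, character(1), "locus")))))
  invisible(x)
}

#' Assign parental-species origins to alleles
#'
#' Each allele is matched against the parental catalog of its locus. The
#' unique species whose cataloged SNV profile equals the allele's profile is
#' assigned; when both species carry the profile, the repeat-cluster
#' signature (e.g. \code{"AC:5"} vs \code{"AC:6"}) breaks the tie -- a
#' signature entry matches when every cataloged \code{motif:copies} term
#' occurs among the allele's clusters. An allele matching no entry keeps
#' origin \code{"unassigned"}; an allele still ambiguous after both criteria
#' is an error.
#'
#' @param alleles an \code{allele_set} or a single \code{allele_record}.
#' @param catalog a \code{\link{parental_catalog}}.
#' @return the input with \code{origin} fields filled in.
#' @export
assign_parental_origin <- function(alleles, catalog) {
  single <- inherits(alleles, "allele_record")
  set <- if (single) list(alleles) else alleles
  out <- lapply(set, function(rec) {
    e <- catalog$entries[catalog$entries$locus == rec$locus, , drop = FALSE]
    if (!nrow(e)) stopf("catalog has no entries for locus %s", rec$locus)
    hit <- e[e$profile == rec$snv_profile, , drop = FALSE]
    if (nrow(hit) && length(unique(hit$species)) > 1L) {
      sig_ok <- vapply(hit$cluster_signature, function(s)
        !is.na(s) && signature_matches(s, rec$clusters), logical(1))
      hit <- hit[sig_ok, , drop = FALSE]
    }
    sp <- unique(hit$species)
    if (length(sp) > 1L)
      stopf("allele %s|%s matches multiple parental species: %s",
            rec$locus, rec$label, paste(sp, collapse = ", "))
    rec$origin <- if (length(sp) == 1L) sp else "unassigned"
    rec
  })
  if (single) return(out[[1]])
  attributes(out) <- attributes(alleles)
  out
}

# TRUE when every "motif:copies" term of the signature string occurs among
# the allele's clusters.
signature_matches <- function(signature, clusters) {
  terms <- strsplit(signature, "+", fixed = TRUE)[[1]]
  all(vapply(terms, function(t) {
    mc <- strsplit(t, ":", fixed = TRUE)[[1]]
    any(clusters$motif == mc[1] & clusters$copies == as.integer(mc[2]))
  }, logical(1)))
}

#' Construct an allele sequence from a locus reference
#'
#' Rebuilds the reference sequence with each repeat cluster's copy number
#' replaced and with SNV profile states planted at the configured flank
#' positions. This is the inverse of
#' \code{\link{parse_repeat_structure}} + \code{\link{extract_snv_profile}}
#' and is used by the fixture builder and the simulator.
#'
#' @param locus a \code{\link{locus_def}} with a reference.
#' @param copies integer vector, one entry per reference cluster (in offset
#'   order).
#' @param profile profile string (one char per SNV position); \code{"-"}
#'   deletes the base.
#' @return nucleotide string.
#' @export
build_allele_sequence <- function(locus, copies, profile = NULL) {
  ref <- locus$reference
  if (is.null(ref)) stopf("locus %s has no reference", locus$name)
  cl <- parse_repeat_structure(ref, locus)
  if (length(copies) != nrow(cl))
    stopf("locus %s: %d copy numbers given for %d reference clusters",
          locus$name, length(copies), nrow(cl))
  chars <- strsplit(ref, "")[[1]]
  if (!is.null(profile) && nzchar(profile)) {
    states <- strsplit(profile, "")[[1]]
    if (length(states) != length(locus$snv_positions))
      stopf("locus %s: profile length %d != %d snv positions",
            locus$name, length(states), length(locus$snv_positions))
    chars[locus$snv_positions + 1L] <- states
  }
  # assemble segments left to right, swapping cluster spans
  pieces <- character()
  cursor <- 1L
  for (i in seq_len(nrow(cl))) {
    from <- cl$offset[i] + 1L
    to <- cl$offset[i] + nchar(cl$motif[i]) * cl$copies[i]
    if (from > cursor)
      pieces <- c(pieces, paste(chars[cursor:(from - 1L)], collapse = ""))
    pieces <- c(pieces, paste(rep(cl$motif[i], copies[i]), collapse = ""))
    cursor <- to + 1L
  }
  if (cursor <= length(chars))
    pieces <- c(pieces, paste(chars[cursor:length(chars)], collapse = ""))
  gsub("-", "", paste(pieces, collapse = ""), fixed = TRUE)
}
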