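#' Define a microsatellite locus
#'
#' A locus definition names the repeat motifs searched at the locus, the
#' minimum number of tandem copies for a run to count as a cluster, the
#' flanking SNV positions that make up the diagnostic profile, and (optionally)
#' a reference allele sequence used as the alignment anchor for profile
#' extraction.
#'
#' @param name locus identifier, e.g. \code{"Du215"}.
#' @param motifs character vector of repeat motifs. Each motif is reduced to
#'   its primitive unit (\code{"GAGA"} becomes \code{"GA"}) and motifs that
#'   are rotations of an earlier one are dropped; the configured spelling
#'   (e.g. \code{"GATA"}, the published cluster name) anchors cluster
#'   scanning and reporting.
#' @param snv_positions strictly increasing integer vector of 0-based
#'   coordinates, relative to the locus reference sequence, at which the
#'   flanking SNV profile is read. Must fall outside repeat clusters of the
#'   reference.
#' @param min_repeats minimum tandem copies for a reported cluster
#'   (integer >= 2).
#' @param reference optional reference allele sequence (uppercase A/C/G/T).
#' @return an object of class \code{locus_def}.
#' @examples
#' locus_def("Du215", "GATA", snv_positions = c(4L, 9L), min_repeats = 3,
#'           reference = "TTCCATGCTTGATAGATAGATAGATACCGTTAG")
#' @export
locus_def <- function(name, motifs, snv_positions = integer(), min_repeats = 3L,
                      reference = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(motifs) == 0L) stopf("locus %s: motifs must be non-empty", name)
  if (any(grepl("[^ACGT]", motifs)))
    stopf("locus %s: motif alphabet must be A/C/G/T", name)
  motifs <- vapply(motifs, primitive_motif, character(1))
  motifs <- motifs[!duplicated(vapply(motifs, canonical_motif, character(1)))]
  min_repeats <- as.integer(min_repeats)
  if (min_repeats < 2L) stopf("locus %s: min_repeats must be >= 2", name)
  snv_positions <- as.integer(snv_positions)
  if (length(snv_positions) && any(diff(snv_positions) <= 0L))
    stopf("locus %s: snv_positions must be strictly increasing", name)
  if (length(snv_positions) && any(snv_positions < 0L))
    stopf("locus %s: snv_positions are 0-based and must be >= 0", name)
  structure(
    list(name = name, motifs = unname(motifs), min_repeats = min_repeats,
         snv_positions = snv_positions, reference = reference),
    class = "locus_def"
  )
}

#' @export
print.locus_def <- function(x, ...) {
  cat(sprintf("<locus %s> motifs: %s; min copies %d; %d SNV position(s)\n",
              x$name, paste(x$motifs, collapse = ","), x$min_repeats,
              length(x$snv_positions)))
  invisible(x)
}

#' Read a locus configuration (loci + parental catalog) from YAML or JSON
#'
#' The document has two top-level sections. \code{loci} is a list of locus
#' entries with fields \code{name}, \code{motifs}, \code{min_repeats},
#' \code{snv_positions} (0-based reference coordinates) and \code{reference}.
#' \code{parental_catalog} binds the abstract parent slots to species names
#' (\code{parentA}, \code{parentB}) and lists diagnostic entries with fields
#' \code{locus}, \code{profile}, optional \code{cluster_signature} (e.g.
#' \code{"AC:5"}) and \code{species} (\code{"parentA"} or \code{"parentB"}).
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return list with components \code{loci} (a named \code{locus_set}) and
#'   \code{catalog} (a \code{\link{parental_catalog}}), plus any
#'   \code{metadata} carried by the file.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  loci <- lapply(doc$loci, function(l)
    locus_def(l$name, unlist(l$motifs), unlist(l$snv_positions) %||% integer(),
              l$min_repeats %||% 3L, l$reference))
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  class(loci) <- "locus_set"
  catalog <- NULL
  if (!is.null(doc$parental_catalog)) {
    pc <- doc$parental_catalog
    entries <- do.call(rbind, lapply(pc$entries, function(e)
      data.frame(locus = e$locus, profile = e$profile,
                 cluster_signature = e$cluster_signature %||% NA_character_,
                 species = e$species, stringsAsFactors = FALSE)))
    catalog <- parental_catalog(entries,
                                parentA = pc$parentA %||% "parentA",
                                parentB = pc$parentB %||% "parentB")
  }
  list(loci = loci, catalog = catalog, metadata = doc$metadata)
}

#' Build a parental allele catalog
#'
#' The catalog lists, per locus, the flanking SNV profiles (and, where needed,
#' repeat-cluster signatures) observed in the two sexual parental species. A
#' profile observed in both species at a locus must be distinguishable by its
#' cluster signature; otherwise the catalog is not diagnostic and construction
#' fails.
#'
#' @param entries data frame with columns \code{locus}, \code{profile},
#'   \code{cluster_signature} (may be \code{NA}) and \code{species} (values
#'   \code{"parentA"}/\code{"parentB"} or literal species names).
#' @param parentA,parentB species names bound to the two parent slots.
#' @return object of class \code{parental_catalog}.
#' @export
parental_catalog <- function(entries, parentA = "parentA", parentB = "parentB") {
  stopifnot(is.data.frame(entries),
            all(c("locus", "profile", "species") %in% names(entries)))
  if (is.null(entries$cluster_signature))
    entries$cluster_signature <- NA_character_
  entries$species <- ifelse(entries$species %in% c("parentA", "A"), parentA,
                     ifelse(entries$species %in% c("parentB", "B"), parentB,
                            entries$species))
  # diagnosticity: same (locus, profile, signature) must not map to 2 species
  key <- paste(entries$locus, entries$profile,
               ifelse(is.na(entries$cluster_signature), "*",
                      entries$cluster_signature))
  bad <- tapply(entries$species, key, function(s) length(unique(s)) > 1L)
  if (any(bad))
    stopf("catalog is not diagnostic: %s maps to multiple species",
          paste(names(bad)[bad], collapse = "; "))
  # a wildcard-signature profile shared across species is equally fatal
  for (loc in unique(entries$locus)) {
    e <- entries[entries$locus == loc, ]
    for (p in unique(e$profile)) {
      ep <- e[e$profile == p, ]
      if (length(unique(ep$species)) > 1L && anyNA(ep$cluster_signature))
        stopf("catalog is not diagnostic at %s: profile %s shared between species without cluster signatures",
              loc, p)
    }
  }
  structure(list(entries = entries, parentA = parentA, parentB = parentB),
            class = "parental_catalog")
}

#' @export
print.parental_catalog <- function(x, ...) {
  cat(sprintf("<parental catalog> parentA = %s, parentB = %s\n",
              x$parentA, x$parentB))
  print(x$entries, row.names = FALSE)
  invisible(x)
}
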