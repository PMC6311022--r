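#' Parent-specific SNV combination of a genotype
#'
#' For each locus, the unordered pair of flanking SNV profiles carried by the
#' genotype's two alleles. Because stepwise repeat mutation cannot alter
#' flanking SNVs, this combination is the fingerprint of the hybridization
#' event that founded the clone's lineage.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param alleles an \code{allele_set} resolving every allele label.
#' @param id genotype id.
#' @return character string like
#'   \code{"Du215:ACT/TGC;Du281:C/T;Du323:AC/CT;Du47G:TAGT/TTCA"} (profiles
#'   sorted within each pair; loci in configuration order).
#' @export
snv_combination <- function(gt, alleles, id) {
  g <- gt$genotypes[gt$genotypes$id == id, , drop = FALSE]
  if (!nrow(g)) stopf("unknown genotype id %s", id)
  parts <- vapply(gt$loci, function(loc) {
    labs <- c(g[[paste0(loc, "_a1")]], g[[paste0(loc, "_a2")]])
    prof <- vapply(labs, function(l) {
      rec <- alleles[[allele_key(loc, l)]]
      if (is.null(rec)) stopf("allele %s|%s not in allele set", loc, l)
      rec$snv_profile
    }, character(1))
    paste0(loc, ":", paste(sort(prof), collapse = "/"))
  }, character(1))
  paste(parts, collapse = ";")
}

#' Group genotypes into founder classes by SNV combination
#'
#' Genotypes sharing an identical parent-specific SNV combination across all
#' loci are compatible with descent from a single hybridization founder
#' event; distinct combinations require distinct events. The class count is
#' therefore a lower bound on the number of independent hybridizations
#' (identical combinations cannot exclude independent crossings of
#' genetically identical parents), recorded in the \code{lower_bound} field.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param alleles an \code{allele_set}.
#' @return object of class \code{founder_classes}: list with \code{classes}
#'   (data frame: \code{class_id}, \code{signature}, \code{n_genotypes},
#'   \code{n_individuals}, \code{members} as comma-joined ids),
#'   \code{members} (list of integer vectors), \code{n_classes},
#'   \code{lower_bound = TRUE}, and \code{genotype_class} (class id per
#'   genotype id). Classes are ordered by individuals covered, descending.
#' @export
classify_founders <- function(gt, alleles) {
  ids <- gt$genotypes$id
  sigs <- vapply(ids, function(i) snv_combination(gt, alleles, i), character(1))
  usig <- unique(sigs)
  n_ind <- vapply(usig, function(s) sum(gt$genotypes$total[sigs == s]),
                  integer(1))
  ord <- order(-n_ind, usig)
  usig <- usig[ord]
  members <- lapply(usig, function(s) ids[sigs == s])
  classes <- data.frame(
    class_id = seq_along(usig), signature = usig,
    n_genotypes = vapply(members, length, integer(1)),
    n_individuals = n_ind[ord],
    members = vapply(members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  structure(list(classes = classes, members = members,
                 n_classes = length(usig), lower_bound = TRUE,
                 genotype_class = setNames(match(sigs, usig), ids)),
            class = "founder_classes")
}

#' @export
print.founder_classes <- function(x, ...) {
  cat(sprintf(
    "<founder classes> at least %d independent hybridization event(s) (lower bound)\n",
    x$n_classes))
  print(x$classes[, c("class_id", "n_genotypes", "n_individuals", "members")],
        row.names = FALSE)
  invisible(x)
}

#' Attribute the difference between two clones to microsatellite mutations
#'
#' Both genotypes must carry the same parent-specific SNV combination (same
#' founder class); differences between genotypes of different classes are
#' founder differences, not mutations, and are refused. For each locus the
#' allele slots are matched (minimizing steps over the two possible slot
#' pairings); a slot whose two alleles share SNV profile and cluster motif
#' inventory contributes the absolute repeat-count difference, otherwise the
#' replacement counts as a single step.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param alleles an \code{allele_set}.
#' @param a,b distinct genotype ids in the same founder class.
#' @return object of class \code{mutation_edge}: list with \code{a}, \code{b},
#'   \code{changes} (data frame: locus, slot, from, to, type, steps) and
#'   \code{step_count}.
#' @export
mutation_attribution <- function(gt, alleles, a, b) {
  if (a == b) stopf("mutation_attribution requires two distinct genotypes")
  sa <- snv_combination(gt, alleles, a)
  sb <- snv_combination(gt, alleles, b)
  if (!identical(sa, sb))
    stopf("genotypes %s and %s are in different founder classes; their differences are founder differences, not mutations",
          a, b)
  ga <- gt$genotypes[gt$genotypes$id == a, ]
  gb <- gt$genotypes[gt$genotypes$id == b, ]
  changes <- list()
  for (loc in gt$loci) {
    pa <- c(ga[[paste0(loc, "_a1")]], ga[[paste0(loc, "_a2")]])
    pb <- c(gb[[paste0(loc, "_a1")]], gb[[paste0(loc, "_a2")]])
    if (identical(sort_labels(pa), sort_labels(pb))) next
    ra <- lapply(pa, function(l) alleles[[allele_key(loc, l)]])
    rb <- lapply(pb, function(l) alleles[[allele_key(loc, l)]])
    # two possible slot pairings of the unordered pairs; keep the cheaper
    pairings <- list(c(1L, 2L), c(2L, 1L))
    cost <- vapply(pairings, function(pr)
      allele_step_distance(ra[[1]], rb[[pr[1]]]) +
        allele_step_distance(ra[[2]], rb[[pr[2]]]), numeric(1))
    pr <- pairings[[which.min(cost)]]
    for (s in 1:2) {
      if (pa[s] == pb[pr[s]]) next
      d <- allele_step_distance(ra[[s]], rb[[pr[s]]])
      type <- if (comparable_clusters(ra[[s]], rb[[pr[s]]])) "smm" else
        "substitution"
      changes[[length(changes) + 1L]] <-
        data.frame(locus = loc, slot = s, from = pa[s], to = pb[pr[s]],
                   type = type, steps = d, stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(locus = character(), slot = integer(), from = character(),
               to = character(), type = character(), steps = numeric(),
               stringsAsFactors = FALSE)
  structure(list(a = a, b = b, changes = changes,
                 step_count = sum(changes$steps)),
            class = "mutation_edge")
}

#' @export
print.mutation_edge <- function(x, ...) {
  cat(sprintf("<mutation edge> genotype %s -> %s: %g step(s)\n",
              x$a, x$b, x$step_count))
  if (nrow(x$changes)) print(x$changes, row.names = FALSE)
  invisible(x)
}

# TRUE when two alleles share SNV profile and cluster motif inventory, so a
# repeat-count (SMM) distance is meaningful.
comparable_clusters <- function(ra, rb) {
  identical(ra$snv_profile, rb$snv_profile) &&
    identical(ra$clusters$motif, rb$clusters$motif)
}

# Step distance between two alleles of one locus: 0 if same label; sum of
# |repeat-count deltas| when cluster-homologous with equal profile; SNV
# mismatches count 1 each and non-homologous cluster structure counts 1
# (presence/absence character).
allele_step_distance <- function(ra, rb) {
  if (identical(ra$label, rb$label)) return(0)
  snv <- 0L
  if (nzchar(ra$snv_profile) || nzchar(rb$snv_profile)) {
    sa <- strsplit(ra$snv_profile, "")[[1]]
    sb <- strsplit(rb$snv_profile, "")[[1]]
    if (length(sa) == length(sb)) snv <- sum(sa != sb) else snv <- 1L
  }
  if (identical(ra$clusters$motif, rb$clusters$motif))
    snv + sum(abs(ra$clusters$copies - rb$clusters$copies))
  else snv + 1
}

#' Write the founder-class report
#'
#' @param fc a \code{\link{classify_founders}} result.
#' @param path output TSV path.
#' @param header optional comment lines.
#' @return the report data frame, invisibly.
#' @export
write_founder_report <- function(fc, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  writeLines("# class count is a lower bound on independent hybridization events", con)
  write.table(fc$classes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fc$classes)
}
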