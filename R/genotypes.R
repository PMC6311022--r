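#' Read per-individual allele calls from TSV
#'
#' One row per individual with columns \code{individual_id},
#' \code{population}, then \code{<locus>_a1} and \code{<locus>_a2} per locus.
#'
#' @param path TSV file.
#' @return data frame of individual calls.
#' @export
read_individuals_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("individual_id", "population")
  if (!all(need %in% names(df)))
    stopf("individuals table must have columns %s", paste(need, collapse = ", "))
  df
}

# Loci named by the *_a1/*_a2 column pairs, in order of appearance.
call_loci <- function(individuals) {
  a1 <- sub("_a1$", "", grep("_a1$", names(individuals), value = TRUE))
  a2 <- sub("_a2$", "", grep("_a2$", names(individuals), value = TRUE))
  if (!length(a1) || !setequal(a1, a2))
    stopf("individuals table needs paired <locus>_a1/<locus>_a2 columns")
  a1
}

# Canonical per-individual composition: per locus the unordered (sorted)
# allele pair. Returns a character matrix n x (2*loci) plus the key string.
canonical_calls <- function(individuals, loci) {
  n <- nrow(individuals)
  mat <- matrix("", n, 2L * length(loci))
  for (j in seq_along(loci)) {
    a1 <- individuals[[paste0(loci[j], "_a1")]]
    a2 <- individuals[[paste0(loci[j], "_a2")]]
    miss <- is.na(a1) | is.na(a2) | a1 == "" | a2 == ""
    if (any(miss))
      stopf("individual %s: missing call at locus %s",
            individuals$individual_id[which(miss)[1]], loci[j])
    swap <- pad_label(a2) < pad_label(a1)
    mat[, 2L * j - 1L] <- ifelse(swap, a2, a1)
    mat[, 2L * j] <- ifelse(swap, a1, a2)
  }
  mat
}

composition_string <- function(row, loci) {
  paste(sprintf("%s(%s+%s)", loci, row[seq_along(loci) * 2L - 1L],
                row[seq_along(loci) * 2L]), collapse = "+")
}

#' Call canonical multilocus genotypes and tabulate them by population
#'
#' Individuals with identical unordered allele pairs at every locus share a
#' genotype ("presumptive clone"). Genotype ids are assigned in descending
#' order of total count, ties broken by numeric-aware lexicographic order of
#' the composition; the same cohort therefore always yields the same ids.
#'
#' @param individuals data frame of individual calls (see
#'   \code{\link{read_individuals_tsv}}).
#' @return object of class \code{genotype_table}: list with
#'   \code{genotypes} (data frame: \code{id}, \code{composition},
#'   \code{total}, \code{freq}, per-locus allele pairs), \code{counts}
#'   (genotype x population matrix), \code{individuals} (input plus
#'   \code{genotype_id}), \code{loci}, and \code{most_frequent} (the flagged
#'   top genotype id).
#' @examples
#' ind <- data.frame(individual_id = c("i1", "i2"), population = "P",
#'                   L1_a1 = c("3", "2"), L1_a2 = c("2", "3"))
#' genotype_table(ind)$genotypes$total  # both individuals share one genotype
#' @export
genotype_table <- function(individuals) {
  if (!nrow(individuals)) stopf("empty cohort")
  loci <- call_loci(individuals)
  mat <- canonical_calls(individuals, loci)
  key <- apply(mat, 1L, paste, collapse = "\r")
  ukey <- unique(key)
  totals <- as.integer(table(key)[ukey])
  umat <- mat[match(ukey, key), , drop = FALSE]
  # id order: count desc, then padded composition columns ascending
  ordcols <- lapply(seq_len(ncol(umat)), function(j) pad_label(umat[, j]))
  ord <- do.call(order, c(list(-totals), ordcols))
  ukey <- ukey[ord]; totals <- totals[ord]
  umat <- umat[ord, , drop = FALSE]
  ids <- seq_along(ukey)
  gid <- ids[match(key, ukey)]
  pops <- unique(individuals$population)
  counts <- table(factor(gid, levels = ids),
                  factor(individuals$population, levels = pops))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(genotype = ids, population = pops))
  comp <- apply(umat, 1L, composition_string, loci = loci)
  geno <- data.frame(id = ids, composition = comp, total = totals,
                     freq = totals / nrow(individuals),
                     stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    geno[[paste0(loci[j], "_a1")]] <- umat[, 2L * j - 1L]
    geno[[paste0(loci[j], "_a2")]] <- umat[, 2L * j]
  }
  out <- list(genotypes = geno, counts = counts,
              individuals = cbind(individuals, genotype_id = gid),
              loci = loci, most_frequent = ids[which.max(totals)])
  class(out) <- "genotype_table"
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "<genotype table> %d individuals, %d populations, %d genotypes; most frequent: genotype %d (n=%d, %.1f%%)\n",
    nrow(x$individuals), ncol(x$counts), nrow(x$genotypes),
    x$most_frequent, max(x$genotypes$total), 100 * max(x$genotypes$freq)))
  print(head(x$genotypes[, c("id", "composition", "total", "freq")], 20),
        row.names = FALSE)
  invisible(x)
}

#' Genotypic diversity of populations
#'
#' 100 * G / N with G distinct genotypes among N individuals, with the
#' convention that a monomorphic population (G = 1) is reported as 0.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param population population name(s); default all.
#' @return named numeric vector of percentages.
#' @export
genotypic_diversity <- function(gt, population = colnames(gt$counts)) {
  unknown <- setdiff(population, colnames(gt$counts))
  if (length(unknown)) stopf("unknown population(s): %s",
                             paste(unknown, collapse = ", "))
  vapply(population, function(p) {
    n <- sum(gt$counts[, p])
    if (n == 0L) stopf("population %s is empty", p)
    g <- sum(gt$counts[, p] > 0L)
    if (g == 1L) 0 else 100 * g / n
  }, numeric(1))
}

#' Write a genotype-by-population report table
#'
#' Mirrors the shape of a genotype composition/distribution table: one row
#' per genotype with composition, per-population counts, total and frequency,
#' plus total and genotypic-diversity summary rows.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param path output TSV path.
#' @param header optional comment lines (prefixed \code{#}) to write first.
#' @return the report data frame, invisibly.
#' @export
write_genotype_report <- function(gt, path, header = character()) {
  df <- data.frame(genotype = gt$genotypes$id,
                   composition = gt$genotypes$composition,
                   gt$counts, check.names = FALSE,
                   total = gt$genotypes$total,
                   frequency = round_half_up(gt$genotypes$freq, 3))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  gd <- genotypic_diversity(gt)
  writeLines(c(paste(c("# individuals", colSums(gt$counts)), collapse = "\t"),
               paste(c("# genotypic_diversity_pct",
                       round_half_up(gd, 1)), collapse = "\t")), con)
  invisible(df)
}
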