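#' Allele frequencies at one locus in a set of individuals
#'
#' Counts over 2n gene copies (each individual contributes both alleles;
#' homozygotes contribute two copies of the same allele).
#'
#' @param individuals data frame of individual calls.
#' @param locus locus name.
#' @return named integer vector of allele counts, with frequencies in
#'   attribute \code{"freq"}.
#' @export
allele_counts <- function(individuals, locus) {
  if (!nrow(individuals)) stopf("no individuals")
  copies <- c(individuals[[paste0(locus, "_a1")]],
              individuals[[paste0(locus, "_a2")]])
  tab <- table(copies)
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[sort_labels(names(counts))]
  attr(counts, "freq") <- counts / sum(counts)
  counts
}

#' Unbiased expected heterozygosity (Nei gene diversity)
#'
#' \eqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)} over 2n gene
#' copies. The small-sample correction can be disabled with
#' \code{unbiased = FALSE}.
#'
#' @param counts named integer vector of allele counts (from
#'   \code{\link{allele_counts}}).
#' @param unbiased apply the \eqn{2n/(2n-1)} correction (default TRUE).
#' @return numeric in [0, 1].
#' @export
expected_heterozygosity <- function(counts, unbiased = TRUE) {
  n2 <- sum(counts)
  if (n2 < 1L) stopf("no gene copies")
  p <- counts / n2
  h <- 1 - sum(p^2)
  if (unbiased && n2 > 1L) h <- h * n2 / (n2 - 1)
  h
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a hypergeometric subsample of
#' \code{g} gene copies drawn without replacement from the observed copies:
#' \eqn{R_S = \sum_i \left[1 - \binom{2n - N_i}{g} / \binom{2n}{g}\right]}
#' for alleles with counts \eqn{N_i}.
#'
#' @param counts allele counts (2n = \code{sum(counts)}).
#' @param g rarefaction size in gene copies; must satisfy \code{g <= 2n}.
#' @return numeric; equals the allele count when \code{g = 2n}.
#' @export
rarefied_richness <- function(counts, g) {
  n2 <- sum(counts)
  if (g > n2) stopf("rarefaction size g = %d exceeds 2n = %d", g, n2)
  sum(1 - exp(lchoose(n2 - counts, g) - lchoose(n2, g)))
}

#' Observed heterozygosity
#'
#' Fraction of individuals whose two alleles at the locus differ.
#'
#' @param individuals data frame of individual calls.
#' @param locus locus name.
#' @return numeric in [0, 1].
#' @export
observed_heterozygosity <- function(individuals, locus) {
  if (!nrow(individuals)) stopf("no individuals")
  mean(individuals[[paste0(locus, "_a1")]] !=
         individuals[[paste0(locus, "_a2")]])
}

#' Per-locus, per-population diversity statistics
#'
#' Computes, for every locus and every retained population: the allele count
#' N, rarefied allelic richness \eqn{R_S} at \code{g} gene copies, unbiased
#' expected heterozygosity \eqn{H_E} and observed heterozygosity \eqn{H_O}.
#' A filter stage precedes the statistics: listed genotypes are dropped
#' (rare clones from minor founder classes are conventionally excluded) and
#' populations falling below \code{min_pop_n} individuals after the drop are
#' removed entirely.
#'
#' @param individuals data frame of individual calls.
#' @param exclude_genotypes integer ids (under \code{\link{genotype_table}}
#'   numbering of the *full* cohort) to drop before computing statistics.
#' @param min_pop_n minimum retained population size (default 2).
#' @param g rarefaction size in gene copies; default \code{NULL} uses twice
#'   the smallest retained population size.
#' @param unbiased apply the small-sample \eqn{H_E} correction.
#' @return object of class \code{diversity_stats}: data frame with columns
#'   \code{locus}, \code{population}, \code{n_individuals}, \code{n_alleles},
#'   \code{rarefied_richness}, \code{expected_het}, \code{observed_het};
#'   attributes \code{g}, \code{excluded_genotypes}, \code{dropped_populations}.
#' @export
diversity_stats <- function(individuals, exclude_genotypes = integer(),
                            min_pop_n = 2L, g = NULL, unbiased = TRUE) {
  loci <- call_loci(individuals)
  keep <- individuals
  if (length(exclude_genotypes)) {
    gt <- genotype_table(individuals)
    keep <- gt$individuals[!(gt$individuals$genotype_id %in% exclude_genotypes), ]
  }
  sizes <- table(keep$population)
  dropped <- names(sizes)[sizes < min_pop_n]
  keep <- keep[!(keep$population %in% dropped), , drop = FALSE]
  if (!nrow(keep)) stopf("no individuals left after filtering")
  pops <- unique(keep$population)
  if (is.null(g)) g <- 2L * min(table(keep$population))
  rows <- list()
  for (loc in loci) {
    for (p in pops) {
      sub <- keep[keep$population == p, , drop = FALSE]
      cnt <- allele_counts(sub, loc)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, population = p, n_individuals = nrow(sub),
        n_alleles = length(cnt),
        rarefied_richness = rarefied_richness(cnt, g),
        expected_het = expected_heterozygosity(cnt, unbiased = unbiased),
        observed_het = observed_heterozygosity(sub, loc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("diversity_stats", "data.frame"), g = g,
            excluded_genotypes = exclude_genotypes,
            dropped_populations = dropped, cohort = keep)
}

#' Render the diversity report with Total and Mean rows
#'
#' Adds, per locus, a \code{Total} row (statistics over the pooled retained
#' individuals; richness at the full pooled size, hence equal to the pooled
#' allele count) and a \code{Mean +/- SE} row (mean of the per-population
#' values; SE = sample standard deviation across populations divided by
#' \eqn{\sqrt{k}}). Values are display-rounded half-up to 2 decimals.
#'
#' @param stats a \code{\link{diversity_stats}} result.
#' @param path optional TSV output path.
#' @param header optional comment lines for the file.
#' @return report data frame (character columns, rounded), invisibly when
#'   writing.
#' @export
report_diversity <- function(stats, path = NULL, header = character()) {
  keep <- attr(stats, "cohort")
  rows <- list()
  fmt <- function(x, d = 2) sprintf(paste0("%.", d, "f"), round_half_up(x, d))
  for (loc in unique(stats$locus)) {
    s <- stats[stats$locus == loc, , drop = FALSE]
    for (i in seq_len(nrow(s)))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, population = s$population[i],
        N = as.character(s$n_alleles[i]),
        R_S = fmt(s$rarefied_richness[i]),
        H_E = fmt(s$expected_het[i]), H_O = fmt(s$observed_het[i]),
        stringsAsFactors = FALSE)
    cnt <- allele_counts(keep, loc)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = loc, population = "Total", N = as.character(length(cnt)),
      R_S = fmt(rarefied_richness(cnt, sum(cnt))),
      H_E = fmt(expected_heterozygosity(cnt)),
      H_O = fmt(observed_heterozygosity(keep, loc)),
      stringsAsFactors = FALSE)
    k <- nrow(s)
    msd <- function(x) sprintf("%s +/- %s", fmt(mean(x)),
                               fmt(sd(x) / sqrt(k)))
    rows[[length(rows) + 1L]] <- data.frame(
      locus = loc, population = "Mean +/- SE",
      N = msd(s$n_alleles), R_S = msd(s$rarefied_richness),
      H_E = msd(s$expected_het), H_O = msd(s$observed_het),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste("#", header), con)
    writeLines(sprintf("# rarefaction g = %d gene copies", attr(stats, "g")), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
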