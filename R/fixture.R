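#' Load a packaged reference cohort fixture
#'
#' \code{"armeniaca_t2"} is a reconstruction of a published 111-individual,
#' 14-population cohort of the parthenogenetic rock lizard
#' \emph{Darevskia armeniaca} genotyped at four sequenced microsatellite
#' loci (Du215, Du281, Du323, Du47G), together with the 17 distinct allele
#' sequences (synthetic backbones carrying the reported repeat-cluster
#' structure and flanking SNV profiles) and the diagnostic parental catalog
#' for \emph{D. mixta} (parentA) and \emph{D. valentini} (parentB).
#' Per-individual population assignments were reconstructed from the printed
#' genotype-by-population table; cells whose placement required corroborating
#' diversity indices are flagged in the fixture metadata.
#'
#' @param name fixture name (only \code{"armeniaca_t2"} is bundled).
#' @return list with \code{individuals} (calls data frame), \code{alleles}
#'   (an \code{allele_set} with origins assigned), \code{loci},
#'   \code{catalog}, \code{metadata}.
#' @export
load_fixture <- function(name = "armeniaca_t2") {
  dir <- system.file("extdata", name, package = "msatclone")
  if (dir == "" || !dir.exists(dir)) stopf("unknown fixture '%s'", name)
  cfg <- read_locus_config(file.path(dir, "config.yaml"))
  alleles <- read_alleles_fasta(file.path(dir, "alleles.fasta"), cfg$loci)
  alleles <- assign_parental_origin(alleles, cfg$catalog)
  individuals <- read_individuals_tsv(file.path(dir, "individuals.tsv"))
  exp <- cfg$metadata$expected
  if (!is.null(exp)) {
    if (nrow(individuals) != exp$n_individuals)
      stopf("fixture checksum mismatch: %d individuals, expected %d",
            nrow(individuals), exp$n_individuals)
    gt <- genotype_table(individuals)
    if (nrow(gt$genotypes) != exp$n_genotypes)
      stopf("fixture checksum mismatch: %d genotypes, expected %d",
            nrow(gt$genotypes), exp$n_genotypes)
    pt <- exp$population_totals
    if (!is.null(pt)) {
      got <- table(individuals$population)
      bad <- names(pt)[unlist(pt) != as.integer(got[names(pt)])]
      if (length(bad))
        stopf("fixture checksum mismatch in population total(s): %s",
              paste(bad, collapse = ", "))
    }
  }
  list(individuals = individuals, alleles = alleles, loci = cfg$loci,
       catalog = cfg$catalog, metadata = cfg$metadata)
}
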