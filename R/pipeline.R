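#' Run the whole inference pipeline and write a report bundle
#'
#' Executes genotype calling, founder classification, within-class network
#' construction, diversity statistics and the linkage-disequilibrium test,
#' and writes TSV reports, GraphML network exports and a JSON summary to
#' \code{out_dir}. Outputs are deterministic given the seed, and every file
#' carries a header naming the package version, a configuration hash and the
#' seed.
#'
#' @param individuals data frame of individual calls.
#' @param alleles an \code{allele_set}.
#' @param catalog optional \code{\link{parental_catalog}}.
#' @param out_dir output directory (created if missing).
#' @param exclude_genotypes genotype ids dropped before diversity statistics;
#'   \code{"minor_classes"} (default) drops every genotype outside the
#'   largest founder class, the convention used for clonal cohorts where
#'   rare independent lineages would otherwise dominate the indices.
#' @param min_pop_n minimum population size kept in diversity statistics.
#' @param g rarefaction size in gene copies (\code{NULL}: twice the smallest
#'   retained population).
#' @param n_perm permutations for the index of association.
#' @param seed RNG seed, recorded in all outputs.
#' @return the \code{\link{infer_clonal_origins}} fit, invisibly, with the
#'   summary list attached as attribute \code{"summary"}.
#' @export
run_pipeline <- function(individuals, alleles, catalog = NULL,
                         out_dir = "msatclone-out",
                         exclude_genotypes = "minor_classes",
                         min_pop_n = 2L, g = NULL, n_perm = 999L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- infer_clonal_origins(individuals, alleles, catalog)
  gt <- fit$genotype_table
  fc <- fit$founder_classes
  header <- output_header(individuals, seed)
  write_genotype_report(gt, file.path(out_dir, "genotypes.tsv"), header)
  write_founder_report(fc, file.path(out_dir, "founder_classes.tsv"), header)
  if (identical(exclude_genotypes, "minor_classes"))
    exclude_genotypes <- unlist(fc$members[-1])
  stats <- diversity_stats(individuals,
                           exclude_genotypes = exclude_genotypes,
                           min_pop_n = min_pop_n, g = g)
  report_diversity(stats, file.path(out_dir, "diversity.tsv"), header)
  ld <- tryCatch(index_of_association(individuals, n_perm = n_perm,
                                      seed = seed),
                 error = function(e) NULL)
  if (!is.null(ld)) {
    ld_df <- data.frame(population = "all", I_A = ld$ia, rbar_d = ld$rbar_d,
                        p = ld$p_value, permutations = ld$n_perm,
                        seed = ld$seed)
    con <- file(file.path(out_dir, "ld.tsv"), "w")
    writeLines(paste("#", header), con)
    write.table(ld_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (k in names(fit$networks))
    write_network(fit$networks[[k]],
                  graphml = file.path(out_dir,
                                      sprintf("network_class%s.graphml", k)),
                  edges_tsv = file.path(out_dir,
                                        sprintf("network_class%s.tsv", k)))
  summary_list <- list(
    n_individuals = nrow(individuals),
    n_genotypes = nrow(gt$genotypes),
    n_founder_classes = fc$n_classes,
    founder_count_is_lower_bound = fc$lower_bound,
    most_common_genotype = gt$most_frequent,
    most_common_genotype_freq = max(gt$genotypes$freq),
    rarefaction_g = attr(stats, "g"),
    seed = seed)
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(fit, "summary") <- summary_list
  invisible(fit)
}

output_header <- function(individuals, seed) {
  tf <- tempfile()
  write.table(individuals, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  c(sprintf("msatclone %s",
            as.character(utils::packageVersion("msatclone"))),
    sprintf("input_md5 %s", hash),
    sprintf("seed %d", seed))
}
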