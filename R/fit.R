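#' Infer the clonal origins of a parthenogenetic cohort
#'
#' The central fitting function. Calls canonical multilocus genotypes,
#' optionally assigns parental origins to the alleles, groups genotypes into
#' founder classes by parent-specific SNV combination (the inferred minimum
#' number of hybridization events), and builds a parsimony mutation network
#' within each class of two or more clones.
#'
#' @param individuals data frame of individual calls (see
#'   \code{\link{read_individuals_tsv}}).
#' @param alleles an \code{allele_set} resolving every allele label.
#' @param catalog optional \code{\link{parental_catalog}}; when given,
#'   allele origins are (re)assigned before classification.
#' @param connection_limit step cap for within-class networks (default
#'   \code{Inf}: unlimited within a founder class).
#' @return object of class \code{clone_origins}: list with
#'   \code{genotype_table}, \code{founder_classes}, \code{networks} (one
#'   \code{\link{clone_network}} per multi-genotype class, named by class
#'   id), \code{alleles}, \code{n_individuals}, \code{call}.
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 42))
#' fit <- infer_clonal_origins(sim$individuals, sim$alleles)
#' fit$founder_classes$n_classes
#' @export
infer_clonal_origins <- function(individuals, alleles, catalog = NULL,
                                 connection_limit = Inf) {
  if (!is.null(catalog))
    alleles <- assign_parental_origin(alleles, catalog)
  gt <- genotype_table(individuals)
  fc <- classify_founders(gt, alleles)
  networks <- list()
  for (k in seq_len(fc$n_classes)) {
    ids <- fc$members[[k]]
    if (length(ids) >= 2L)
      networks[[as.character(k)]] <-
        clone_network(gt, alleles, ids, connection_limit = connection_limit)
  }
  structure(list(genotype_table = gt, founder_classes = fc,
                 networks = networks, alleles = alleles,
                 n_individuals = nrow(individuals),
                 call = match.call()),
            class = "clone_origins")
}

#' @export
print.clone_origins <- function(x, ...) {
  gt <- x$genotype_table
  cat(sprintf(
    "Clonal origin inference: %d individuals, %d populations\n",
    x$n_individuals, ncol(gt$counts)))
  cat(sprintf("  genotypes (presumptive clones): %d\n", nrow(gt$genotypes)))
  cat(sprintf("  most frequent: genotype %d, n = %d (%.1f%%)\n",
              gt$most_frequent, max(gt$genotypes$total),
              100 * max(gt$genotypes$freq)))
  cat(sprintf(
    "  founder classes: at least %d independent hybridization event(s)\n",
    x$founder_classes$n_classes))
  invisible(x)
}

#' @export
summary.clone_origins <- function(object, ...) {
  structure(list(fit = object), class = "summary.clone_origins")
}

#' @export
print.summary.clone_origins <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nFounder classes (SNV-combination fingerprints):\n")
  print(fit$founder_classes$classes[, c("class_id", "n_genotypes",
                                        "n_individuals", "members")],
        row.names = FALSE)
  cat("\nGenotypes:\n")
  print(fit$genotype_table$genotypes[, c("id", "composition", "total",
                                         "freq")], row.names = FALSE)
  for (k in names(fit$networks)) {
    hs <- hub_statistics(fit$networks[[k]])
    cat(sprintf("\nClass %s network hub: genotype %s (degree %d, eccentricity %g steps)\n",
                k, hs$id[1], hs$degree[1], hs$eccentricity[1]))
  }
  invisible(x)
}

#' Plot the mutation network(s) of a clonal origin fit
#'
#' @param x a \code{\link{infer_clonal_origins}} fit.
#' @param class_id founder class to plot (default the largest with a
#'   network).
#' @param ... passed to \code{\link{plot.clone_network}}.
#' @export
plot.clone_origins <- function(x, class_id = NULL, ...) {
  if (!length(x$networks)) stopf("no multi-genotype class to plot")
  k <- as.character(class_id %||% names(x$networks)[1])
  if (is.null(x$networks[[k]])) stopf("class %s has no network", k)
  plot(x$networks[[k]], ...)
}
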