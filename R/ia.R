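#' Multilocus linkage disequilibrium: index of association
#'
#' Computes the index of association \eqn{I_A = V_O/V_E - 1} and its
#' standardized form \eqn{\bar r_d} from pairwise inter-individual distances.
#' Per locus, the distance between two individuals is the number of allele
#' slots at which their unordered pairs differ (0, 1 or 2). \eqn{V_O} is the
#' variance over pairs of the summed distance, \eqn{V_E} the sum of the
#' per-locus variances; \eqn{\bar r_d} divides the excess covariance by
#' \eqn{2\sum_{j<k}\sqrt{\mathrm{var}(d_j)\mathrm{var}(d_k)}}, bounding it in
#' [-1, 1]. Significance is assessed by permuting the per-locus genotype
#' columns among individuals independently (which preserves every single-locus
#' distribution while destroying between-locus association); with
#' \code{shuffle = "allele"} the 2n allele copies are re-paired instead.
#'
#' @param individuals data frame of individual calls (>= 3 individuals,
#'   >= 2 loci).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed recorded in the result.
#' @param clone_correct keep one individual per multilocus genotype before
#'   testing.
#' @param shuffle \code{"genotype"} (default) or \code{"allele"}.
#' @return object of class \code{ia_test}: list with \code{ia},
#'   \code{rbar_d}, \code{p_value} (for \eqn{\bar r_d}; one-sided upper),
#'   \code{p_ia}, \code{n_perm}, \code{seed}, \code{n_individuals},
#'   \code{degenerate} flag. Degenerate cohorts (no variance) return
#'   \code{NA} statistics with \code{degenerate = TRUE}.
#' @export
index_of_association <- function(individuals, n_perm = 999L, seed = 1L,
                                 clone_correct = FALSE,
                                 shuffle = c("genotype", "allele")) {
  shuffle <- match.arg(shuffle)
  loci <- call_loci(individuals)
  if (length(loci) < 2L) stopf("index of association needs >= 2 loci")
  if (clone_correct) {
    gt <- genotype_table(individuals)
    individuals <- gt$individuals[!duplicated(gt$individuals$genotype_id), ,
                                  drop = FALSE]
  }
  n <- nrow(individuals)
  if (n < 3L) stopf("index of association needs >= 3 individuals")
  mats <- lapply(loci, function(loc) locus_distance_matrix(individuals, loc))
  obs <- ia_from_matrices(mats)
  if (is.na(obs$rbar_d))
    return(structure(list(ia = NA_real_, rbar_d = NA_real_,
                          p_value = NA_real_, p_ia = NA_real_,
                          n_perm = n_perm, seed = seed, n_individuals = n,
                          degenerate = TRUE), class = "ia_test"))
  set.seed(seed)
  hits_rd <- 0L
  hits_ia <- 0L
  for (b in seq_len(n_perm)) {
    pm <- if (shuffle == "genotype")
      lapply(mats, function(m) {
        p <- sample.int(n)
        m[p, p, drop = FALSE]
      })
    else
      lapply(loci, function(loc)
        locus_distance_matrix(shuffle_alleles(individuals, loc), loc))
    r <- ia_from_matrices(pm)
    if (!is.na(r$rbar_d) && r$rbar_d >= obs$rbar_d) hits_rd <- hits_rd + 1L
    if (!is.na(r$ia) && r$ia >= obs$ia) hits_ia <- hits_ia + 1L
  }
  structure(list(ia = obs$ia, rbar_d = obs$rbar_d,
                 p_value = (hits_rd + 1L) / (n_perm + 1L),
                 p_ia = (hits_ia + 1L) / (n_perm + 1L),
                 n_perm = n_perm, seed = seed, n_individuals = n,
                 degenerate = FALSE),
            class = "ia_test")
}

#' @export
print.ia_test <- function(x, ...) {
  if (x$degenerate) {
    cat("<index of association> degenerate cohort (no variance); statistics undefined\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<index of association> I_A = %.4f, rbar_d = %.4f, p = %.4g (%d permutations, seed %d, n = %d)\n",
    x$ia, x$rbar_d, x$p_value, x$n_perm, x$seed, x$n_individuals))
  invisible(x)
}

# n x n matrix of per-locus mismatch distances (0/1/2 allele slots).
locus_distance_matrix <- function(individuals, locus) {
  a1 <- individuals[[paste0(locus, "_a1")]]
  a2 <- individuals[[paste0(locus, "_a2")]]
  swap <- pad_label(a2) < pad_label(a1)
  x1 <- ifelse(swap, a2, a1)
  x2 <- ifelse(swap, a1, a2)
  n <- length(x1)
  shared <- outer(seq_len(n), seq_len(n), function(i, j) {
    both <- (x1[i] == x1[j]) & (x2[i] == x2[j])
    one <- (x1[i] == x1[j]) | (x1[i] == x2[j]) | (x2[i] == x1[j]) |
      (x2[i] == x2[j])
    ifelse(both, 2L, ifelse(one, 1L, 0L))
  })
  2L - shared
}

# I_A and rbar_d from a list of per-locus distance matrices.
ia_from_matrices <- function(mats) {
  lower <- lower.tri(mats[[1]])
  d <- vapply(mats, function(m) m[lower], numeric(sum(lower)))
  vars <- apply(d, 2L, pop_var)
  VE <- sum(vars)
  D <- rowSums(d)
  VO <- pop_var(D)
  denom <- 0
  nl <- ncol(d)
  for (j in seq_len(nl - 1L))
    for (k in (j + 1L):nl) denom <- denom + sqrt(vars[j] * vars[k])
  if (VE <= 0 || denom <= 0)
    return(list(ia = NA_real_, rbar_d = NA_real_))
  list(ia = VO / VE - 1, rbar_d = (VO - VE) / (2 * denom))
}

pop_var <- function(x) mean(x^2) - mean(x)^2

# Re-pair the 2n allele copies of one locus at random (allele shuffle null).
shuffle_alleles <- function(individuals, locus) {
  copies <- sample(c(individuals[[paste0(locus, "_a1")]],
                     individuals[[paste0(locus, "_a2")]]))
  n <- nrow(individuals)
  individuals[[paste0(locus, "_a1")]] <- copies[seq_len(n)]
  individuals[[paste0(locus, "_a2")]] <- copies[n + seq_len(n)]
  individuals
}
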