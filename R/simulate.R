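#' Default simulated locus panel
#'
#' Four loci shaped like the sequenced Du-series microsatellites: a
#' (GATA)n cluster with species-diagnostic flanking SNV profiles, one locus
#' carrying an additional fixed (AC)n cluster whose copy number also differs
#' between the parental species, and profile pools of four per species per
#' locus (parental species are themselves polymorphic in their flanks).
#'
#' @return list of simulated locus specifications.
#' @export
sim_default_loci <- function() {
  list(
    list(name = "simDu215", motifs = "GATA", flank_len = 40L,
         profiles = list(parentA = c("TGC", "TGA", "CGC", "AGC"),
                         parentB = c("ACT", "ACG", "TCT", "GCT")),
         copy_ranges = list(parentA = list(GATA = c(7L, 10L)),
                            parentB = list(GATA = c(11L, 14L)))),
    list(name = "simDu281", motifs = "GATA", flank_len = 40L,
         profiles = list(parentA = c("T", "A"),
                         parentB = c("C", "G")),
         copy_ranges = list(parentA = list(GATA = c(6L, 9L)),
                            parentB = list(GATA = c(10L, 13L)))),
    list(name = "simDu323", motifs = c("GATA", "AC"), flank_len = 40L,
         profiles = list(parentA = c("CT", "CA", "CG", "TT"),
                         parentB = c("AC", "AG", "GC", "GG")),
         copy_ranges = list(parentA = list(GATA = c(8L, 11L), AC = c(5L, 5L)),
                            parentB = list(GATA = c(12L, 15L), AC = c(6L, 6L)))),
    list(name = "simDu47G", motifs = "GATA", flank_len = 40L,
         profiles = list(parentA = c("AAGA", "TAGT", "AAGG", "TAGA"),
                         parentB = c("TTCA", "TTCG", "CTCA", "TCCA")),
         copy_ranges = list(parentA = list(GATA = c(6L, 9L)),
                            parentB = list(GATA = c(10L, 14L))))
  )
}

#' Simulation configuration
#'
#' Describes the generative model the analysis assumes: two diverged sexual
#' parental species with species-diagnostic flanking SNV profiles,
#' \code{n_founders} independent interspecific hybridization events (each
#' founder takes one allele per locus from each parent), clonal propagation
#' for \code{generations} generations under a single-step symmetric stepwise
#' mutation model (per allele per generation mutation probability \code{mu},
#' one repeat gained or lost, reflecting upward at \code{min_copies}), and
#' population sampling with per-population founder mixture weights. Flanking
#' SNVs never mutate (model assumption). Only the first (primary) motif's
#' cluster mutates; secondary clusters are fixed species markers.
#'
#' @param loci list of locus specifications (default
#'   \code{\link{sim_default_loci}}).
#' @param n_founders number of founder events F (>= 1; default 3).
#' @param generations clonal generations between founding and sampling
#'   (default 100).
#' @param mu per-allele per-generation mutation probability (default 1e-3).
#' @param pops list of populations, each \code{list(name, n, weights)} where
#'   \code{weights} are founder mixture weights (recycled/normalized).
#'   Default: three populations (20, 10, 10) dominated by founder 1,
#'   emulating one widespread clone plus rare ones.
#' @param pool_size parental alleles per species per locus (default 6).
#' @param distinct_founders resample founder allele draws until the founder
#'   SNV signatures are pairwise distinct (default TRUE; the premise of
#'   counting events from signatures).
#' @param min_copies reflecting lower bound for repeat counts (default 3;
#'   shorter runs would fall below the cluster-detection threshold and break
#'   homology).
#' @param seed RNG seed; replaying the same configuration is bit-identical.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(loci = sim_default_loci(), n_founders = 3L,
                       generations = 100L, mu = 1e-3, pops = NULL,
                       pool_size = 6L, distinct_founders = TRUE,
                       min_copies = 3L, seed = 1L) {
  stopifnot(n_founders >= 1L, mu >= 0, mu <= 1, generations >= 0L)
  if (is.null(pops)) {
    w <- if (n_founders == 1L) 1 else
      c(0.8, rep(0.2 / (n_founders - 1L), n_founders - 1L))
    pops <- list(list(name = "PopA", n = 20L, weights = w),
                 list(name = "PopB", n = 10L, weights = w),
                 list(name = "PopC", n = 10L, weights = w))
  }
  for (p in pops) stopifnot(p$n >= 1L)
  structure(list(loci = loci, n_founders = as.integer(n_founders),
                 generations = as.integer(generations), mu = mu, pops = pops,
                 pool_size = as.integer(pool_size),
                 distinct_founders = isTRUE(distinct_founders),
                 min_copies = as.integer(min_copies),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the parental allele pools
#'
#' Draws, per species and locus, \code{pool_size} alleles with a
#' species-diagnostic SNV profile and repeat counts from the configured
#' ranges. A profile configured in both species triggers a warning (it makes
#' parental assignment ambiguous -- useful for testing that case, fatal for
#' diagnosticity).
#'
#' @param config a \code{\link{sim_config}}.
#' @return nested list \code{pools[[species]][[locus]]}: list of alleles,
#'   each \code{list(profile, copies)} with \code{copies} named by motif.
#' @export
simulate_parental_pools <- function(config) {
  set.seed(config$seed)
  draw_pools(config)
}

draw_pools <- function(config) {
  pools <- list(parentA = list(), parentB = list())
  for (l in config$loci) {
    shared <- intersect(l$profiles$parentA, l$profiles$parentB)
    if (length(shared))
      warning(sprintf("locus %s: profile(s) %s configured in both species",
                      l$name, paste(shared, collapse = ",")), call. = FALSE)
    for (sp in c("parentA", "parentB")) {
      pools[[sp]][[l$name]] <- lapply(seq_len(config$pool_size), function(i) {
        copies <- vapply(l$motifs, function(m) {
          r <- l$copy_ranges[[sp]][[m]]
          if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
        }, integer(1))
        list(profile = sample(l$profiles[[sp]], 1L),
             copies = setNames(copies, l$motifs))
      })
    }
  }
  pools
}

#' Simulate a clonal hybrid cohort with full ground truth
#'
#' Implements the model described in \code{\link{sim_config}}. Each sampled
#' individual picks a founder according to its population's mixture weights
#' and then accumulates stepwise repeat mutations independently over the
#' configured number of clonal generations.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_result}: list with
#'   \code{individuals} (calls data frame usable by
#'   \code{\link{genotype_table}}), \code{alleles} (an \code{allele_set}
#'   of every realized allele with truth origin), \code{truth}
#'   (per individual x locus x slot: founder, origin species, mutation event
#'   count, net repeat delta, step history), \code{founders} (signature and
#'   allele draw per founder), \code{pools}, and \code{config}.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  pools <- draw_pools(config)
  lnames <- vapply(config$loci, `[[`, character(1), "name")
  # founder draws: one parentA + one parentB allele per locus
  draw_founders <- function() lapply(seq_len(config$n_founders), function(f)
    setNames(lapply(lnames, function(ln)
      list(A = pools$parentA[[ln]][[sample.int(config$pool_size, 1L)]],
           B = pools$parentB[[ln]][[sample.int(config$pool_size, 1L)]])),
      lnames))
  founder_sig <- function(fd) paste(vapply(lnames, function(ln)
    paste(sort(c(fd[[ln]]$A$profile, fd[[ln]]$B$profile)), collapse = "/"),
    character(1)), collapse = ";")
  founders <- draw_founders()
  if (config$distinct_founders) {
    tries <- 0L
    while (anyDuplicated(vapply(founders, founder_sig, character(1)))) {
      tries <- tries + 1L
      if (tries > 1000L)
        stopf("cannot draw %d founders with distinct SNV signatures; enlarge the profile pools",
              config$n_founders)
      founders <- draw_founders()
    }
  }
  mutate_copies <- function(copies) {
    # SMM on the primary (first) motif only
    n_events <- rbinom(1L, config$generations, config$mu)
    hist <- integer(0)
    if (n_events > 0L) {
      for (e in seq_len(n_events)) {
        step <- sample(c(-1L, 1L), 1L)
        if (copies[1] + step < config$min_copies) step <- 1L
        copies[1] <- copies[1] + step
        hist <- c(hist, step)
      }
    }
    list(copies = copies, history = hist)
  }
  rows <- list()
  truth <- list()
  realized <- list() # per locus: list of list(profile, copies)
  for (p in config$pops) {
    w <- rep_len(p$weights, config$n_founders)
    w <- w / sum(w)
    for (i in seq_len(p$n)) {
      iid <- sprintf("%s_%03d", p$name, i)
      f <- sample.int(config$n_founders, 1L, prob = w)
      row <- list(individual_id = iid, population = p$name)
      for (ln in lnames) {
        for (slot in c("A", "B")) {
          src <- founders[[f]][[ln]][[slot]]
          mut <- mutate_copies(src$copies)
          al <- list(profile = src$profile, copies = mut$copies)
          realized[[ln]] <- c(realized[[ln]], list(al))
          row[[paste0(ln, "_a", if (slot == "A") 1L else 2L)]] <-
            allele_id_string(al)
          truth[[length(truth) + 1L]] <- data.frame(
            individual_id = iid, population = p$name, locus = ln,
            slot = if (slot == "A") 1L else 2L, founder = f,
            origin = if (slot == "A") "parentA" else "parentB",
            n_mutations = length(mut$history),
            net_delta = sum(mut$history),
            history = paste(mut$history, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  individuals <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  # label realized alleles per locus, deterministically by (profile, copies)
  registry <- list()
  for (ln in lnames) {
    ids <- vapply(realized[[ln]], allele_id_string, character(1))
    uq <- realized[[ln]][!duplicated(ids)]
    key <- vapply(uq, allele_id_string, character(1))
    ord <- order(vapply(uq, `[[`, character(1), "profile"),
                 vapply(uq, function(a) paste(sprintf("%04d", a$copies),
                                              collapse = ","), character(1)))
    uq <- uq[ord]; key <- key[ord]
    labels <- sprintf("s%02d", seq_along(uq))
    registry[[ln]] <- list(alleles = uq, key = key, labels = labels)
    for (col in paste0(ln, c("_a1", "_a2")))
      individuals[[col]] <- labels[match(individuals[[col]], key)]
  }
  # build allele records with truth origins
  spec_by_name <- setNames(config$loci, lnames)
  recs <- list()
  for (ln in lnames) {
    reg <- registry[[ln]]
    for (i in seq_along(reg$alleles)) {
      al <- reg$alleles[[i]]
      sp <- if (al$profile %in% spec_by_name[[ln]]$profiles$parentA)
        "parentA" else "parentB"
      recs[[allele_key(ln, reg$labels[i])]] <- structure(
        list(locus = ln, label = reg$labels[i], species = "sim",
             seq = NULL,
             clusters = data.frame(motif = names(al$copies),
                                   copies = as.integer(al$copies),
                                   offset = NA_integer_,
                                   stringsAsFactors = FALSE),
             snv_profile = al$profile,
             signature = paste(sprintf("%s:%d", names(al$copies), al$copies),
                               collapse = "+"),
             origin = sp),
        class = "allele_record")
    }
  }
  alleles <- structure(recs, class = "allele_set")
  fdf <- data.frame(founder = seq_along(founders),
                    signature = vapply(founders, founder_sig, character(1)),
                    stringsAsFactors = FALSE)
  structure(list(individuals = individuals, alleles = alleles, truth = truth,
                 founders = fdf, founder_draws = founders, pools = pools,
                 registry = registry, config = config),
            class = "sim_result")
}

allele_id_string <- function(al)
  paste0(al$profile, "#", paste(al$copies, collapse = ","))

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<simulated cohort> %d individuals, %d loci, %d founder event(s), mu = %g, %d generations\n",
    nrow(x$individuals), length(x$config$loci), x$config$n_founders,
    x$config$mu, x$config$generations))
  invisible(x)
}

#' Locus definitions and parental catalog for a simulation
#'
#' Builds, deterministically from the configuration seed, a
#' \code{locus_set} with reference sequences (random flanks that contain no
#' spurious motif runs and do not extend clusters at the junctions) and the
#' matching diagnostic \code{\link{parental_catalog}}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{loci} (a \code{locus_set}) and \code{catalog}.
#' @export
sim_locus_defs <- function(config) {
  set.seed(config$seed + 10000L)
  loci <- list()
  entries <- list()
  for (l in config$loci) {
    ref_copies <- vapply(l$motifs, function(m)
      max(l$copy_ranges$parentA[[m]][2], l$copy_ranges$parentB[[m]][2]) + 2L,
      integer(1))
    flankL <- clean_flank(l$flank_len, l$motifs, config$min_copies,
                          right_neighbor = l$motifs[1])
    flankR <- clean_flank(l$flank_len, l$motifs, config$min_copies,
                          left_neighbor = l$motifs[length(l$motifs)])
    spacer <- if (length(l$motifs) > 1L)
      vapply(seq_len(length(l$motifs) - 1L), function(i)
        clean_flank(6L, l$motifs, config$min_copies,
                    left_neighbor = l$motifs[i],
                    right_neighbor = l$motifs[i + 1L]), character(1))
    else character(0)
    pieces <- flankL
    for (i in seq_along(l$motifs)) {
      pieces <- c(pieces, paste(rep(l$motifs[i], ref_copies[i]),
                                collapse = ""))
      if (i < length(l$motifs)) pieces <- c(pieces, spacer[i])
    }
    ref <- paste(c(pieces, flankR), collapse = "")
    n_snv <- nchar(l$profiles$parentA[1])
    snv_pos <- seq(4L, by = 7L, length.out = n_snv)
    stopifnot(max(snv_pos) < l$flank_len - 1L)
    loci[[l$name]] <- locus_def(l$name, l$motifs, snv_positions = snv_pos,
                                min_repeats = config$min_copies,
                                reference = ref)
    for (sp in c("parentA", "parentB"))
      for (pr in l$profiles[[sp]])
        entries[[length(entries) + 1L]] <- data.frame(
          locus = l$name, profile = pr, cluster_signature = NA_character_,
          species = sp, stringsAsFactors = FALSE)
  }
  class(loci) <- "locus_set"
  list(loci = loci,
       catalog = parental_catalog(do.call(rbind, entries)))
}

# Random flank containing no motif run that could be called a cluster and no
# full motif copy at a junction with an adjacent cluster.
clean_flank <- function(len, motifs, min_repeats, left_neighbor = NULL,
                        right_neighbor = NULL) {
  probe <- locus_def("probe", motifs, min_repeats = min_repeats)
  repeat {
    fl <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    if (nrow(parse_repeat_structure(fl, probe))) next
    if (!is.null(right_neighbor) &&
        endsWith(fl, right_neighbor)) next
    if (!is.null(left_neighbor) &&
        startsWith(fl, left_neighbor)) next
    return(fl)
  }
}

#' Emit FASTA sequences for the realized alleles of a simulation
#'
#' Constructs each allele's sequence as left flank + clusters + right flank
#' with its SNV states planted at the configured flank positions. The
#' sequences round-trip through \code{\link{parse_repeat_structure}} and
#' \code{\link{extract_snv_profile}} to the same clusters and profile,
#' letting the sequence-level pipeline be tested end to end.
#'
#' @param sim a \code{\link{simulate_cohort}} result.
#' @param path optional FASTA output path.
#' @return list with \code{sequences} (a \code{Biostrings::DNAStringSet}
#'   named \code{locus|sim|label}), \code{loci}, \code{catalog}.
#' @export
emit_sequences <- function(sim, path = NULL) {
  defs <- sim_locus_defs(sim$config)
  seqs <- character(0)
  for (ln in names(sim$registry)) {
    reg <- sim$registry[[ln]]
    ldef <- defs$loci[[ln]]
    # profile states plant the allele's profile; remaining snv chars (if the
    # locus profile is shorter than others) do not exist by construction
    for (i in seq_along(reg$alleles)) {
      al <- reg$alleles[[i]]
      s <- build_allele_sequence(ldef, copies = as.integer(al$copies),
                                 profile = al$profile)
      cl <- parse_repeat_structure(s, ldef)
      if (!identical(as.integer(cl$copies), as.integer(al$copies)))
        stopf("locus %s allele %s: emitted sequence does not round-trip",
              ln, reg$labels[i])
      seqs[paste(ln, "sim", reg$labels[i], sep = "|")] <- s
    }
  }
  ss <- Biostrings::DNAStringSet(seqs)
  if (!is.null(path)) Biostrings::writeXStringSet(ss, path)
  list(sequences = ss, loci = defs$loci, catalog = defs$catalog)
}
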