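small_pops <- function(n1 = 6L, n2 = 4L)
  list(list(name = "P1", n = n1, weights = 1),
       list(name = "P2", n = n2, weights = 1))

# decompose an emitted DNAStringSet without touching disk
read_alleles_fasta_from_set <- function(em) {
  out <- list()
  for (i in seq_along(em$sequences)) {
    parts <- strsplit(names(em$sequences)[i], "|", fixed = TRUE)[[1]]
    out[[paste(parts[1], parts[3], sep = "|")]] <-
      allele_record(as.character(em$sequences[[i]]), em$loci[[parts[1]]],
                    label = parts[3], species = parts[2])
  }
  out
}

sampled_founders <- function(sim) length(unique(sim$truth$founder))

cfg_small <- function(F = 2L, mu = 0, gen = 10L, seed = 1L) {
  w <- if (F == 1L) 1 else c(0.7, rep(0.3 / (F - 1), F - 1))
  sim_config(n_founders = F, generations = gen, mu = mu, seed = seed,
             pops = list(list(name = "P1", n = 6L, weights = w),
                         list(name = "P2", n = 4L, weights = w)))
}

test_that("seeded simulation replays bit-identically", {
  s1 <- simulate_cohort(cfg_small(F = 3L, mu = 0.02, seed = 7L))
  s2 <- simulate_cohort(cfg_small(F = 3L, mu = 0.02, seed = 7L))
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_parental_pools(cfg_small(seed = 7L))
  p2 <- simulate_parental_pools(cfg_small(seed = 7L))
  expect_identical(p1, p2)
})

test_that("parental pools carry species-diagnostic profiles and ranges", {
  cfg <- cfg_small(seed = 3L)
  pools <- simulate_parental_pools(cfg)
  for (l in cfg$loci) {
    for (sp in c("parentA", "parentB")) {
      pool <- pools[[sp]][[l$name]]
      expect_length(pool, cfg$pool_size)
      for (al in pool) {
        expect_true(al$profile %in% l$profiles[[sp]])
        for (m in names(al$copies)) {
          r <- l$copy_ranges[[sp]][[m]]
          expect_gte(al$copies[[m]], r[1])
          expect_lte(al$copies[[m]], r[2])
        }
      }
    }
  }
})

test_that("a shared profile between species triggers the collision warning", {
  loci <- sim_default_loci()
  loci[[1]]$profiles$parentB[1] <- loci[[1]]$profiles$parentA[1]
  cfg <- sim_config(loci = loci, n_founders = 1L, seed = 2L,
                    pops = small_pops(2L, 2L), distinct_founders = FALSE)
  expect_warning(simulate_parental_pools(cfg), "both species")
})

test_that("with mu = 0 every genotype equals its founder genotype", {
  for (F in c(1L, 3L)) {
    sim <- simulate_cohort(cfg_small(F = F, mu = 0, seed = 11L + F))
    gt <- genotype_table(sim$individuals)
    expect_equal(nrow(gt$genotypes), sampled_founders(sim))
    fc <- classify_founders(gt, sim$alleles)
    expect_equal(fc$n_classes, sampled_founders(sim))
    # no mutation events recorded
    expect_true(all(sim$truth$n_mutations == 0L))
  }
})

test_that("SMM mutations never alter founder-class recovery", {
  for (seed in 1:5) {
    sim <- simulate_cohort(cfg_small(F = 3L, mu = 0.05, gen = 20L,
                                     seed = seed))
    gt <- genotype_table(sim$individuals)
    fc <- classify_founders(gt, sim$alleles)
    expect_equal(fc$n_classes, sampled_founders(sim))
    # truth founder ids map one-to-one onto inferred classes
    ind <- gt$individuals
    tru <- unique(sim$truth[, c("individual_id", "founder")])
    ind$founder <- tru$founder[match(ind$individual_id, tru$individual_id)]
    ind$class <- fc$genotype_class[as.character(ind$genotype_id)]
    expect_equal(length(unique(paste(ind$founder, ind$class))),
                 length(unique(ind$founder)))
  }
})

test_that("repeat counts respect the reflecting lower bound", {
  cfg <- sim_config(n_founders = 1L, generations = 400L, mu = 0.2, seed = 5L,
                    pops = list(list(name = "P", n = 6L, weights = 1)))
  sim <- simulate_cohort(cfg)
  for (rec in sim$alleles)
    expect_true(all(rec$clusters$copies >= cfg$min_copies))
})

test_that("emitted sequences round-trip through the sequence pipeline", {
  sim <- simulate_cohort(cfg_small(F = 2L, mu = 0.05, gen = 10L, seed = 9L))
  em <- emit_sequences(sim)
  al2 <- read_alleles_fasta_from_set(em)
  for (key in names(sim$alleles)) {
    expect_equal(al2[[key]]$clusters$motif, sim$alleles[[key]]$clusters$motif)
    expect_equal(al2[[key]]$clusters$copies, sim$alleles[[key]]$clusters$copies)
    expect_equal(al2[[key]]$snv_profile, sim$alleles[[key]]$snv_profile)
  }
  # and FASTA writing itself round-trips through the file reader
  fa <- tempfile(fileext = ".fasta")
  emit_sequences(sim, path = fa)
  al3 <- read_alleles_fasta(fa, em$loci)
  expect_setequal(names(al3), names(sim$alleles))
})

test_that("simulated origins agree with catalog assignment on sequences", {
  sim <- simulate_cohort(cfg_small(F = 2L, mu = 0, seed = 13L))
  em <- emit_sequences(sim)
  fa <- tempfile(fileext = ".fasta")
  emit_sequences(sim, path = fa)
  al <- assign_parental_origin(read_alleles_fasta(fa, em$loci), em$catalog)
  for (key in names(al))
    expect_equal(al[[key]]$origin, sim$alleles[[key]]$origin)
})
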