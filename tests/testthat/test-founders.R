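# Shared fixture-level objects for founder tests
fx_env <- new.env()
fixture_fit <- function() {
  if (is.null(fx_env$fit)) {
    fx <- load_fixture("armeniaca_t2")
    fx_env$fx <- fx
    fx_env$gt <- genotype_table(fx$individuals)
    fx_env$fc <- classify_founders(fx_env$gt, fx$alleles)
  }
  fx_env
}

test_that("SNV combinations carry the expected per-locus profile pairs", {
  e <- fixture_fit()
  sig1 <- snv_combination(e$gt, e$fx$alleles, 1L)
  expect_match(sig1, "Du47G:TAGT/TTCA")
  expect_match(sig1, "Du215:ACT/TGC")
  expect_match(sig1, "Du281:C/T")
  expect_match(sig1, "Du323:AC/CT")
  # Du47G homozygote 5+5 -> TTCA/TTCA
  hom <- e$gt$genotypes[e$gt$genotypes$Du47G_a1 == "5" &
                          e$gt$genotypes$Du47G_a2 == "5", "id"]
  for (i in hom)
    expect_match(snv_combination(e$gt, e$fx$alleles, i), "Du47G:TTCA/TTCA")
  # Du47G 6+7 -> TTCA/AAGA (sorted AAGA/TTCA)
  g13 <- e$gt$genotypes[e$gt$genotypes$Du47G_a1 == "6", "id"]
  expect_match(snv_combination(e$gt, e$fx$alleles, g13), "Du47G:AAGA/TTCA")
})

test_that("fixture genotypes partition into three founder classes", {
  e <- fixture_fit()
  fc <- e$fc
  expect_equal(fc$n_classes, 3L)
  expect_true(fc$lower_bound)
  expect_equal(fc$classes$n_genotypes, c(9L, 3L, 1L))
  expect_equal(fc$classes$n_individuals, c(106L, 4L, 1L))
  # partition property: every genotype in exactly one class
  all_members <- unlist(fc$members)
  expect_setequal(all_members, e$gt$genotypes$id)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("a single genotype forms a single class", {
  a <- make_cohort(list(list(pop = "P", L1 = c("1", "2"))))
  al <- make_allele_set(list(
    list(locus = "L1", label = "1", profile = "A", motifs = "GATA",
         copies = 5L),
    list(locus = "L1", label = "2", profile = "C", motifs = "GATA",
         copies = 7L)))
  fc <- classify_founders(genotype_table(a), al)
  expect_equal(fc$n_classes, 1L)
})

test_that("merging genotype sets never lowers the class count below either part", {
  e <- fixture_fit()
  ids <- e$gt$genotypes$id
  nclass <- function(rows) {
    sub <- e$gt$individuals[e$gt$individuals$genotype_id %in% rows, ]
    classify_founders(genotype_table(sub[, setdiff(names(sub), "genotype_id")]),
                      e$fx$alleles)$n_classes
  }
  set.seed(3)
  for (i in 1:5) {
    a <- sample(ids, 4)
    b <- sample(ids, 4)
    expect_gte(nclass(union(a, b)), max(nclass(a), nclass(b)))
  }
})

test_that("mutation attribution reports SMM steps within a class", {
  e <- fixture_fit()
  # genotypes 1 and 2 differ by Du47G allele 5 (12 repeats) vs 4 (11)
  me <- mutation_attribution(e$gt, e$fx$alleles, 1L, 2L)
  expect_equal(nrow(me$changes), 1L)
  expect_equal(me$changes$locus, "Du47G")
  expect_equal(me$changes$type, "smm")
  expect_equal(me$step_count, 1)
  expect_error(mutation_attribution(e$gt, e$fx$alleles, 1L, 1L), "distinct")
  # class II vs class I is a founder difference, not a mutation
  expect_error(mutation_attribution(e$gt, e$fx$alleles, 1L, 13L),
               "founder differences")
})

test_that("simulated single-step mutants attribute to one SMM step", {
  cfg <- sim_config(n_founders = 1L, generations = 1L, mu = 0, seed = 5,
                    pops = list(list(name = "P", n = 2L, weights = 1)))
  sim <- simulate_cohort(cfg)
  ind <- sim$individuals
  # plant one +1 step at the first locus's first allele of individual 2
  loc <- sub("_a1$", "", grep("_a1$", names(ind), value = TRUE))[1]
  lab <- ind[[paste0(loc, "_a1")]][2]
  rec <- sim$alleles[[paste(loc, lab, sep = "|")]]
  mut <- rec
  mut$label <- "mut"
  mut$clusters$copies[1] <- mut$clusters$copies[1] + 1L
  sim$alleles[[paste(loc, "mut", sep = "|")]] <- mut
  ind[[paste0(loc, "_a1")]][2] <- "mut"
  gt <- genotype_table(ind)
  expect_equal(nrow(gt$genotypes), 2L)
  me <- mutation_attribution(gt, sim$alleles, gt$genotypes$id[1],
                             gt$genotypes$id[2])
  expect_equal(me$step_count, 1)
  expect_equal(me$changes$type, "smm")
})
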