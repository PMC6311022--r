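round_half_up2 <- function(x) floor(x * 100 + 0.5) / 100

test_that("allele counts pool gene copies, homozygotes counting twice", {
  a <- make_cohort(list(list(pop = "P", L1 = c("2", "3")),
                        list(pop = "P", L1 = c("2", "3")),
                        list(pop = "P", L1 = c("5", "5"))))
  cnt <- allele_counts(a, "L1")
  expect_equal(as.integer(cnt), c(2L, 2L, 2L))
  expect_equal(names(cnt), c("2", "3", "5"))
  expect_equal(unname(attr(cnt, "freq")), rep(1 / 3, 3))
})

test_that("unbiased expected heterozygosity matches hand-derived values", {
  # two alleles at 0.5 in n individuals: H_E = (2n/(2n-1)) * 0.5
  expect_equal(expected_heterozygosity(c(a = 21L, b = 21L)),
               42 / 41 * 0.5, tolerance = 1e-12)
  expect_equal(round_half_up2(expected_heterozygosity(c(a = 21, b = 21))), 0.51)
  expect_equal(round_half_up2(expected_heterozygosity(c(a = 17, b = 17))), 0.52)
  expect_equal(round_half_up2(expected_heterozygosity(c(a = 2, b = 2))), 0.67)
  expect_equal(expected_heterozygosity(c(a = 10L)), 0)
  expect_equal(expected_heterozygosity(c(a = 5, b = 5), unbiased = FALSE), 0.5)
})

test_that("H_E is relabeling invariant and maximal at equal frequencies", {
  cnt <- c(x = 7L, y = 2L, z = 5L)
  perm <- c(z = 5L, x = 7L, y = 2L)
  expect_equal(expected_heterozygosity(cnt), expected_heterozygosity(perm))
  even <- c(a = 5L, b = 5L, c = 4L)  # closest to even for 14 copies, 3 alleles
  skew <- c(a = 10L, b = 3L, c = 1L)
  expect_gt(expected_heterozygosity(even), expected_heterozygosity(skew))
})

test_that("rarefied richness matches exact enumeration on a small pool", {
  # oracle: enumerate all C(6,3) subsamples of counts (3,2,1), count distinct
  pool <- rep(c("a", "b", "c"), c(3, 2, 1))
  combs <- combn(6, 3)
  oracle <- mean(apply(combs, 2, function(ix) length(unique(pool[ix]))))
  expect_equal(rarefied_richness(c(a = 3L, b = 2L, c = 1L), 3L), oracle,
               tolerance = 1e-12)
})

test_that("rarefaction closed form reproduces table-derived values", {
  expect_equal(round_half_up2(rarefied_richness(c(21, 21), 4L)), 1.89)
  expect_equal(round_half_up2(rarefied_richness(c(8, 8), 4L)), 1.92)
  expect_equal(rarefied_richness(c(2, 2), 4L), 2)  # every allele always drawn
  expect_error(rarefied_richness(c(1, 1), 4L), "exceeds")
})

test_that("richness is monotone in g and equals N at g = 2n", {
  cnt <- c(a = 9L, b = 4L, c = 2L, d = 1L)
  g <- 2:16
  rs <- vapply(g, function(gg) rarefied_richness(cnt, gg), numeric(1))
  expect_true(all(diff(rs) > -1e-12))
  expect_equal(rs[length(rs)], 4)
  expect_true(all(rs <= 4 + 1e-12))
  expect_true(all(rs >= 1))
})

test_that("observed heterozygosity is the heterozygote fraction", {
  a <- make_cohort(c(
    replicate(6, list(pop = "P", L1 = c("1", "2")), simplify = FALSE),
    list(list(pop = "P", L1 = c("2", "2")))))
  expect_equal(observed_heterozygosity(a, "L1"), 6 / 7)
  expect_equal(observed_heterozygosity(a[1:6, ], "L1"), 1)
  expect_equal(observed_heterozygosity(a[7, ], "L1"), 0)
})

test_that("clonal cohorts give H_O of exactly 0 or 1 and n-driven H_E", {
  one <- make_cohort(replicate(9, list(pop = "P", L1 = c("1", "2")),
                               simplify = FALSE))
  st <- diversity_stats(one, min_pop_n = 1L, g = 2L)
  expect_equal(st$observed_het, 1)
  expect_equal(st$expected_het, 18 / 17 * 0.5, tolerance = 1e-12)
})

test_that("the filter stage drops genotypes and small populations", {
  fx <- load_fixture("armeniaca_t2")
  gt <- genotype_table(fx$individuals)
  fc <- classify_founders(gt, fx$alleles)
  minor <- unlist(fc$members[-1])
  st <- diversity_stats(fx$individuals, exclude_genotypes = minor)
  expect_equal(attr(st, "g"), 4L)
  expect_setequal(attr(st, "dropped_populations"), c("Sevan", "Lchashen"))
  expect_equal(sort(unique(st$population)), sort(setdiff(
    unique(fx$individuals$population), c("Sevan", "Lchashen"))))
  expect_equal(st$n_individuals[st$population == "Dsegh"][1], 2L)
  expect_equal(st$n_individuals[st$population == "Harich"][1], 17L)
  expect_true(all(st$rarefied_richness <= st$n_alleles + 1e-12))
  expect_true(all(st$rarefied_richness >= 1))
})

test_that("the report layer renders Total and Mean rows", {
  fx <- load_fixture("armeniaca_t2")
  gt <- genotype_table(fx$individuals)
  fc <- classify_founders(gt, fx$alleles)
  st <- diversity_stats(fx$individuals,
                        exclude_genotypes = unlist(fc$members[-1]))
  rep <- report_diversity(st)
  tot <- rep[rep$population == "Total" & rep$locus == "Du281", ]
  expect_equal(tot$N, "4")
  expect_equal(tot$R_S, "4.00")  # richness at full pooled size equals N
  du215 <- rep[rep$locus == "Du215" & rep$population == "Artavaz", ]
  expect_equal(du215$H_E, "0.51")
  expect_equal(du215$R_S, "1.89")
  expect_true(any(grepl("\\+/- ", rep$H_E)))
})
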