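# Helper: fixture fit shared across network tests
net_env <- new.env()
net_fixture <- function() {
  if (is.null(net_env$fx)) {
    net_env$fx <- load_fixture("armeniaca_t2")
    net_env$gt <- genotype_table(net_env$fx$individuals)
    net_env$fc <- classify_founders(net_env$gt, net_env$fx$alleles)
  }
  net_env
}

test_that("codes are equal-length and identical genotypes code identically", {
  e <- net_fixture()
  codes <- encode_genotypes(e$gt, e$fx$alleles)
  expect_equal(nrow(codes$repeat_mat), 13L)
  expect_equal(nrow(codes$snv_mat), 13L)
  D <- code_distances(codes)
  expect_true(all(D[upper.tri(D)] > 0))  # all 13 compositions distinct
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 13))
})

test_that("step distances equal brute-force character comparison", {
  e <- net_fixture()
  codes <- encode_genotypes(e$gt, e$fx$alleles)
  D <- code_distances(codes)
  brute <- function(i, j)
    sum(abs(codes$repeat_mat[i, ] - codes$repeat_mat[j, ])) +
      sum(codes$snv_mat[i, ] != codes$snv_mat[j, ])
  for (i in 1:12) for (j in (i + 1):13)
    expect_equal(D[i, j], brute(i, j))
  # genotype 1 vs 2 differ only by the Du47G 5 vs 4 repeat count (12 vs 11)
  expect_equal(D["1", "2"], 1)
})

test_that("class-I network is a star around the widespread clone", {
  e <- net_fixture()
  ids <- e$fc$members[[1]]
  net <- clone_network(e$gt, e$fx$alleles, ids)
  hs <- hub_statistics(net)
  expect_equal(hs$id[1], as.character(e$gt$most_frequent))
  expect_equal(hs$rank[1], 1L)
  expect_equal(sum(hs$rank == 1L), 1L)  # unique maximum-degree hub
  expect_lte(hs$eccentricity[hs$id == "1"], 2)
  expect_true(all(hs$eccentricity >= hs$eccentricity[hs$id == "1"]))
})

test_that("tie retention keeps equally parsimonious edges (network, not tree)", {
  # genotype 6-like case: two 1-step neighbors both retained at one level
  al <- make_allele_set(list(
    list(locus = "L", label = "1", profile = "A", motifs = "GATA", copies = 10L),
    list(locus = "L", label = "2", profile = "A", motifs = "GATA", copies = 11L),
    list(locus = "M", label = "1", profile = "C", motifs = "GATA", copies = 7L),
    list(locus = "M", label = "2", profile = "C", motifs = "GATA", copies = 8L)))
  a <- make_cohort(list(
    list(pop = "P", L = c("1", "1"), M = c("1", "1")),
    list(pop = "P", L = c("2", "2"), M = c("1", "1")),
    list(pop = "P", L = c("1", "1"), M = c("2", "2")),
    list(pop = "P", L = c("2", "2"), M = c("2", "2"))))
  gt <- genotype_table(a)
  net <- clone_network(gt, al, gt$genotypes$id)
  # 4-cycle: all four 2-step... here L/M homozygous diffs are 2 steps each;
  # all pairs at distance 2 or 4; level-2 snapshot keeps the 4-cycle edges
  expect_equal(nrow(net$edges), 4L)
  expect_true(all(net$edges$steps == 2))
})

test_that("multi-step edges materialize unsampled intermediate nodes", {
  al <- make_allele_set(list(
    list(locus = "L", label = "1", profile = "A", motifs = "GATA", copies = 10L),
    list(locus = "L", label = "2", profile = "A", motifs = "GATA", copies = 13L)))
  a <- make_cohort(list(list(pop = "P", L = c("1", "1")),
                        list(pop = "P", L = c("2", "2"))))
  gt <- genotype_table(a)
  net <- clone_network(gt, al, gt$genotypes$id)
  expect_equal(net$edges$steps, 6)
  expect_equal(sum(!net$nodes$sampled), 5L)
  hs <- hub_statistics(net)
  expect_equal(hs$eccentricity, c(6, 6))
})

test_that("the connection limit leaves distant pairs unconnected", {
  al <- make_allele_set(list(
    list(locus = "L", label = "1", profile = "A", motifs = "GATA", copies = 10L),
    list(locus = "L", label = "2", profile = "A", motifs = "GATA", copies = 20L)))
  a <- make_cohort(list(list(pop = "P", L = c("1", "1")),
                        list(pop = "P", L = c("2", "2"))))
  gt <- genotype_table(a)
  net <- clone_network(gt, al, gt$genotypes$id, connection_limit = 5)
  expect_equal(nrow(net$edges), 0L)
  expect_error(hub_statistics(net), "not connected")
})

test_that("path topology yields the middle node as hub", {
  al <- make_allele_set(lapply(1:3, function(i)
    list(locus = "L", label = as.character(i), profile = "A",
         motifs = "GATA", copies = 9L + i)))
  a <- make_cohort(list(list(pop = "P", L = c("1", "1")),
                        list(pop = "P", L = c("2", "2")),
                        list(pop = "P", L = c("3", "3"))))
  gt <- genotype_table(a)
  net <- clone_network(gt, al, gt$genotypes$id)
  hs <- hub_statistics(net)
  mid <- gt$genotypes$id[gt$genotypes$L_a1 == "2"]
  expect_equal(hs$id[1], as.character(mid))
  expect_equal(hs$degree[1], 2L)
})

test_that("network exports write GraphML and edge TSV", {
  e <- net_fixture()
  net <- clone_network(e$gt, e$fx$alleles, e$fc$members[[1]])
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  write_network(net, graphml = gml, edges_tsv = tsv)
  expect_true(file.exists(gml))
  expect_match(readLines(gml, n = 2)[2], "graphml", ignore.case = TRUE)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
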