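test_that("species heterozygosity summaries aggregate per-sample QC", {
  gm <- gm_from_rows(list(
    a = c("AA", "AB", "AB", "AB", "AB", "AA", "AA", "AA", "AA", "AA"),
    b = c("AB", "AB", "AB", "AA", "AA", "AA", "AA", "AA", "AA", "AA"),
    c = c("AB", "AB", "AB", "AB", "AB", "AB", "AB", "AB", "AA", "AA")
  ))
  meta <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    species = c("sp1", "sp1", "sp2")
  )
  hs <- species_het_summary(gm, meta)
  sp1 <- hs[hs$species == "sp1", ]
  expect_equal(sp1$n_accessions, 2L)
  expect_equal(sp1$mean_obs_het, mean(c(0.4, 0.3)))
  expect_equal(sp1$min_obs_het, 0.3)
  expect_equal(sp1$max_obs_het, 0.4)
  sp2 <- hs[hs$species == "sp2", ]
  expect_equal(sp2$mean_obs_het, sp2$min_obs_het)
  expect_equal(sp2$mean_obs_het, sp2$max_obs_het)
})

test_that("wild clusters show lower heterozygosity than the cultivated cluster", {
  sim <- simulate_panel(tiny_config(seed = 14))
  hs <- species_het_summary(sim$genotypes, sim$samples)
  expect_lt(
    hs$mean_obs_het[hs$species == "V. riparia"],
    hs$mean_obs_het[hs$species == "V. vinifera ssp. sativa"]
  )
})

test_that("genotype PCA satisfies the ordination contracts", {
  sim <- simulate_panel(tiny_config(seed = 15))
  pca <- genotype_pca(sim$genotypes, n_components = 6)
  ve <- pca$var_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-8)
  expect_equal(nrow(pca$scores), nrow(sim$genotypes))
  # deterministic including axis signs
  pca2 <- genotype_pca(sim$genotypes, n_components = 6)
  expect_equal(pca$scores, pca2$scores)
})

test_that("planted population structure separates on the first axis", {
  sim <- simulate_panel(tiny_config(seed = 16))
  pca <- genotype_pca(sim$genotypes)
  sc <- dplyr::inner_join(pca$scores, sim$samples, by = "sample_id")
  wild <- sc$wild # offspring carry FALSE; founders follow their population
  # mean silhouette of the two clusters on PC1 must be positive
  x <- sc$PC1
  sil <- vapply(seq_along(x), function(i) {
    own <- mean(abs(x[i] - x[wild == wild[i] & seq_along(x) != i]))
    other <- mean(abs(x[i] - x[wild != wild[i]]))
    (other - own) / max(own, other)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0)
})

test_that("duplicate pairs sit nearly on top of each other in the PCA", {
  sim <- simulate_panel(tiny_config(seed = 17))
  pca <- genotype_pca(sim$genotypes)
  d <- sim$truth$duplicates
  sc <- pca$scores
  x1 <- sc$PC1[sc$sample_id == d$source]
  x2 <- sc$PC1[sc$sample_id == d$clone]
  expect_lt(abs(x1 - x2), 0.01 * diff(range(sc$PC1)))
})

test_that("the MAF floor is enforced", {
  gm <- gm_from_rows(list(
    a = c("AA", "AA"), b = c("AA", "AA"), c = c("AA", "AB")
  ))
  expect_error(genotype_pca(gm, maf_floor = 0.4), "MAF floor")
})

test_that("concordance arithmetic, zygosity mode and missing handling", {
  set.seed(51)
  n <- 100
  calls <- sample(c("AA", "AB", "BB"), n, replace = TRUE)
  ma <- matrix(calls, 1, n, dimnames = list("s1", sprintf("m%03d", 1:n)))
  mb <- ma
  # three zygosity flips among 100 shared called markers
  flip <- c(5, 40, 77)
  mb[1, flip] <- ifelse(ma[1, flip] == "AB", "AA", "AB")
  cc <- platform_concordance(genotype_matrix(ma), genotype_matrix(mb))
  expect_equal(cc$n_shared_markers, 100L)
  expect_equal(cc$concordance_perc, 97)
  # identical matrices give 100%
  cc2 <- platform_concordance(genotype_matrix(ma), genotype_matrix(ma))
  expect_equal(cc2$concordance_perc, 100)
  # markers missing on either platform are excluded
  mb2 <- mb
  mb2[1, 1:10] <- "NC"
  cc3 <- platform_concordance(genotype_matrix(ma), genotype_matrix(mb2))
  expect_equal(cc3$n_shared_markers, 90L)
})

test_that("strict mode with allele-swap harmonisation matches zygosity on swapped data", {
  set.seed(52)
  n <- 200
  calls <- matrix(
    sample(c("AA", "AB", "BB"), 5 * n, replace = TRUE), 5, n,
    dimnames = list(sprintf("s%d", 1:5), sprintf("m%03d", 1:n))
  )
  swapped <- ifelse(calls == "AA", "BB", ifelse(calls == "BB", "AA", calls))
  # platform B labels half the markers with swapped alleles
  mb <- calls
  mb[, 1:100] <- swapped[, 1:100]
  za <- platform_concordance(
    genotype_matrix(calls), genotype_matrix(mb),
    mode = "zygosity"
  )
  st <- platform_concordance(
    genotype_matrix(calls), genotype_matrix(mb),
    mode = "strict", harmonize = TRUE
  )
  expect_equal(st$concordance_perc, za$concordance_perc)
  expect_equal(st$concordance_perc, rep(100, 5))
})

test_that("concordance is invariant to marker order", {
  set.seed(53)
  calls <- matrix(
    sample(c("AA", "AB", "BB", "NC"), 3 * 50, replace = TRUE), 3, 50,
    dimnames = list(c("x", "y", "z"), sprintf("m%02d", 1:50))
  )
  gma <- genotype_matrix(calls)
  gmb <- genotype_matrix(calls[, sample(50)])
  cc <- platform_concordance(gma, gmb)
  expect_equal(cc$concordance_perc, rep(100, 3))
})
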