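test_that("duo statistics match a hand-enumerated example", {
  gm <- gm_from_rows(list(
    a = c("AA", "AB", "BB", "NC"),
    b = c("BB", "AA", "BB", "AA")
  ))
  duo <- compute_duo(gm, "a", "b")
  expect_equal(duo$n_compared, 3L)
  expect_equal(duo$n_opposing_hom, 1L)
  expect_equal(duo$duo_errors_perc, 100 / 3, tolerance = 1e-10)
  expect_equal(duo$het_mismatch_A1A2, 1L)
  expect_equal(duo$het_mismatch_A2A1, 0L)
  expect_equal(duo$perc_mismatches, 100 / 3, tolerance = 1e-10)
})

test_that("a sample against itself shows zero error", {
  gm <- gm_from_rows(list(a = c("AA", "AB", "BB", "NC")))
  m <- rbind(unclass(gm), unclass(gm))
  rownames(m) <- c("a", "a2")
  duo <- compute_duo(genotype_matrix(m), "a", "a2")
  expect_equal(duo$n_opposing_hom, 0L)
  expect_equal(duo$het_mismatch_A1A2, 0L)
  expect_equal(duo$het_mismatch_A2A1, 0L)
})

test_that("swapping a duo preserves symmetric fields and swaps directional counters", {
  set.seed(31)
  calls <- matrix(
    sample(c("AA", "AB", "BB", "NC"), 60 * 500, replace = TRUE,
      prob = c(0.3, 0.3, 0.3, 0.1)
    ), 60, 500,
    dimnames = list(sprintf("s%02d", 1:60), sprintf("m%03d", 1:500))
  )
  gm <- genotype_matrix(calls)
  ids <- sample_ids(gm)
  for (k in seq_len(200)) {
    pr <- sample(ids, 2)
    d1 <- compute_duo(gm, pr[1], pr[2])
    d2 <- compute_duo(gm, pr[2], pr[1])
    expect_equal(d1$n_compared, d2$n_compared)
    expect_equal(d1$n_opposing_hom, d2$n_opposing_hom)
    expect_equal(d1$duo_errors_perc, d2$duo_errors_perc)
    expect_equal(d1$perc_mismatches, d2$perc_mismatches)
    expect_equal(d1$het_mismatch_A1A2, d2$het_mismatch_A2A1)
    expect_equal(d1$het_mismatch_A2A1, d2$het_mismatch_A1A2)
  }
})

test_that("the vectorised all-pairs table agrees with per-pair computation", {
  set.seed(32)
  calls <- matrix(
    sample(c("AA", "AB", "BB", "NC"), 20 * 200, replace = TRUE), 20, 200,
    dimnames = list(sprintf("s%02d", 1:20), sprintf("m%03d", 1:200))
  )
  gm <- genotype_matrix(calls)
  tab <- all_duos(gm)
  expect_equal(nrow(tab), choose(20, 2))
  for (k in sample(nrow(tab), 25)) {
    ref <- compute_duo(gm, tab$sample_a[k], tab$sample_b[k])
    expect_equal(tab$n_compared[k], ref$n_compared)
    expect_equal(tab$n_opposing_hom[k], ref$n_opposing_hom)
    expect_equal(tab$het_mismatch_A1A2[k], ref$het_mismatch_A1A2)
    expect_equal(tab$het_mismatch_A2A1[k], ref$het_mismatch_A2A1)
  }
})

test_that("trio incompatibility equals the gamete-pairing oracle on all 27 combinations", {
  lv <- c("AA", "AB", "BB")
  combos <- expand.grid(o = lv, p1 = lv, p2 = lv, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    rows[[paste0("o", i)]] <- combos$o[i]
    rows[[paste0("p", i)]] <- combos$p1[i]
    rows[[paste0("q", i)]] <- combos$p2[i]
  }
  # one marker per combination, three samples each
  m <- matrix("NC", 3, nrow(combos), dimnames = list(
    c("o", "p", "q"), sprintf("c%02d", seq_len(nrow(combos)))
  ))
  m["o", ] <- combos$o
  m["p", ] <- combos$p1
  m["q", ] <- combos$p2
  gm <- genotype_matrix(m)
  trio <- compute_trio(gm, "o", "p", "q")
  expected_inc <- sum(!mapply(oracle_trio_compatible, combos$o, combos$p1, combos$p2))
  expect_equal(trio$n_evaluable, 27L)
  expect_equal(trio$n_incompatible, expected_inc)
  # forced transmission and the textbook impossible cases
  gm2 <- gm_from_rows(list(o = c("AB", "AA"), p = c("AA", "BB"), q = c("BB", "BB")))
  t2 <- compute_trio(gm2, "o", "p", "q")
  expect_equal(t2$n_incompatible, 1L) # AB from AAxBB fine; AA from BBxBB impossible
})

test_that("duplicate detection reports identical and near-identical pairs only", {
  set.seed(33)
  calls <- matrix(
    sample(c("AA", "AB", "BB"), 10 * 300, replace = TRUE), 10, 300,
    dimnames = list(sprintf("s%02d", 1:10), sprintf("m%03d", 1:300))
  )
  calls["s02", ] <- calls["s01", ]
  gm <- genotype_matrix(calls)
  dup <- find_duplicates(gm, max_diff = 10)
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$n_diff, 0L)
  expect_setequal(c(dup$sample_a, dup$sample_b), c("s01", "s02"))
})

test_that("divergent founders are never reported as duplicates", {
  sim <- simulate_panel(tiny_config(seed = 6))
  dup <- find_duplicates(sim$genotypes, max_diff = 10)
  planted <- sim$truth$duplicates
  expect_equal(nrow(dup), nrow(planted))
  expect_setequal(
    paste(dup$sample_a, dup$sample_b),
    paste(
      pmin(planted$source, planted$clone), pmax(planted$source, planted$clone)
    )
  )
})

test_that("pedigree classes and relationship coefficients are derived correctly", {
  ped <- tibble::tibble(
    sample_id = c("gm", "gf", "m", "f", "u", "c1", "c2", "h", "x"),
    mother_id = c("", "", "gm", "", "gm", "m", "m", "m", ""),
    father_id = c("", "", "gf", "", "gf", "f", "f", "x", "")
  )
  rel <- pedigree_relationships(ped)
  cls <- stats::setNames(rel$class, paste(rel$sample_a, rel$sample_b))
  r <- stats::setNames(rel$r, paste(rel$sample_a, rel$sample_b))
  expect_equal(cls[["c1 m"]], "PO")
  expect_equal(r[["c1 m"]], 0.5)
  expect_equal(cls[["c1 c2"]], "FS")
  expect_equal(r[["c1 c2"]], 0.5)
  expect_equal(cls[["c1 gm"]], "GP")
  expect_equal(r[["c1 gm"]], 0.25)
  expect_equal(cls[["c1 h"]], "HS") # shared mother only
  expect_equal(r[["c1 h"]], 0.25)
  expect_equal(cls[["c1 u"]], "UN") # u is a full sibling of m
  expect_equal(r[["c1 u"]], 0.25)
  expect_equal(cls[["c1 x"]], "OTHER")
})

test_that("threshold relaxation captures all pedigree-known PO pairs", {
  sim <- simulate_panel(tiny_config(seed = 8))
  rel <- infer_relationships(sim$genotypes, sim$truth$pedigree,
    duo_threshold_init = 0.01
  )
  # initial threshold is far too strict; relaxation must lift it to the
  # maximum known-PO error so every planted duo is recovered
  key <- paste(rel$duos$sample_a, rel$duos$sample_b)
  po <- sim$truth$po_duos
  want <- paste(pmin(po$parent, po$offspring), pmax(po$parent, po$offspring))
  expect_true(all(want %in% key))
  expect_gte(rel$threshold_used, 0.01)
})

test_that("without pedigree-known pairs the initial threshold is used", {
  sim <- simulate_panel(tiny_config(seed = 8))
  empty_ped <- tibble::tibble(
    sample_id = character(0), mother_id = character(0), father_id = character(0)
  )
  rel <- infer_relationships(sim$genotypes, empty_ped, duo_threshold_init = 0.4)
  expect_equal(rel$threshold_used, 0.4)
})

test_that("iterative curation reaches a fixed point under the error threshold", {
  sim <- simulate_panel(tiny_config(seed = 10))
  cur <- run_iterative_curation(sim$genotypes, sim$truth$pedigree)
  expect_true(cur$converged)
  # fixed-point property: recomputed error rates on kept markers are all
  # at or below the threshold
  rel <- cur$relationships
  fm <- filter_mendelian(
    cur$genotypes,
    duos = rel$duos[, c("sample_a", "sample_b")],
    trios = rel$trios[, c("offspring", "parent1", "parent2")]
  )
  expect_equal(length(fm$removed), 0L)
  rates <- fm$table$error_rate
  expect_true(all(is.na(rates) | rates <= 0.03))
})

test_that("the relationship PCA projects OTHER pairs without touching the axes", {
  sim <- simulate_panel(tiny_config(seed = 12))
  labels <- pedigree_relationships(sim$truth$pedigree)
  tab <- all_duos(sim$genotypes)
  fit_all <- classify_relationships(tab, labels)
  keep <- paste(labels$sample_a, labels$sample_b)[labels$class != "OTHER"]
  fit_act <- classify_relationships(
    tab[paste(tab$sample_a, tab$sample_b) %in% keep, ], labels
  )
  expect_equal(fit_all$var_explained, fit_act$var_explained)
  expect_equal(fit_all$rotation, fit_act$rotation)
  # active coordinates identical whether or not supplementaries are present
  act <- fit_all$pairs[!fit_all$pairs$supplementary, ]
  expect_equal(
    act[order(act$sample_a, act$sample_b), ]$PC1,
    fit_act$pairs[order(fit_act$pairs$sample_a, fit_act$pairs$sample_b), ]$PC1
  )
  # per-axis variable contributions sum to 100%
  expect_equal(unname(colSums(fit_all$contributions)), rep(100, 4))
  expect_error(
    classify_relationships(tab[1:5, ], labels[0, ]),
    "fewer than 3"
  )
})
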