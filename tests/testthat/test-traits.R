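colour_collapse <- c(
  `6` = "colored", `5` = "colored", `2` = "non_colored", `1` = "non_colored"
)

test_that("a dominant colour rule scores carriers and lists wrong samples", {
  gm <- gm_from_rows(list(
    s1 = "AB", s2 = "BB", s3 = "AA", s4 = "AA", s5 = "NC"
  ))
  pheno <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5),
    berry_color = c("6", "5", "1", "6", "2") # s4: colored without B allele
  )
  rule <- trait_rule(
    "color", "berry_color", "m1", "allele_present", "colored",
    else_class = "non_colored"
  )
  ev <- evaluate_rule(gm, rule, pheno, collapse = colour_collapse)
  expect_equal(ev$n_evaluable, 4L) # s5 has a no-call
  expect_equal(ev$n_correct, 3L)
  expect_equal(ev$n_wrong, 1L)
  expect_identical(ev$wrong_sample_ids[[1]], "s4")
  expect_false(ev$fully_predictive)
})

test_that("rule evaluation is invariant to sample order and non-evaluable removal", {
  sim <- simulate_panel(tiny_config(
    seed = 19, genotyping_error_rate = 0, missing_rate_base = 0,
    missing_rate_wild_boost = 0, n_noisy_markers = 0
  ))
  rule <- trait_rule(
    "color", "berry_color", "color_01", "allele_present", "colored",
    else_class = "non_colored"
  )
  pheno <- sim$samples
  e1 <- evaluate_rule(sim$genotypes, rule, pheno, collapse = colour_collapse)
  perm <- sim$genotypes[rev(seq_len(nrow(sim$genotypes))), ]
  e2 <- evaluate_rule(perm, rule, pheno, collapse = colour_collapse)
  expect_equal(e1$n_correct, e2$n_correct)
  expect_equal(e1$n_wrong, e2$n_wrong)
  # dropping non-evaluable samples does not change the counts for the rest
  detail <- evaluate_rule(sim$genotypes, rule, pheno,
    collapse = colour_collapse, detail = TRUE
  )
  keep <- detail$sample_id[detail$evaluable]
  e3 <- evaluate_rule(sim$genotypes[keep, ], rule, pheno, collapse = colour_collapse)
  expect_equal(e3$n_correct, e1$n_correct)
  expect_equal(e3$n_wrong, e1$n_wrong)
})

test_that("planted penetrant loci are fully predictive without genotyping error", {
  sim <- simulate_panel(tiny_config(
    seed = 20, genotyping_error_rate = 0, missing_rate_base = 0,
    missing_rate_wild_boost = 0, n_noisy_markers = 0
  ))
  pheno <- sim$samples
  rules <- list(
    trait_rule("color", "berry_color", "color_01", "allele_present",
      "colored", else_class = "non_colored"
    ),
    trait_rule("seed", "seed", "seed_01", "allele_present", "none",
      else_class = "complete"
    ),
    trait_rule("muscat", "taste", "musc_01", "allele_present", "muscat")
  )
  for (r in rules) {
    ev <- evaluate_rule(sim$genotypes, r, pheno, collapse = colour_collapse)
    expect_true(ev$fully_predictive, label = r$rule_id)
    expect_gt(ev$n_evaluable, 0)
  }
})

test_that("the combined sex call follows the two-marker-set logic", {
  roles <- tibble::tibble(
    marker_id = c("m1", "m2"), role = c("female_sterility", "male_sterility")
  )
  rules <- sex_rules_from_roles(roles)
  gm <- gm_from_rows(list(
    herm = c("AA", "AA"), # neither indicated
    male = c("AB", "AA"),
    fem = c("AA", "BB"),
    carrier = c("AA", "AB"), # het at the recessive marker: hermaphrodite
    confl = c("AB", "BB"), # both indicated
    nocall = c("NC", "AA")
  ))
  pheno <- tibble::tibble(
    sample_id = c("herm", "male", "fem", "carrier", "confl", "nocall"),
    flower_sex = c("hermaphrodite", "male", "female", "hermaphrodite", "male", "male")
  )
  res <- evaluate_flower_sex_panel(gm, rules, pheno)
  call <- stats::setNames(res$combined$combined_call, res$combined$sample_id)
  expect_equal(call[["herm"]], "hermaphrodite")
  expect_equal(call[["male"]], "male")
  expect_equal(call[["fem"]], "female")
  expect_equal(call[["carrier"]], "hermaphrodite")
  expect_equal(call[["confl"]], "conflict")
  expect_true(is.na(call[["nocall"]]))
  # conflicts and no-calls are excluded from accuracy
  expect_equal(res$combined_accuracy, 1)
})

test_that("recombined sex markers lose full predictiveness, the others keep it", {
  sim <- simulate_panel(tiny_config(
    seed = 22, genotyping_error_rate = 0, missing_rate_base = 0,
    missing_rate_wild_boost = 0, n_noisy_markers = 0,
    sex_recombinant_markers = c("sex_02", "sex_07")
  ))
  rules <- sex_rules_from_roles(sim$truth$sex_marker_roles)
  res <- evaluate_flower_sex_panel(
    sim$genotypes, rules, sim$samples,
    drop_samples = sim$truth$duplicates$clone
  )
  expect_equal(res$n_fully_predictive, 7L)
  bad <- res$per_marker$rule_id[!res$per_marker$fully_predictive]
  expect_setequal(bad, c("sex_02", "sex_07"))
})

test_that("haplotype rules identify carriers and skip samples with no-calls", {
  gm <- gm_from_rows(list(
    carrier = c("AB", "AB", "AB"),
    near = c("AB", "AB", "AA"),
    masked = c("AB", "NC", "AB"),
    none = c("AA", "AA", "AA")
  ))
  rule <- trait_rule(
    "hap", "taste", c("m1", "m2", "m3"), "haplotype_match", "herbaceous",
    expected = c("AB", "AB", "any")
  )
  res <- evaluate_haplotype_rule(gm, rule)
  expect_setequal(res$carriers, c("carrier", "near"))
  expect_identical(res$non_evaluable_samples, "masked")
})

test_that("planted haplotype groups are recovered exactly", {
  sim <- simulate_panel(tiny_config(
    seed = 23, genotyping_error_rate = 0, missing_rate_base = 0,
    missing_rate_wild_boost = 0, n_noisy_markers = 0
  ))
  dip <- sim$truth$trait_diplotypes
  dip <- dip[dip$locus == "pyrazine", ]
  # duplicates are removed before panel-level carrier counts
  gm <- sim$genotypes[
    setdiff(sample_ids(sim$genotypes), sim$truth$duplicates$clone),
  ]
  mk <- sprintf("pyr_%02d", 1:11)
  h1_rule <- trait_rule("h1", "taste", mk, "haplotype_match", "herbaceous",
    expected = rep("AB", 11)
  )
  h2_rule <- trait_rule("h2", "taste", mk, "haplotype_match", "herbaceous",
    expected = c(rep("AB", 6), rep("AA", 5))
  )
  r1 <- evaluate_haplotype_rule(gm, h1_rule)
  r2 <- evaluate_haplotype_rule(gm, h2_rule)
  in_gm <- function(x) intersect(x, sample_ids(gm))
  want1 <- in_gm(dip$sample_id[
    (dip$allele1 == "h1") + (dip$allele2 == "h1") == 1 &
      (dip$allele1 == "n") + (dip$allele2 == "n") == 1
  ])
  want2 <- in_gm(dip$sample_id[
    (dip$allele1 == "h2") + (dip$allele2 == "h2") == 1 &
      (dip$allele1 == "n") + (dip$allele2 == "n") == 1
  ])
  expect_setequal(r1$carriers, want1)
  expect_setequal(r2$carriers, want2)
  expect_equal(length(intersect(r1$carriers, r2$carriers)), 0L)
})
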