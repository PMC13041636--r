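mk_variant <- function(variant_id, chromosome = "chr1", position = 1000,
                       ref = "A", alt = "G", quality = 150,
                       missing_fraction = 0, min_called_depth = 20,
                       mean_called_depth = 20, species_of_origin = "vinifera",
                       score = NA_real_) {
  tibble::tibble(
    variant_id = variant_id, chromosome = chromosome, position = position,
    ref = ref, alt = alt,
    n_alleles = 1L + lengths(strsplit(alt, ",")),
    quality = quality, missing_fraction = missing_fraction,
    min_called_depth = min_called_depth, mean_called_depth = mean_called_depth,
    species_of_origin = species_of_origin, score = score
  )
}

test_that("the filter chain keeps clean SNVs and names every failed criterion", {
  v <- dplyr::bind_rows(
    mk_variant("clean"),
    mk_variant("at", ref = "A", alt = "T"),
    mk_variant("cg", ref = "G", alt = "C"),
    mk_variant("miss", missing_fraction = 0.25),
    mk_variant("qual", quality = 99),
    mk_variant("noqual", quality = NA),
    mk_variant("indel", ref = "AT"),
    mk_variant("multi", alt = "G,T"),
    mk_variant("depth", min_called_depth = 7)
  )
  fl <- apply_variant_filters(v)
  expect_identical(fl$kept$variant_id, "clean")
  flags <- stats::setNames(fl$rejected$flags, fl$rejected$variant_id)
  expect_identical(flags[["at"]], "at_cg")
  expect_identical(flags[["cg"]], "at_cg")
  expect_identical(flags[["miss"]], "high_missing")
  expect_identical(flags[["qual"]], "low_qual")
  expect_identical(flags[["noqual"]], "low_qual")
  expect_identical(flags[["indel"]], "indel")
  expect_true("multiallelic" %in% flags[["multi"]])
  expect_identical(flags[["depth"]], "low_depth")
  # kept + rejected partition the input; refiltering kept is a fixed point
  expect_setequal(c(fl$kept$variant_id, fl$rejected$variant_id), v$variant_id)
  again <- apply_variant_filters(fl$kept)
  expect_equal(nrow(again$rejected), 0L)
  # boundary: exactly 20% missing and QUAL exactly 100 pass
  edge <- apply_variant_filters(dplyr::bind_rows(
    mk_variant("m20", missing_fraction = 0.20),
    mk_variant("q100", quality = 100),
    mk_variant("d8", min_called_depth = 8)
  ))
  expect_equal(nrow(edge$rejected), 0L)
})

test_that("mean-depth mode aggregates instead of failing on a single sample", {
  v <- mk_variant("x", min_called_depth = 3, mean_called_depth = 25)
  expect_equal(nrow(apply_variant_filters(v)$rejected), 1L)
  expect_equal(nrow(apply_variant_filters(v, dp_mode = "mean")$rejected), 0L)
})

test_that("proximity is inclusive at the window boundary and chromosome-local", {
  v <- dplyr::bind_rows(
    mk_variant("a", position = 100),
    mk_variant("b", position = 135),
    mk_variant("c", position = 171),
    mk_variant("d", chromosome = "chr2", position = 110)
  )
  fl <- flag_proximal(v, window = 35)
  expect_identical(
    stats::setNames(fl$proximity, fl$variant_id),
    c(a = TRUE, b = TRUE, c = FALSE, d = FALSE) # gaps: 35 (in), 36 (out)
  )
})

test_that("proximity at gap 36 is not flagged", {
  v <- dplyr::bind_rows(
    mk_variant("a", position = 100),
    mk_variant("b", position = 136)
  )
  expect_false(any(flag_proximal(v, 35)$proximity))
})

test_that("single-pass proximity agrees with the all-pairs oracle", {
  set.seed(99)
  for (rep in 1:3) {
    v <- tibble::tibble(
      variant_id = sprintf("v%04d", 1:2000),
      chromosome = sample(paste0("chr", 1:5), 2000, replace = TRUE),
      position = sample.int(200000, 2000)
    )
    got <- flag_proximal(v, window = 35)$proximity
    expect_identical(got, oracle_proximal(v, 35))
  }
})

test_that("quota selection fills cells, reports shortfalls and shares the R-locus bonus", {
  set.seed(7)
  pool <- dplyr::bind_rows(
    mk_variant(sprintf("vv%03d", 1:500),
      position = seq(1000, by = 500, length.out = 500),
      species_of_origin = "vinifera", score = stats::runif(500)
    ),
    mk_variant(sprintf("wa%03d", 1:25),
      position = seq(2000, by = 700, length.out = 25),
      species_of_origin = "aestivalis", score = stats::runif(25)
    ),
    mk_variant(sprintf("wr%03d", 1:200),
      chromosome = "chr12",
      position = seq(1500, by = 600, length.out = 200),
      species_of_origin = "riparia", score = stats::runif(200)
    )
  )
  q <- selection_quota(r_locus_chromosomes = "chr12")
  sel <- select_markers(pool, q)
  counts <- dplyr::count(sel$selection, .data$species_of_origin, .data$chromosome)
  expect_equal(
    counts$n[counts$species_of_origin == "vinifera"], 130L
  )
  # 25 available under quota 40: all selected, shortfall reported
  expect_equal(counts$n[counts$species_of_origin == "aestivalis"], 25L)
  cells <- sel$cells
  expect_equal(
    cells$shortfall[cells$species_of_origin == "aestivalis"], 15L
  )
  # riparia alone on an R-locus chromosome: 40 + full 60 bonus
  expect_equal(counts$n[counts$species_of_origin == "riparia"], 100L)
  # brute-force re-count from the selection table never exceeds quota
  recount <- table(paste(sel$selection$species_of_origin, sel$selection$chromosome))
  quota_of <- stats::setNames(cells$quota, paste(cells$species_of_origin, cells$chromosome))
  expect_true(all(recount <= quota_of[names(recount)]))
})

test_that("selection is deterministic and never picks flagged candidates", {
  set.seed(11)
  pool <- mk_variant(sprintf("v%03d", 1:300),
    position = sample.int(1e6, 300), score = stats::runif(300)
  )
  pool$proximity <- c(rep(TRUE, 50), rep(FALSE, 250))
  q <- selection_quota()
  s1 <- select_markers(pool, q)
  s2 <- select_markers(pool, q)
  expect_identical(s1$selection, s2$selection)
  expect_false(any(s1$selection$variant_id %in% pool$variant_id[pool$proximity]))
})

test_that("score ranking drives selection before spacing", {
  pool <- mk_variant(sprintf("v%02d", 1:10),
    position = 1:10 * 1000, score = c(rep(1, 5), rep(0.5, 5))
  )
  sel <- select_markers(pool, selection_quota(per_chromosome_vinifera = 5))
  expect_setequal(sel$selection$variant_id, sprintf("v%02d", 1:5))
})
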