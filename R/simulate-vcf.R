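# Synthetic candidate-variant VCF with planted filter failures, the fixture
# generator for the array-design filter chain and quota selection.

#' Configuration for the synthetic candidate VCF
#'
#' Controls the candidate pool emitted by [simulate_candidate_vcf()]. Clean
#' records are biallelic SNVs (never A/T or C/G), QUAL in `[150, 900]`, all
#' per-sample depths in `[10, 60]`, missingness below 20%, spaced at least
#' 200 nt apart. Planted failure records violate exactly one criterion each
#' (low QUAL, indel, multiallelic, low per-sample depth at a called
#' genotype, high missingness, A/T or C/G transversion); proximal pairs are
#' two otherwise clean records placed within the proximity window of each
#' other.
#'
#' @param species Species-of-origin labels for the candidate pools; the
#'   first label is taken as the cultivated (vinifera-like) pool by
#'   [select_markers()] conventions.
#' @param chromosomes Chromosome labels.
#' @param n_samples Samples carried in the VCF genotype columns.
#' @param n_clean_per_cell Clean candidates per (species, chromosome) cell.
#' @param n_low_qual,n_indel,n_multiallelic,n_low_depth,n_high_missing,n_at_cg
#'   Total planted single-failure records (spread across cells).
#' @param n_proximal_pairs Planted pairs of clean records within 35 nt.
#' @param seed Integer seed.
#' @return A list of class `vcf_sim_config`.
#' @export
vcf_sim_config <- function(species = c(
                             "vinifera", "aestivalis", "berlandieri",
                             "cinerea", "labrusca", "rotundifolia"
                           ),
                           chromosomes = paste0("chr", 1:19),
                           n_samples = 12,
                           n_clean_per_cell = 330,
                           n_low_qual = 20,
                           n_indel = 15,
                           n_multiallelic = 15,
                           n_low_depth = 20,
                           n_high_missing = 20,
                           n_at_cg = 20,
                           n_proximal_pairs = 10,
                           seed = 1L) {
  cfg <- list(
    species = species, chromosomes = chromosomes,
    n_samples = as.integer(n_samples),
    n_clean_per_cell = as.integer(n_clean_per_cell),
    n_low_qual = as.integer(n_low_qual), n_indel = as.integer(n_indel),
    n_multiallelic = as.integer(n_multiallelic),
    n_low_depth = as.integer(n_low_depth),
    n_high_missing = as.integer(n_high_missing),
    n_at_cg = as.integer(n_at_cg),
    n_proximal_pairs = as.integer(n_proximal_pairs),
    seed = as.integer(seed)
  )
  class(cfg) <- "vcf_sim_config"
  cfg
}

SAFE_ALLELE_PAIRS <- list(
  c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
  c("A", "C"), c("G", "T")
)

#' Simulate a candidate-variant VCF with planted filter-failure truth
#'
#' Writes a VCF 4.2 file of candidate variants and returns a truth table
#' labelling every record with the filter criteria it was planted to fail
#' (empty for clean records). Records carry `SP` (species of origin) and
#' `SC` (recommendation score) INFO keys and per-sample `GT:DP` fields.
#'
#' @param cfg A [vcf_sim_config()].
#' @param path Output VCF path.
#' @return A list with elements `path`, `truth` (tibble: `variant_id`,
#'   `chromosome`, `position`, `species_of_origin`, `fails` list-column,
#'   `proximal` logical) and `n_records`.
#' @export
simulate_candidate_vcf <- function(cfg = vcf_sim_config(), path) {
  stopifnot(inherits(cfg, "vcf_sim_config"))
  withr::with_seed(cfg$seed, {
    recs <- build_candidate_records(cfg)
    write_vcf_records(recs, path, cfg$n_samples)
  })
  truth <- tibble::tibble(
    variant_id = recs$id, chromosome = recs$chrom, position = recs$pos,
    species_of_origin = recs$species, fails = recs$fails,
    proximal = recs$proximal
  )
  list(path = path, truth = truth, n_records = nrow(recs))
}

build_candidate_records <- function(cfg) {
  ns <- cfg$n_samples
  cells <- tidyr::expand_grid(species = cfg$species, chromosome = cfg$chromosomes)
  fail_kinds <- rep(
    c("low_qual", "indel", "multiallelic", "low_depth", "high_missing", "at_cg"),
    times = c(
      cfg$n_low_qual, cfg$n_indel, cfg$n_multiallelic,
      cfg$n_low_depth, cfg$n_high_missing, cfg$n_at_cg
    )
  )
  # spread failures over cells deterministically
  fail_cell <- if (length(fail_kinds)) {
    1L + (seq_along(fail_kinds) - 1L) %% nrow(cells)
  } else {
    integer(0)
  }

  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sp <- cells$species[ci]
    ch <- cells$chromosome[ci]
    kinds <- c(
      rep("clean", cfg$n_clean_per_cell),
      fail_kinds[fail_cell == ci]
    )
    n <- length(kinds)
    # each species occupies its own 1-Mb band per chromosome so that
    # cross-species candidates never fall inside the proximity window
    offset <- (match(sp, cfg$species) - 1L) * 1000000L
    pos <- offset + cumsum(200L + sample.int(300L, n, replace = TRUE))
    rec <- make_records(kinds, sp, ch, pos, ns)
    out[[ci]] <- rec
  }
  recs <- dplyr::bind_rows(out)

  # proximal pairs: clean in every other respect, planted on the first
  # chromosome of the first species beyond the occupied region
  if (cfg$n_proximal_pairs > 0) {
    base <- max(recs$pos) + 10000L
    pos1 <- base + seq_len(cfg$n_proximal_pairs) * 1000L
    gap <- sample(10:35, cfg$n_proximal_pairs, replace = TRUE)
    pp <- make_records(
      rep("clean", 2L * cfg$n_proximal_pairs),
      cfg$species[1], cfg$chromosomes[1],
      as.vector(rbind(pos1, pos1 + gap)), ns
    )
    pp$proximal <- TRUE
    recs <- dplyr::bind_rows(recs, pp)
  }
  recs$id <- sprintf("cand_%05d", seq_len(nrow(recs)))
  recs <- dplyr::arrange(recs, match(.data$chrom, cfg$chromosomes), .data$pos)
  recs
}

make_records <- function(kinds, sp, ch, pos, ns) {
  n <- length(kinds)
  alle <- SAFE_ALLELE_PAIRS[sample.int(length(SAFE_ALLELE_PAIRS), n, replace = TRUE)]
  ref <- vapply(alle, `[`, character(1), 1)
  alt <- vapply(alle, `[`, character(1), 2)
  qual <- round(stats::runif(n, 150, 900), 1)
  qual[kinds == "low_qual"] <- round(stats::runif(sum(kinds == "low_qual"), 5, 99), 1)
  ref[kinds == "indel"] <- "AT"
  alt[kinds == "multiallelic"] <- paste0(alt[kinds == "multiallelic"], ",T")
  at_cg <- kinds == "at_cg"
  ref[at_cg] <- sample(c("A", "C"), sum(at_cg), replace = TRUE)
  alt[at_cg] <- ifelse(ref[at_cg] == "A", "T", "G")
  # avoid accidental multiallelic/identical alleles
  same <- ref == alt & kinds != "indel"
  alt[same] <- ifelse(ref[same] == "A", "G", "A")

  gts <- matrix("0/1", n, ns)
  p <- stats::runif(n, 0.15, 0.85)
  g <- matrix(
    stats::rbinom(n * ns, 2L, rep(p, times = ns)), n, ns
  )
  gts <- matrix(c("0/0", "0/1", "1/1")[g + 1L], n, ns)
  # clean missingness at most 1 sample (< 20% of 12)
  miss1 <- sample.int(ns, n, replace = TRUE)
  has_miss <- stats::runif(n) < 0.3
  gts[cbind(which(has_miss), miss1[has_miss])] <- "./."
  hm <- which(kinds == "high_missing")
  for (i in hm) {
    k <- ceiling(0.25 * ns) # > 20% missing
    gts[i, sample.int(ns, k)] <- "./."
  }
  dp <- matrix(sample(10:60, n * ns, replace = TRUE), n, ns)
  ld <- which(kinds == "low_depth")
  for (i in ld) {
    j <- which(gts[i, ] != "./.")[1]
    dp[i, j] <- sample(1:7, 1)
  }
  tibble::tibble(
    chrom = ch, pos = as.integer(pos), ref = ref, alt = alt, qual = qual,
    species = sp, score = round(stats::runif(n), 4),
    gt = lapply(seq_len(n), function(i) gts[i, ]),
    dp = lapply(seq_len(n), function(i) dp[i, ]),
    fails = lapply(kinds, function(k) if (k == "clean") character(0) else k),
    proximal = FALSE
  )
}

write_vcf_records <- function(recs, path, ns) {
  sample_names <- sprintf("S%02d", seq_len(ns))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SP,Number=1,Type=String,Description=\"Species of origin\">",
    "##INFO=<ID=SC,Number=1,Type=Float,Description=\"Recommendation score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample_names
    ), collapse = "\t")
  )
  geno <- vapply(seq_len(nrow(recs)), function(i) {
    paste(paste0(recs$gt[[i]], ":", recs$dp[[i]]), collapse = "\t")
  }, character(1))
  body <- paste(
    recs$chrom, recs$pos, recs$id, recs$ref, recs$alt, recs$qual, ".",
    paste0("SP=", recs$species, ";SC=", recs$score), "GT:DP", geno,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
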