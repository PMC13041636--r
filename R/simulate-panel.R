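# Synthetic multi-species genotyping panel with planted truth: founder
# clusters under a Balding-Nichols divergence model, Mendelian transmission
# through an explicit pedigree, planted somatic-variant duplicates, failing
# probes, maternally inherited plastid haplotypes and deterministic trait
# loci. Every downstream stage of the package can be tested against the
# returned truth record.

#' Simulation configuration for a genotyping panel
#'
#' Builds the configuration consumed by [simulate_panel()]. The defaults
#' describe the reference study conditions used throughout the package's
#' tests: a 120-sample panel (one cultivated cluster, one sylvestris-like
#' cluster and three divergent wild clusters, a two-generation pedigree with
#' 68 offspring, two somatic-variant duplicate pairs) genotyped at roughly
#' 5,000 autosomal markers plus trait and plastid loci, with 0.5% per-call
#' genotyping error, 3% baseline missingness (doubled in wild founders) and
#' 150 failing-probe markers at 10% miscall rate.
#'
#' @param chromosomes Autosome labels.
#' @param n_markers_per_chromosome Anonymous background markers per autosome.
#' @param populations Tibble with columns `name`, `species`, `prefix`,
#'   `fst`, `n_founders`, `wild`.
#' @param crosses Tibble with columns `offspring`, `mother`, `father`, one
#'   row per planned offspring; parents must be founders or earlier offspring.
#' @param genotyping_error_rate Per-call probability of a symmetric
#'   single-step miscall (hom to het; het to either hom).
#' @param missing_rate_base Per-call no-call probability.
#' @param missing_rate_wild_boost Additional no-call probability for founders
#'   of wild populations (ascertainment-driven missingness).
#' @param duplicate_sources Sample ids cloned as somatic-variant duplicates.
#' @param n_duplicate_pairs Number of duplicate pairs (first
#'   `n_duplicate_pairs` entries of `duplicate_sources` are used).
#' @param duplicate_discordance Exact number of discordant called genotypes
#'   planted between a clone and its source (before missingness).
#' @param n_noisy_markers Number of planted failing-probe markers.
#' @param noisy_error_rate Per-call probability that a failing-probe marker
#'   reports one of the other two genotype classes.
#' @param include_trait_loci Plant the default trait loci (flower sex panel,
#'   berry colour, seed development, muscat taste, methoxypyrazine
#'   haplotype)?
#' @param sex_recombinant_markers Ids among the nine sex-panel markers whose
#'   linkage with the sex locus is broken in a few samples (emulating
#'   historical recombination).
#' @param sex_recombination_n Number of samples perturbed per recombinant
#'   marker.
#' @param plastid_chromosome Label of the plastid pseudo-chromosome.
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(chromosomes = paste0("chr", 1:19),
                              n_markers_per_chromosome = 263,
                              populations = default_populations(),
                              crosses = NULL,
                              genotyping_error_rate = 0.005,
                              missing_rate_base = 0.03,
                              missing_rate_wild_boost = 0.03,
                              duplicate_sources = c("cv23", "rp06"),
                              n_duplicate_pairs = length(duplicate_sources),
                              duplicate_discordance = 6,
                              n_noisy_markers = 150,
                              noisy_error_rate = 0.10,
                              include_trait_loci = TRUE,
                              sex_recombinant_markers = character(0),
                              sex_recombination_n = 3,
                              plastid_chromosome = "chrC",
                              seed = 1L) {
  cfg <- list(
    chromosomes = chromosomes,
    n_markers_per_chromosome = as.integer(n_markers_per_chromosome),
    populations = populations,
    crosses = crosses %||% default_crosses(populations),
    genotyping_error_rate = genotyping_error_rate,
    missing_rate_base = missing_rate_base,
    missing_rate_wild_boost = missing_rate_wild_boost,
    duplicate_sources = duplicate_sources,
    n_duplicate_pairs = as.integer(n_duplicate_pairs),
    duplicate_discordance = as.integer(duplicate_discordance),
    n_noisy_markers = as.integer(n_noisy_markers),
    noisy_error_rate = noisy_error_rate,
    include_trait_loci = include_trait_loci,
    sex_recombinant_markers = sex_recombinant_markers,
    sex_recombination_n = as.integer(sex_recombination_n),
    plastid_chromosome = plastid_chromosome,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  nf <- sum(x$populations$n_founders)
  cat(sprintf(
    "<simulation_config> %d founders in %d populations, %d offspring, %d duplicate pair(s)\n",
    nf, nrow(x$populations), nrow(x$crosses), x$n_duplicate_pairs
  ))
  cat(sprintf(
    "  %d autosomes x %d markers, error %.3g, missing %.3g (+%.3g wild), seed %d\n",
    length(x$chromosomes), x$n_markers_per_chromosome,
    x$genotyping_error_rate, x$missing_rate_base,
    x$missing_rate_wild_boost, x$seed
  ))
  invisible(x)
}

#' Default population layout of the simulated panel
#'
#' One cultivated (vinifera-like) cluster, one sylvestris-like cluster and
#' three strongly diverged wild clusters, with Balding-Nichols divergence
#' parameters increasing from cultivated to wild.
#'
#' @return A tibble with one row per population.
#' @export
default_populations <- function() {
  tibble::tibble(
    name = c("vinifera", "sylvestris", "riparia", "labrusca", "amurensis"),
    species = c(
      "V. vinifera ssp. sativa", "V. vinifera ssp. sylvestris",
      "V. riparia", "V. labrusca", "V. amurensis"
    ),
    prefix = c("cv", "sy", "rp", "lb", "am"),
    fst = c(0.05, 0.12, 0.35, 0.35, 0.30),
    n_founders = c(24L, 8L, 6L, 6L, 6L),
    wild = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Default pedigree of the simulated panel
#'
#' Two generations of biparental crosses among cultivated founders (48 F1 in
#' 24 crosses, 16 F2 in 8 F1 x F1 crosses) plus four wild x cultivated hybrid
#' offspring, giving 136 parent-offspring duos, 68 trios, and full-sib,
#' half-sib, grandparent and avuncular structure.
#'
#' @param populations Population tibble (see [default_populations()]).
#' @return Tibble with columns `offspring`, `mother`, `father`.
#' @export
default_crosses <- function(populations = default_populations()) {
  f1 <- purrr::map_dfr(1:24, function(i) {
    tibble::tibble(
      offspring = sprintf("f1_%02d", c(2 * i - 1, 2 * i)),
      mother = sprintf("cv%02d", ((i - 1) %% 12) + 1),
      father = sprintf("cv%02d", 13 + ((i - 1) * 3) %% 10)
    )
  })
  hy <- tibble::tibble(
    offspring = sprintf("hy_%02d", 1:4),
    mother = c("rp01", "rp01", "cv03", "cv03"),
    father = c("cv02", "cv02", "lb01", "lb01")
  )
  f2 <- purrr::map_dfr(0:7, function(k) {
    tibble::tibble(
      offspring = sprintf("f2_%02d", c(2 * k + 1, 2 * k + 2)),
      mother = sprintf("f1_%02d", 4 * k + 1),
      father = sprintf("f1_%02d", 4 * k + 3)
    )
  })
  dplyr::bind_rows(f1, hy, f2)
}

founder_ids <- function(populations) {
  purrr::pmap(populations, function(name, prefix, n_founders, ...) {
    stats::setNames(sprintf("%s%02d", prefix, seq_len(n_founders)), NULL)
  }) |> stats::setNames(populations$name)
}

validate_simulation_config <- function(cfg) {
  probs <- c(
    cfg$genotyping_error_rate, cfg$missing_rate_base,
    cfg$missing_rate_wild_boost, cfg$noisy_error_rate
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  n_auto <- length(cfg$chromosomes) * cfg$n_markers_per_chromosome
  if (cfg$duplicate_discordance < 0 || cfg$duplicate_discordance > n_auto) {
    stop("duplicate_discordance must lie in [0, n_markers]", call. = FALSE)
  }
  if (cfg$n_duplicate_pairs > length(cfg$duplicate_sources)) {
    stop("n_duplicate_pairs exceeds the configured duplicate_sources", call. = FALSE)
  }
  fids <- unlist(founder_ids(cfg$populations), use.names = FALSE)
  known <- fids
  for (i in seq_len(nrow(cfg$crosses))) {
    cr <- cfg$crosses[i, ]
    if (!cr$mother %in% known || !cr$father %in% known) {
      stop(sprintf(
        "cross for offspring '%s' references unknown parent '%s'",
        cr$offspring, setdiff(c(cr$mother, cr$father), known)[1]
      ), call. = FALSE)
    }
    known <- c(known, cr$offspring)
  }
  src_ok <- cfg$duplicate_sources[seq_len(cfg$n_duplicate_pairs)] %in% known
  if (!all(src_ok)) stop("duplicate source not present in panel", call. = FALSE)
  invisible(cfg)
}

# ---- trait locus definitions -----------------------------------------------

# A trait locus is a single Mendelian gene with named haplotype alleles;
# its array markers are deterministic per-position B-dosage readouts of the
# two carried alleles, so marker linkage within a locus is perfect.
default_trait_loci <- function() {
  wild_sex <- c(M = 0.5, H = 0, F = 0.5)
  list(
    sex = list(
      name = "sex", trait = "flower_sex", chromosome = "chr2",
      marker_ids = sprintf("sex_%02d", 1:9), base_position = 4900000L,
      alleles = c(M = "BBBBAAAAA", H = "AAAAAAAAA", F = "AAAABBBBB"),
      freqs = list(
        vinifera = c(M = 0, H = 0.7, F = 0.3),
        sylvestris = c(M = 0.45, H = 0.10, F = 0.45),
        riparia = wild_sex, labrusca = wild_sex, amurensis = wild_sex
      ),
      phenotype = function(a1, a2) {
        if (a1 == "M" || a2 == "M") "male" else if (a1 == "F" && a2 == "F") "female" else "hermaphrodite"
      }
    ),
    color = list(
      name = "color", trait = "berry_color", chromosome = "chr2",
      marker_ids = "color_01", base_position = 14200000L,
      alleles = c(A = "A", B = "B"),
      freqs = list(
        vinifera = c(A = 0.6, B = 0.4), sylvestris = c(A = 0.4, B = 0.6),
        riparia = c(A = 0.3, B = 0.7), labrusca = c(A = 0.3, B = 0.7),
        amurensis = c(A = 0.3, B = 0.7)
      ),
      # OIV-225 codes: B dominant for anthocyanin-rich skin
      phenotype = function(a1, a2) {
        d <- (a1 == "B") + (a2 == "B")
        if (d == 2) "6" else if (d == 1) "5" else "1"
      }
    ),
    seed = list(
      name = "seed", trait = "seed", chromosome = "chr18",
      marker_ids = "seed_01", base_position = 26900000L,
      alleles = c(A = "A", B = "B"),
      freqs = list(
        vinifera = c(A = 0.85, B = 0.15), sylvestris = c(A = 0.98, B = 0.02),
        riparia = c(A = 1, B = 0), labrusca = c(A = 1, B = 0),
        amurensis = c(A = 1, B = 0)
      ),
      phenotype = function(a1, a2) {
        if (a1 == "B" || a2 == "B") "none" else "complete"
      }
    ),
    muscat = list(
      name = "muscat", trait = "taste", chromosome = "chr5",
      marker_ids = "musc_01", base_position = 20500000L,
      alleles = c(A = "A", B = "B"),
      freqs = list(
        vinifera = c(A = 0.88, B = 0.12), sylvestris = c(A = 1, B = 0),
        riparia = c(A = 1, B = 0), labrusca = c(A = 1, B = 0),
        amurensis = c(A = 1, B = 0)
      ),
      phenotype = function(a1, a2) {
        if (a1 == "B" || a2 == "B") "muscat" else "none"
      }
    ),
    pyrazine = list(
      name = "pyrazine", trait = NA_character_, chromosome = "chr3",
      marker_ids = sprintf("pyr_%02d", 1:11), base_position = 9100000L,
      alleles = c(
        n = "AAAAAAAAAAA", h1 = "BBBBBBBBBBB", h2 = "BBBBBBAAAAA"
      ),
      freqs = list(
        vinifera = c(n = 0.86, h1 = 0.06, h2 = 0.08),
        sylvestris = c(n = 0.90, h1 = 0, h2 = 0.10),
        riparia = c(n = 1, h1 = 0, h2 = 0),
        labrusca = c(n = 1, h1 = 0, h2 = 0),
        amurensis = c(n = 1, h1 = 0, h2 = 0)
      ),
      phenotype = NULL
    )
  )
}

# Plastid haplotypes over six chloroplast markers; the last marker is
# monomorphic across haplotypes (non-discriminating by construction).
default_plastid <- function() {
  list(
    marker_ids = sprintf("cp_%02d", 1:6),
    haplotypes = c(h1 = "AAAAAA", h2 = "BBBAAA", h3 = "ABABAA"),
    freqs = list(
      vinifera = c(h1 = 0.50, h2 = 0.25, h3 = 0.25),
      sylvestris = c(h1 = 0.70, h2 = 0.30, h3 = 0),
      riparia = c(h1 = 0.90, h2 = 0, h3 = 0.10),
      labrusca = c(h1 = 0.90, h2 = 0, h3 = 0.10),
      amurensis = c(h1 = 0.90, h2 = 0, h3 = 0.10)
    )
  )
}

# ---- panel simulation ------------------------------------------------------

#' Simulate a genotyping panel with planted truth
#'
#' Generates a complete synthetic panel: genotype-call matrix, sample and
#' marker metadata, and a truth record listing every planted relationship
#' (parent-offspring duos, trios, duplicate pairs), the plastid haplotype of
#' each sample, trait-locus diplotypes and the identities of the planted
#' failing-probe markers.
#'
#' Founder allele frequencies are drawn per population from a
#' Balding-Nichols model (a common ancestral frequency perturbed by each
#' population's divergence parameter); offspring receive one allele from
#' each parent at every marker independently (no linkage); genotyping error
#' is then applied, duplicates are cloned with exactly the configured number
#' of discordant calls, and missingness is applied last. Plastid markers are
#' copied from the mother and exempt from error and missingness. Random
#' number streams are split per concern so that toggling one process does
#' not shift the others.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `panel_sim` with elements `genotypes`
#'   (a [genotype_matrix()]), `samples`, `markers` (tibbles), `truth`
#'   (list) and `config`.
#' @export
simulate_panel <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  validate_simulation_config(cfg)

  streams <- withr::with_seed(
    cfg$seed,
    stats::setNames(
      sample.int(.Machine$integer.max - 1L, 8),
      c(
        "founders", "transmission", "traits", "plastid",
        "noisy_pick", "error", "duplicates", "missingness"
      )
    )
  )

  pops <- cfg$populations
  fids <- founder_ids(pops)
  founders <- unlist(fids, use.names = FALSE)
  crosses <- cfg$crosses
  offspring <- crosses$offspring
  dup_src <- cfg$duplicate_sources[seq_len(cfg$n_duplicate_pairs)]
  clones <- if (length(dup_src)) paste0(dup_src, "_clone") else character(0)
  samples <- c(founders, offspring, clones)

  n_auto <- length(cfg$chromosomes) * cfg$n_markers_per_chromosome
  auto_ids <- as.vector(vapply(
    cfg$chromosomes,
    function(ch) sprintf("snp_%s_%03d", ch, seq_len(cfg$n_markers_per_chromosome)),
    character(cfg$n_markers_per_chromosome)
  ))
  auto_chrom <- rep(cfg$chromosomes, each = cfg$n_markers_per_chromosome)
  auto_pos <- rep(seq_len(cfg$n_markers_per_chromosome) * 50000L, length(cfg$chromosomes))

  # founder dosages under Balding-Nichols divergence
  pop_of_founder <- rep(pops$name, pops$n_founders)
  founder_dosage <- withr::with_seed(streams[["founders"]], {
    p_anc <- stats::runif(n_auto, 0.1, 0.9)
    out <- matrix(0L, length(founders), n_auto, dimnames = list(founders, auto_ids))
    for (k in seq_len(nrow(pops))) {
      f <- pops$fst[k]
      p_k <- if (f > 0) {
        stats::rbeta(n_auto, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      } else {
        p_anc
      }
      p_k <- pmin(pmax(p_k, 1e-4), 1 - 1e-4)
      ids <- fids[[pops$name[k]]]
      out[ids, ] <- matrix(
        stats::rbinom(length(ids) * n_auto, 2L, rep(p_k, each = length(ids))),
        nrow = length(ids)
      )
    }
    out
  })

  # Mendelian transmission, one allele per parent per marker
  dosage <- matrix(0L, length(samples), n_auto, dimnames = list(samples, auto_ids))
  dosage[founders, ] <- founder_dosage
  dosage <- withr::with_seed(streams[["transmission"]], {
    gamete <- function(d) as.integer(d == 2L) + as.integer(d == 1L) * stats::rbinom(length(d), 1L, 0.5)
    for (i in seq_len(nrow(crosses))) {
      dosage[crosses$offspring[i], ] <- gamete(dosage[crosses$mother[i], ]) +
        gamete(dosage[crosses$father[i], ])
    }
    dosage
  })

  # trait loci: Mendelian genes with haplotype alleles and derived markers
  loci <- if (cfg$include_trait_loci) default_trait_loci() else list()
  mothers_set <- unique(crosses$mother)
  fathers_set <- unique(crosses$father)
  body_samples <- c(founders, offspring) # clones are copied later, post-error
  trait_state <- withr::with_seed(streams[["traits"]], {
    simulate_trait_loci(loci, pops, fids, crosses, body_samples, mothers_set, fathers_set)
  })
  trait_dosage <- trait_state$dosage # body samples x trait markers (possibly 0 cols)

  # sex-panel recombination injection (breaks marker-locus linkage)
  sex_recomb <- tibble::tibble(marker_id = character(0), sample_id = character(0))
  if (length(cfg$sex_recombinant_markers)) {
    rec <- withr::with_seed(streams[["traits"]] + 1L, {
      inject_sex_recombination(
        trait_dosage, trait_state$phenotypes, cfg$sex_recombinant_markers,
        cfg$sex_recombination_n,
        exclude = clones
      )
    })
    trait_dosage <- rec$dosage
    sex_recomb <- rec$log
  }

  # plastid haplotypes, maternally inherited, error-free
  plastid <- default_plastid()
  chloro <- withr::with_seed(streams[["plastid"]], {
    hap <- character(length(samples))
    names(hap) <- samples
    for (k in seq_len(nrow(pops))) {
      ids <- fids[[pops$name[k]]]
      fr <- plastid$freqs[[pops$name[k]]] %||% c(h1 = 1)
      hap[ids] <- sample(names(fr), length(ids), replace = TRUE, prob = fr)
    }
    for (i in seq_len(nrow(crosses))) hap[crosses$offspring[i]] <- hap[[crosses$mother[i]]]
    hap
  })
  for (cl in seq_along(clones)) chloro[clones[cl]] <- chloro[[dup_src[cl]]]

  # assemble true calls (duplicate rows are placeholders, overwritten after error)
  td_full <- matrix(
    0L, length(samples), ncol(trait_dosage),
    dimnames = list(samples, colnames(trait_dosage))
  )
  if (ncol(trait_dosage)) td_full[body_samples, ] <- trait_dosage[body_samples, ]
  d_all <- cbind(dosage, td_full)
  calls <- dosage_to_calls(d_all)

  # failing-probe markers: uniform miscall to one of the other two classes
  noisy_markers <- withr::with_seed(
    streams[["noisy_pick"]],
    sort(sample(auto_ids, min(cfg$n_noisy_markers, n_auto)))
  )
  body_idx <- setdiff(seq_len(nrow(calls)), match(clones, rownames(calls)))
  calls <- withr::with_seed(streams[["error"]], {
    apply_call_errors(
      calls, body_idx, noisy_markers,
      base_rate = cfg$genotyping_error_rate, noisy_rate = cfg$noisy_error_rate
    )
  })

  # somatic-variant duplicates: clone post-error, plant exact discordances
  dup_truth <- tibble::tibble(
    clone = character(0), source = character(0), n_discordant = integer(0)
  )
  if (length(clones)) {
    calls <- withr::with_seed(streams[["duplicates"]], {
      for (cl in seq_along(clones)) {
        row <- calls[dup_src[cl], ]
        flip <- sample(seq_along(auto_ids), cfg$duplicate_discordance)
        for (j in flip) {
          row[j] <- sample(setdiff(c("AA", "AB", "BB"), row[j]), 1)
        }
        calls[clones[cl], ] <- row
      }
      calls
    })
    dup_truth <- tibble::tibble(
      clone = clones, source = dup_src,
      n_discordant = cfg$duplicate_discordance
    )
  }

  # missingness last; wild founders (and their clones) get the boost
  wild_founder <- stats::setNames(rep(pops$wild, pops$n_founders), founders)
  is_wild <- stats::setNames(rep(FALSE, length(samples)), samples)
  is_wild[founders] <- wild_founder
  if (length(clones)) is_wild[clones] <- is_wild[dup_src]
  calls <- withr::with_seed(streams[["missingness"]], {
    rate <- cfg$missing_rate_base + cfg$missing_rate_wild_boost * is_wild[rownames(calls)]
    mask <- matrix(
      stats::runif(length(calls)) < rep(rate, ncol(calls)),
      nrow(calls), ncol(calls)
    )
    calls[mask] <- "NC"
    calls
  })

  # plastid calls appended after noise (exempt by design)
  cp_calls <- t(vapply(
    chloro[rownames(calls)],
    function(h) {
      ifelse(strsplit(plastid$haplotypes[[h]], "")[[1]] == "B", "BB", "AA")
    },
    character(length(plastid$marker_ids))
  ))
  colnames(cp_calls) <- plastid$marker_ids
  calls <- cbind(calls, cp_calls)
  gm <- genotype_matrix(calls)

  # ---- metadata and truth --------------------------------------------------
  pop_of <- stats::setNames(rep(NA_character_, length(samples)), samples)
  pop_of[founders] <- pop_of_founder
  if (length(clones)) pop_of[clones] <- pop_of[dup_src]
  anc <- ancestry_populations(founders, pop_of_founder, crosses)
  for (cl in seq_along(clones)) anc[[clones[cl]]] <- anc[[dup_src[cl]]]
  species_of <- stats::setNames(pops$species, pops$name)

  samp_tbl <- tibble::tibble(sample_id = samples) |>
    dplyr::mutate(
      population = pop_of[.data$sample_id],
      clone_of = dup_truth$source[match(.data$sample_id, dup_truth$clone)],
      mother_id = crosses$mother[match(.data$sample_id, crosses$offspring)],
      father_id = crosses$father[match(.data$sample_id, crosses$offspring)],
      mother_id = dplyr::coalesce(.data$mother_id, ""),
      father_id = dplyr::coalesce(.data$father_id, "")
    )
  samp_tbl$taxon_class <- vapply(samp_tbl$sample_id, function(s) {
    a <- anc[[s]]
    if (length(a) == 1) {
      species_of[[a]]
    } else if (all(a %in% c("vinifera", "sylvestris"))) {
      "V. vinifera ssp. sativa"
    } else if ("vinifera" %in% a) {
      "Vitis hybrid with V. vinifera"
    } else {
      "Vitis hybrid without V. vinifera"
    }
  }, character(1))
  samp_tbl$species <- vapply(samp_tbl$sample_id, function(s) {
    a <- anc[[s]]
    if (length(a) == 1) species_of[[a]] else "Vitis hybrid"
  }, character(1))
  samp_tbl$wild <- unname(is_wild[samp_tbl$sample_id])

  phen <- trait_state$phenotypes
  for (tr in c("flower_sex", "seed", "berry_color", "taste")) {
    samp_tbl[[tr]] <- if (tr %in% names(phen)) phen[[tr]][samp_tbl$sample_id] else NA_character_
  }
  # clones inherit the source's phenotypes; fruit traits are not scored on males
  if (length(clones)) {
    for (tr in c("flower_sex", "seed", "berry_color", "taste")) {
      samp_tbl[[tr]][match(clones, samp_tbl$sample_id)] <-
        samp_tbl[[tr]][match(dup_src, samp_tbl$sample_id)]
    }
  }
  male <- !is.na(samp_tbl$flower_sex) & samp_tbl$flower_sex == "male"
  for (tr in c("seed", "berry_color", "taste")) samp_tbl[[tr]][male] <- NA_character_

  marker_tbl <- tibble::tibble(
    marker_id = auto_ids, chromosome = auto_chrom, position = auto_pos,
    source = "resequencing", species_of_origin = "", is_plastid = FALSE,
    trait_annotation = ""
  )
  if (length(loci)) {
    marker_tbl <- dplyr::bind_rows(marker_tbl, purrr::map_dfr(loci, function(lc) {
      tibble::tibble(
        marker_id = lc$marker_ids, chromosome = lc$chromosome,
        position = lc$base_position + 100L * seq_along(lc$marker_ids),
        source = "trait_candidate", species_of_origin = "",
        is_plastid = FALSE, trait_annotation = lc$name
      )
    }))
  }
  marker_tbl <- dplyr::bind_rows(marker_tbl, tibble::tibble(
    marker_id = plastid$marker_ids, chromosome = cfg$plastid_chromosome,
    position = 1000L * seq_along(plastid$marker_ids),
    source = "prior_chip", species_of_origin = "", is_plastid = TRUE,
    trait_annotation = "chlorotype"
  ))

  po_duos <- dplyr::bind_rows(
    tibble::tibble(parent = crosses$mother, offspring = crosses$offspring),
    tibble::tibble(parent = crosses$father, offspring = crosses$offspring)
  )
  truth <- list(
    pedigree = tibble::tibble(
      sample_id = samp_tbl$sample_id,
      mother_id = samp_tbl$mother_id, father_id = samp_tbl$father_id
    ),
    po_duos = po_duos,
    trios = tibble::tibble(
      offspring = crosses$offspring,
      parent1 = crosses$mother, parent2 = crosses$father
    ),
    duplicates = dup_truth,
    noisy_markers = noisy_markers,
    chlorotype = tibble::tibble(
      sample_id = samples,
      haplotype_name = unname(chloro[samples]),
      haplotype = unname(plastid$haplotypes[chloro[samples]])
    ),
    trait_diplotypes = trait_state$diplotypes,
    sex_marker_roles = trait_state$sex_marker_roles,
    sex_recombined = sex_recomb,
    plastid_marker_ids = plastid$marker_ids
  )

  structure(
    list(
      genotypes = gm, samples = samp_tbl, markers = marker_tbl,
      truth = truth, config = cfg
    ),
    class = "panel_sim"
  )
}

#' @export
print.panel_sim <- function(x, ...) {
  cat(sprintf(
    "<panel_sim> %d samples x %d markers; %d planted PO duos, %d trios, %d duplicate pair(s)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    nrow(x$truth$po_duos), nrow(x$truth$trios), nrow(x$truth$duplicates)
  ))
  invisible(x)
}

# draw founder diplotypes and transmit trait-locus alleles
simulate_trait_loci <- function(loci, pops, fids, crosses, samples,
                                mothers_set, fathers_set) {
  if (!length(loci)) {
    return(list(
      dosage = matrix(
        integer(0), length(samples), 0,
        dimnames = list(samples, character(0))
      ),
      phenotypes = list(), diplotypes = tibble::tibble(),
      sex_marker_roles = tibble::tibble()
    ))
  }
  diplos <- list()
  phenos <- list()
  dosage_blocks <- list()
  for (lc in loci) {
    a1 <- a2 <- stats::setNames(rep(NA_character_, length(samples)), samples)
    for (k in seq_len(nrow(pops))) {
      ids <- fids[[pops$name[k]]]
      fr <- lc$freqs[[pops$name[k]]]
      if (is.null(fr)) fr <- stats::setNames(c(1, rep(0, length(lc$alleles) - 1)), names(lc$alleles))
      for (s in ids) {
        fr_m <- fr
        if (lc$name == "sex" && s %in% mothers_set && "M" %in% names(fr_m)) {
          fr_m["M"] <- 0 # a seed parent cannot be male
          if (sum(fr_m) == 0) stop("no non-male allele available for mother ", s, call. = FALSE)
        }
        draw <- sample(names(fr_m), 2, replace = TRUE, prob = fr_m)
        # a pollen parent cannot be purely female
        if (lc$name == "sex" && s %in% fathers_set && all(draw == "F")) {
          draw[1] <- if (fr["H"] > 0) "H" else "M"
        }
        a1[s] <- draw[1]
        a2[s] <- draw[2]
      }
    }
    for (i in seq_len(nrow(crosses))) {
      o <- crosses$offspring[i]
      m <- crosses$mother[i]
      f <- crosses$father[i]
      a1[o] <- sample(c(a1[[m]], a2[[m]]), 1)
      a2[o] <- sample(c(a1[[f]], a2[[f]]), 1)
      if (lc$name == "sex" && o %in% fathers_set && a1[[o]] == "F" && a2[[o]] == "F") {
        a2[o] <- "H" # keep designated pollen parents fertile
      }
    }
    hap <- lapply(lc$alleles, function(s) strsplit(s, "")[[1]] == "B")
    n_mk <- length(lc$marker_ids)
    v <- vapply(
      samples,
      function(s) as.integer(hap[[a1[[s]]]]) + as.integer(hap[[a2[[s]]]]),
      integer(n_mk)
    )
    dos <- if (n_mk == 1) matrix(v, ncol = 1) else t(v)
    dimnames(dos) <- list(samples, lc$marker_ids)
    dosage_blocks[[lc$name]] <- dos
    diplos[[lc$name]] <- tibble::tibble(
      locus = lc$name, sample_id = samples,
      allele1 = unname(a1[samples]), allele2 = unname(a2[samples])
    )
    if (!is.null(lc$phenotype)) {
      phenos[[lc$trait]] <- stats::setNames(
        mapply(lc$phenotype, a1[samples], a2[samples]), samples
      )
    }
  }
  roles <- tibble::tibble(
    marker_id = sprintf("sex_%02d", 1:9),
    role = c(rep("female_sterility", 4), rep("male_sterility", 5))
  )
  list(
    dosage = do.call(cbind, dosage_blocks),
    phenotypes = phenos,
    diplotypes = dplyr::bind_rows(diplos),
    sex_marker_roles = if ("sex" %in% names(dosage_blocks)) roles else tibble::tibble()
  )
}

# Break the marker-sex linkage at chosen markers in a few samples so those
# markers stop being fully predictive while the rest of the panel is intact.
inject_sex_recombination <- function(trait_dosage, phenotypes, markers, n_per_marker,
                                     exclude = character(0)) {
  sex <- phenotypes[["flower_sex"]]
  log <- list()
  for (mk in markers) {
    if (!mk %in% colnames(trait_dosage)) stop("unknown sex marker: ", mk, call. = FALSE)
    idx <- as.integer(sub("sex_", "", mk))
    fem_role <- idx <= 4
    pool <- if (fem_role) {
      # plant a B allele in a non-male carrier-free sample
      names(sex)[sex != "male" & trait_dosage[names(sex), mk] == 0]
    } else {
      # plant a homozygous B in a non-female sample
      names(sex)[sex != "female" & trait_dosage[names(sex), mk] < 2]
    }
    pool <- setdiff(pool, exclude)
    pick <- sample(pool, min(n_per_marker, length(pool)))
    trait_dosage[pick, mk] <- if (fem_role) 1L else 2L
    log[[mk]] <- tibble::tibble(marker_id = mk, sample_id = pick)
  }
  list(dosage = trait_dosage, log = dplyr::bind_rows(log))
}

# symmetric single-step base error + uniform miscall on failing probes
apply_call_errors <- function(calls, row_idx, noisy_markers, base_rate, noisy_rate) {
  sub <- calls[row_idx, , drop = FALSE]
  noisy <- colnames(sub) %in% noisy_markers
  rate <- ifelse(noisy, noisy_rate, base_rate)
  u <- matrix(stats::runif(length(sub)), nrow(sub), ncol(sub))
  flip <- u < rep(rate, each = nrow(sub))
  if (any(flip)) {
    v <- stats::runif(sum(flip))
    cur <- sub[flip]
    is_noisy_cell <- matrix(rep(noisy, each = nrow(sub)), nrow(sub), ncol(sub))[flip]
    new <- cur
    # failing probe: uniform over the other two classes
    new[is_noisy_cell] <- ifelse(
      cur[is_noisy_cell] == "AA", ifelse(v[is_noisy_cell] < 0.5, "AB", "BB"),
      ifelse(
        cur[is_noisy_cell] == "AB", ifelse(v[is_noisy_cell] < 0.5, "AA", "BB"),
        ifelse(v[is_noisy_cell] < 0.5, "AA", "AB")
      )
    )
    # base model: single allele step
    base_cell <- !is_noisy_cell
    new[base_cell] <- ifelse(
      cur[base_cell] == "AB", ifelse(v[base_cell] < 0.5, "AA", "BB"), "AB"
    )
    sub[flip] <- new
  }
  calls[row_idx, ] <- sub
  calls
}

# set of founder populations contributing to each sample
ancestry_populations <- function(founders, pop_of_founder, crosses) {
  anc <- stats::setNames(as.list(pop_of_founder), founders)
  for (i in seq_len(nrow(crosses))) {
    anc[[crosses$offspring[i]]] <- sort(unique(c(
      anc[[crosses$mother[i]]], anc[[crosses$father[i]]]
    )))
  }
  # clones resolved by caller via pop_of; give them their source's ancestry
  anc
}
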