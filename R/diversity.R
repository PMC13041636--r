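# Panel-level diversity: per-species heterozygosity summaries, genotype
# PCA on B-allele dosage, and cross-platform concordance.

#' Observed heterozygosity summarised by species
#'
#' Joins per-sample QC statistics with species labels and summarises, per
#' species: number of accessions, mean/min/max observed heterozygosity and
#' mean genotyping call count. Rounding is left to presentation. Markers
#' ascertained in the cultivated pool are less polymorphic in divergent
#' taxa, so wild species are expected to show lower observed
#' heterozygosity.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Tibble with `sample_id` and `species` columns.
#' @return A tibble with one row per species present in the matrix.
#' @export
species_het_summary <- function(gm, samples) {
  qc <- sample_qc(gm, min_call_rate = 0)
  qc |>
    dplyr::inner_join(samples[, c("sample_id", "species")], by = "sample_id") |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_accessions = dplyr::n(),
      mean_obs_het = mean(.data$observed_heterozygosity, na.rm = TRUE),
      min_obs_het = min(.data$observed_heterozygosity, na.rm = TRUE),
      max_obs_het = max(.data$observed_heterozygosity, na.rm = TRUE),
      mean_calls = mean(.data$n_called),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species)
}

#' Genotype PCA on B-allele dosage
#'
#' Drops markers below the MAF floor, codes genotypes as the count of B
#' alleles (0/1/2), mean-imputes no-calls per marker, centres columns
#' (optionally standardises) and runs a principal component analysis.
#' Axis signs are fixed so the marker with the largest absolute loading on
#' each axis loads positively, making results deterministic.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_floor Minimum minor allele frequency.
#' @param n_components Number of axes to retain.
#' @param scale. Standardise marker columns?
#' @return An object of class `genotype_pca`: `scores` (tibble
#'   `sample_id`, `PC1`...), `var_explained`, `rotation`, `n_markers_used`.
#' @export
genotype_pca <- function(gm, maf_floor = 0.05, n_components = 10, scale. = FALSE) {
  gm <- as_genotype_matrix(gm)
  maf <- marker_qc(gm, min_call_rate = 0)$maf
  keep <- !is.na(maf) & maf >= maf_floor
  if (!any(keep)) stop("no markers at or above the MAF floor", call. = FALSE)
  d <- gm_dosage(gm)[, keep, drop = FALSE]
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  if (scale.) {
    sds <- apply(d, 2, stats::sd)
    d <- d[, sds > 0, drop = FALSE]
  }
  k <- min(n_components, nrow(d) - 1, ncol(d))
  pc <- stats::prcomp(d, center = TRUE, scale. = scale., rank. = k)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = sample_ids(gm)),
        tibble::as_tibble(pc$x)
      ),
      var_explained = stats::setNames(
        var_expl[seq_len(k)], colnames(pc$rotation)
      ),
      rotation = pc$rotation,
      n_markers_used = ncol(d)
    ),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf(
    "<genotype_pca> %d samples, %d markers used\n",
    nrow(x$scores), x$n_markers_used
  ))
  cat("variance explained:", paste(
    sprintf("%s %.1f%%", names(x$var_explained), 100 * x$var_explained),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' Per-sample concordance between two genotyping platforms
#'
#' Compares samples genotyped on two platforms over a shared marker set.
#' Markers missing on either platform are discarded per sample. In
#' `zygosity` mode (default) a marker is concordant when both platforms
#' agree on the heterozygous/homozygous class — the robust comparison when
#' A/B allele assignment is platform-specific. In `strict` mode calls must
#' match exactly, optionally after a per-marker allele-swap harmonisation
#' (a marker's B platform calls are flipped when that increases matches
#' across samples).
#'
#' @param gm_a,gm_b Genotype matrices from the two platforms.
#' @param shared_markers Optional tibble `marker_a`, `marker_b` mapping
#'   identifiers across platforms; defaults to the markers common to both.
#' @param mode `"zygosity"` or `"strict"`.
#' @param harmonize In strict mode, apply per-marker allele-swap
#'   harmonisation?
#' @return A tibble: `sample_id`, `n_shared_markers`, `n_concordant`,
#'   `concordance_perc`, `evaluable`.
#' @export
platform_concordance <- function(gm_a, gm_b, shared_markers = NULL,
                                 mode = c("zygosity", "strict"),
                                 harmonize = TRUE) {
  mode <- match.arg(mode)
  gm_a <- as_genotype_matrix(gm_a)
  gm_b <- as_genotype_matrix(gm_b)
  if (is.null(shared_markers)) {
    common <- intersect(marker_ids(gm_a), marker_ids(gm_b))
    shared_markers <- tibble::tibble(marker_a = common, marker_b = common)
  }
  samples <- intersect(sample_ids(gm_a), sample_ids(gm_b))
  if (!length(samples) || !nrow(shared_markers)) {
    stop("no shared samples or markers between platforms", call. = FALSE)
  }
  ma <- unclass(gm_a)[samples, shared_markers$marker_a, drop = FALSE]
  mb <- unclass(gm_b)[samples, shared_markers$marker_b, drop = FALSE]
  if (mode == "strict" && harmonize) {
    swapped <- ifelse(mb == "AA", "BB", ifelse(mb == "BB", "AA", mb))
    both <- ma != "NC" & mb != "NC"
    plain <- colSums(both & ma == mb)
    flip <- colSums(both & ma == swapped)
    do_swap <- flip > plain
    mb[, do_swap] <- swapped[, do_swap]
  }
  both <- ma != "NC" & mb != "NC"
  conc <- if (mode == "zygosity") {
    both & ((ma == "AB") == (mb == "AB"))
  } else {
    both & ma == mb
  }
  n_shared <- unname(rowSums(both))
  n_conc <- unname(rowSums(conc))
  tibble::tibble(
    sample_id = samples,
    n_shared_markers = as.integer(n_shared),
    n_concordant = as.integer(n_conc),
    concordance_perc = ifelse(n_shared > 0, 100 * n_conc / n_shared, NA_real_),
    evaluable = n_shared > 0
  )
}
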