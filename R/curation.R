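# Post-genotyping curation on exported genotype calls: per-sample QC,
# per-marker QC and the Mendelian-error marker filter.

#' Per-sample quality control
#'
#' Computes, over non-missing calls, each sample's call rate and observed
#' heterozygosity (fraction of called markers at which the sample is AB).
#' Samples pass when their call rate reaches `min_call_rate`; the default
#' 0.85 accommodates multi-species panels in which species-specific probe
#' design inflates missingness.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Minimum call rate to pass.
#' @return A tibble: `sample_id`, `n_called`, `call_rate`,
#'   `observed_heterozygosity` (NA when nothing is called), `passes`.
#' @export
sample_qc <- function(gm, min_call_rate = 0.85) {
  gm <- as_genotype_matrix(gm)
  if (!nrow(gm) || !ncol(gm)) stop("empty genotype matrix", call. = FALSE)
  ind <- gm_indicators(gm)
  n_called <- unname(rowSums(ind$called))
  het <- ifelse(n_called > 0, unname(rowSums(ind$AB)) / n_called, NA_real_)
  cr <- n_called / ncol(gm)
  tibble::tibble(
    sample_id = sample_ids(gm),
    n_called = as.integer(n_called),
    call_rate = cr,
    observed_heterozygosity = het,
    passes = cr >= min_call_rate & n_called > 0
  )
}

#' Per-marker quality control
#'
#' Classifies each marker by call rate, number of observed genotype classes
#' and minor allele frequency. MAF is computed from allele counts,
#' `min(p, 1 - p)` with `p = (2 n_AA + n_AB) / (2 n_called)`; no-calls are
#' excluded from every denominator. Status precedence is
#' `LOW_CALL_RATE > MONO > PASS`; `MONO` means exactly one genotype class
#' among called samples. Intensity-based array classes cannot be
#' reproduced from calls alone, so these call-level statuses are a
#' documented proxy.
#'
#' @param gm A [genotype_matrix()] (samples already filtered by
#'   [sample_qc()]).
#' @param min_call_rate Minimum marker call rate.
#' @param maf_floor MAF threshold reported as `below_maf_floor` (used by
#'   the diversity PCA, not a rejection here).
#' @return A tibble: `marker_id`, `call_rate`, `maf`, `n_classes_observed`,
#'   `below_maf_floor`, `status`.
#' @export
marker_qc <- function(gm, min_call_rate = 0.85, maf_floor = 0.05) {
  gm <- as_genotype_matrix(gm)
  ind <- gm_indicators(gm)
  n_called <- unname(colSums(ind$called))
  n_aa <- unname(colSums(ind$AA))
  n_ab <- unname(colSums(ind$AB))
  n_bb <- unname(colSums(ind$BB))
  p <- ifelse(n_called > 0, (2 * n_aa + n_ab) / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  n_classes <- (n_aa > 0) + (n_ab > 0) + (n_bb > 0)
  cr <- n_called / nrow(gm)
  status <- dplyr::case_when(
    cr < min_call_rate ~ "LOW_CALL_RATE",
    n_classes == 1 ~ "MONO",
    .default = "PASS"
  )
  tibble::tibble(
    marker_id = marker_ids(gm),
    call_rate = cr,
    maf = maf,
    n_classes_observed = as.integer(n_classes),
    below_maf_floor = !is.na(maf) & maf < maf_floor,
    status = status
  )
}

#' Remove markers with excess Mendelian segregation error
#'
#' For each marker, counts incompatible transmissions across the supplied
#' confirmed parent-offspring duos and parent-parent-offspring trios
#' (opposing homozygotes for duos; gamete-pairing violations for trios; a
#' transmission is evaluable only when every member is called) and removes
#' markers whose error rate exceeds `max_error`.
#'
#' @param gm A [genotype_matrix()].
#' @param duos Tibble of confirmed duos with columns `parent` and
#'   `offspring` (or `sample_a`/`sample_b`).
#' @param trios Optional tibble of confirmed trios with columns
#'   `offspring`, `parent1`, `parent2`.
#' @param max_error Maximum tolerated per-marker Mendelian error rate.
#' @return A list: `kept` and `removed` (marker id vectors) and `table`
#'   (per-marker `n_evaluable`, `n_incompatible`, `error_rate`).
#' @export
filter_mendelian <- function(gm, duos, trios = NULL, max_error = 0.03) {
  gm <- as_genotype_matrix(gm)
  m <- unclass(gm)
  n_mark <- ncol(m)
  if (is.null(duos)) duos <- tibble::tibble(parent = character(0), offspring = character(0))
  if (!"parent" %in% names(duos) && all(c("sample_a", "sample_b") %in% names(duos))) {
    duos <- dplyr::rename(duos, parent = "sample_a", offspring = "sample_b")
  }
  n_rel <- nrow(duos) + if (is.null(trios)) 0L else nrow(trios)
  if (n_rel == 0) {
    warning("no confirmed relationships supplied; no markers removed")
    return(list(
      kept = marker_ids(gm), removed = character(0),
      table = tibble::tibble(
        marker_id = marker_ids(gm), n_evaluable = 0L,
        n_incompatible = 0L, error_rate = NA_real_
      )
    ))
  }
  n_eval <- n_inc <- numeric(n_mark)
  for (i in seq_len(nrow(duos))) {
    a <- m[duos$parent[i], ]
    b <- m[duos$offspring[i], ]
    ok <- a != "NC" & b != "NC"
    n_eval <- n_eval + ok
    n_inc <- n_inc + (ok & ((a == "AA" & b == "BB") | (a == "BB" & b == "AA")))
  }
  if (!is.null(trios) && nrow(trios)) {
    for (i in seq_len(nrow(trios))) {
      g_o <- m[trios$offspring[i], ]
      g_1 <- m[trios$parent1[i], ]
      g_2 <- m[trios$parent2[i], ]
      ok <- g_o != "NC" & g_1 != "NC" & g_2 != "NC"
      n_eval <- n_eval + ok
      inc <- logical(n_mark)
      inc[ok] <- !trio_compatible(g_o[ok], g_1[ok], g_2[ok])
      n_inc <- n_inc + inc
    }
  }
  n_eval <- unname(n_eval)
  n_inc <- unname(n_inc)
  rate <- ifelse(n_eval > 0, n_inc / n_eval, NA_real_)
  removed <- marker_ids(gm)[!is.na(rate) & rate > max_error]
  list(
    kept = setdiff(marker_ids(gm), removed),
    removed = removed,
    table = tibble::tibble(
      marker_id = marker_ids(gm),
      n_evaluable = as.integer(n_eval),
      n_incompatible = as.integer(n_inc),
      error_rate = rate
    )
  )
}
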