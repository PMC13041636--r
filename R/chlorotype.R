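# Plastid haplotype assignment and maternal-lineage verdicts. The
# chloroplast is maternally inherited and haploid: array calls at plastid
# loci are expected homozygous, heterozygous calls are technical artifacts.

#' Assign chloroplast haplotypes
#'
#' Builds, per sample, the plastid haplotype string over the supplied
#' plastid markers: `AA` reads as `A`, `BB` as `B`; heterozygous calls are
#' counted as anomalies (`n_het_calls`, the plastid being haploid) and
#' masked as missing, as are no-calls. Markers monomorphic across the
#' panel are reported as non-discriminating; haplotype identity and type
#' assignment use the discriminating positions only. Distinct complete
#' haplotypes are labelled `Type1`, `Type2`, ... by descending panel
#' frequency (ties broken lexicographically by haplotype string).
#'
#' @param gm A [genotype_matrix()].
#' @param plastid_markers Character vector of plastid marker ids (subset of
#'   the matrix markers).
#' @return A tibble of class `chlorotype_assignment`: `sample_id`,
#'   `haplotype` (string over A/B/N across all plastid markers),
#'   `n_het_calls`, `type_label` (NA when a discriminating position is
#'   missing). Attributes: `types` (tibble `type_label`, `haplotype`,
#'   `n_samples`) and `non_discriminating` (marker ids).
#' @export
assign_chlorotypes <- function(gm, plastid_markers) {
  gm <- as_genotype_matrix(gm)
  if (!length(plastid_markers)) stop("empty plastid marker set", call. = FALSE)
  missing_mk <- setdiff(plastid_markers, marker_ids(gm))
  if (length(missing_mk)) {
    stop("plastid markers absent from matrix: ", paste(missing_mk, collapse = ", "),
      call. = FALSE
    )
  }
  m <- unclass(gm)[, plastid_markers, drop = FALSE]
  sym <- ifelse(m == "AA", "A", ifelse(m == "BB", "B", "N"))
  n_het <- rowSums(m == "AB")

  observed <- apply(sym, 2, function(col) sort(unique(col[col != "N"])))
  discr <- vapply(observed, function(v) length(v) >= 2, logical(1))
  non_discr <- plastid_markers[!discr]
  key <- apply(sym[, discr, drop = FALSE], 1, paste, collapse = "")
  complete <- !grepl("N", key, fixed = TRUE) & sum(discr) > 0

  freq <- sort(table(key[complete]), decreasing = TRUE)
  if (length(freq)) {
    # stable ordering: frequency desc, then lexicographic haplotype
    ord <- order(-as.integer(freq), names(freq))
    type_of <- stats::setNames(paste0("Type", seq_along(freq)), names(freq)[ord])
  } else {
    type_of <- character(0)
  }
  type_label <- ifelse(complete, unname(type_of[key]), NA_character_)

  out <- tibble::tibble(
    sample_id = sample_ids(gm),
    haplotype = apply(sym, 1, paste, collapse = ""),
    n_het_calls = as.integer(n_het),
    type_label = type_label
  )
  types <- tibble::tibble(
    type_label = unname(type_of),
    haplotype = names(type_of),
    n_samples = as.integer(table(key[complete])[names(type_of)])
  ) |> dplyr::arrange(.data$type_label)
  attr(out, "types") <- types
  attr(out, "non_discriminating") <- non_discr
  class(out) <- c("chlorotype_assignment", class(out))
  out
}

#' Maternal-lineage verdicts from chlorotypes and pedigree
#'
#' For every offspring with two recorded parents, compares its chlorotype
#' with the parents'. The verdict is `confirmed` (parents' types differ and
#' the offspring matches the recorded mother), `inconclusive` (parents
#' carry identical chlorotypes, so the maternal side cannot be resolved),
#' `excluded` (the recorded mother's type differs from the offspring's —
#' the recorded mother cannot be the maternal donor), or `unassessable`
#' (offspring or a parent lacks a type assignment).
#'
#' @param assignments A [assign_chlorotypes()] result (or any tibble with
#'   `sample_id` and `type_label`).
#' @param pedigree Tibble `sample_id`, `mother_id`, `father_id` (empty
#'   string for unknown).
#' @return A tibble: `sample_id`, `mother_id`, `father_id`,
#'   `offspring_type`, `mother_type`, `father_type`, `verdict`,
#'   `maternal_parent` (the confirmed maternal donor, else NA).
#' @export
maternal_lineage <- function(assignments, pedigree) {
  type_of <- stats::setNames(assignments$type_label, assignments$sample_id)
  ped <- pedigree[pedigree$mother_id != "" & pedigree$father_id != "", , drop = FALSE]
  lookup <- function(id) {
    if (id %in% names(type_of)) type_of[[id]] else NA_character_
  }
  purrr::pmap_dfr(ped, function(sample_id, mother_id, father_id) {
    ot <- lookup(sample_id)
    mt <- lookup(mother_id)
    ft <- lookup(father_id)
    verdict <- if (is.na(ot) || is.na(mt)) {
      "unassessable"
    } else if (ot != mt) {
      "excluded"
    } else if (is.na(ft)) {
      "unassessable"
    } else if (mt == ft) {
      "inconclusive"
    } else {
      "confirmed"
    }
    tibble::tibble(
      sample_id = sample_id, mother_id = mother_id, father_id = father_id,
      offspring_type = ot, mother_type = mt, father_type = ft,
      verdict = verdict,
      maternal_parent = if (verdict == "confirmed") mother_id else NA_character_
    )
  })
}
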