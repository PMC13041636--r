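# Array-design stage: candidate-variant filtering and quota-based marker
# selection with per-chromosome species quotas and R-locus enrichment.

#' Filter candidate variants for array design
#'
#' Applies the array-design filter chain to a candidate tibble (as returned
#' by [read_candidate_vcf()]): minimum site quality, biallelic SNVs only,
#' per-sample depth, maximum missingness, and removal of A/T and C/G
#' transversions (which require two probes on strand-symmetric arrays).
#' Every rejected variant carries the flags naming the criteria it failed.
#' Proximity flags (see [flag_proximal()]) are annotations, not rejection
#' criteria. The function is idempotent and partitions its input.
#'
#' @param variants Candidate tibble; requires columns `quality`, `ref`,
#'   `alt`, `n_alleles`, `missing_fraction` and (for the depth rule)
#'   `min_called_depth` or `mean_called_depth`.
#' @param qual_min Minimum site QUAL; absent QUAL fails the rule.
#' @param dp_min Minimum depth.
#' @param dp_mode `"per_sample"` fails a site when any called sample is
#'   below `dp_min` (per-sample DP semantics); `"mean"` uses the mean depth
#'   over called samples.
#' @param max_missing Maximum tolerated fraction of missing genotypes.
#' @param drop_at_cg Reject A/T and C/G polymorphisms?
#' @return A list with tibbles `kept` and `rejected`; `rejected` gains a
#'   `flags` list-column naming the failed criteria.
#' @export
apply_variant_filters <- function(variants,
                                  qual_min = 100,
                                  dp_min = 8,
                                  dp_mode = c("per_sample", "mean"),
                                  max_missing = 0.20,
                                  drop_at_cg = TRUE) {
  dp_mode <- match.arg(dp_mode)
  if (!nrow(variants)) {
    return(list(kept = variants, rejected = dplyr::mutate(variants, flags = list())))
  }
  alt1 <- stringr::str_split(variants$alt, ",")
  is_indel <- nchar(variants$ref) > 1 |
    purrr::map_lgl(alt1, function(a) any(nchar(a) > 1))
  is_multi <- variants$n_alleles > 2
  pair <- purrr::map2_chr(variants$ref, alt1, function(r, a) {
    if (nchar(r) == 1 && length(a) == 1 && nchar(a[1]) == 1) {
      paste(sort(c(r, a[1])), collapse = "/")
    } else {
      ""
    }
  })
  at_cg <- drop_at_cg & pair %in% c("A/T", "C/G")
  low_qual <- is.na(variants$quality) | variants$quality < qual_min
  depth_val <- if (dp_mode == "per_sample") {
    variants$min_called_depth
  } else {
    variants$mean_called_depth
  }
  low_depth <- !is.na(depth_val) & depth_val < dp_min
  high_missing <- variants$missing_fraction > max_missing

  flag_mat <- cbind(
    low_qual = low_qual, indel = is_indel, multiallelic = is_multi,
    low_depth = low_depth, high_missing = high_missing, at_cg = at_cg
  )
  flags <- apply(flag_mat, 1, function(z) colnames(flag_mat)[z], simplify = FALSE)
  out <- dplyr::mutate(variants, flags = flags)
  keep <- !rowSums(flag_mat)
  list(
    kept = out[keep, , drop = FALSE],
    rejected = out[!keep, , drop = FALSE]
  )
}

#' Flag variants with a close neighbouring polymorphism
#'
#' A variant is flagged when any other polymorphism (of any type, including
#' ones later rejected by [apply_variant_filters()]) lies on the same
#' chromosome within `window` nucleotides, boundary inclusive. Probe
#' interference does not depend on why a neighbour is later dropped, so the
#' flag is computed against the full input. Implemented as a single pass
#' over positions sorted within chromosome: a variant has a neighbour
#' within the window iff its nearest sorted neighbour is.
#'
#' @param variants Tibble with `chromosome` and `position` columns.
#' @param window Maximum distance in nucleotides (default 35).
#' @return The input with a logical `proximity` column added (input row
#'   order preserved).
#' @export
flag_proximal <- function(variants, window = 35) {
  stopifnot(window >= 0)
  if (!nrow(variants)) {
    return(dplyr::mutate(variants, proximity = logical(0)))
  }
  variants |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$chromosome, .data$position) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(
      .gap_prev = .data$position - dplyr::lag(.data$position),
      .gap_next = dplyr::lead(.data$position) - .data$position,
      proximity = (!is.na(.data$.gap_prev) & .data$.gap_prev <= window) |
        (!is.na(.data$.gap_next) & .data$.gap_next <= window)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row", -".gap_prev", -".gap_next")
}

#' Selection quotas for array design
#'
#' @param per_chromosome_wild Markers per chromosome per wild species.
#' @param per_chromosome_vinifera Markers per chromosome for the cultivated
#'   pool.
#' @param r_locus_bonus Extra markers per chromosome carrying known
#'   resistance loci; the bonus is a per-chromosome pool shared round-robin
#'   across the wild species present there.
#' @param r_locus_chromosomes Chromosome labels carrying R loci.
#' @param vinifera_label Species label of the cultivated pool.
#' @param allow_proximal Tolerate proximity-flagged candidates?
#' @return A list of class `selection_quota`.
#' @export
selection_quota <- function(per_chromosome_wild = 40,
                            per_chromosome_vinifera = 130,
                            r_locus_bonus = 60,
                            r_locus_chromosomes = character(0),
                            vinifera_label = "vinifera",
                            allow_proximal = FALSE) {
  stopifnot(
    per_chromosome_wild >= 0, per_chromosome_vinifera >= 0, r_locus_bonus >= 0
  )
  structure(
    list(
      per_chromosome_wild = as.integer(per_chromosome_wild),
      per_chromosome_vinifera = as.integer(per_chromosome_vinifera),
      r_locus_bonus = as.integer(r_locus_bonus),
      r_locus_chromosomes = r_locus_chromosomes,
      vinifera_label = vinifera_label,
      allow_proximal = allow_proximal
    ),
    class = "selection_quota"
  )
}

#' Select array markers under per-chromosome species quotas
#'
#' For every (species, chromosome) cell, selects `min(quota, available)`
#' candidates: the cultivated pool receives `per_chromosome_vinifera` per
#' chromosome, each wild species `per_chromosome_wild`, and chromosomes
#' configured as R-locus carriers get `r_locus_bonus` additional slots
#' distributed round-robin across the wild species present there. Within a
#' cell, candidates are ranked by recommendation score (descending); ties
#' (and score-less pools) are resolved by a greedy spacing rule that
#' maximises the minimum distance to already selected markers, breaking
#' remaining ties by position then identifier, so re-runs are
#' byte-identical.
#'
#' @param candidates Tibble of filtered candidates with columns
#'   `variant_id`, `chromosome`, `position`, `species_of_origin` and
#'   optionally `score` and `proximity`.
#' @param quota A [selection_quota()].
#' @return A list with `selection` (tibble of selected candidates with a
#'   within-cell `rank`) and `cells` (tibble of per-cell quota, availability,
#'   selected count and shortfall).
#' @export
select_markers <- function(candidates, quota = selection_quota()) {
  stopifnot(inherits(quota, "selection_quota"))
  if (anyNA(candidates$species_of_origin)) {
    stop("candidates carry unknown species labels", call. = FALSE)
  }
  pool <- candidates
  if (!quota$allow_proximal && "proximity" %in% names(pool)) {
    pool <- pool[!pool$proximity, , drop = FALSE]
  }
  if (!"score" %in% names(pool)) pool$score <- NA_real_

  species <- sort(unique(pool$species_of_origin))
  wild_species <- setdiff(species, quota$vinifera_label)
  cells <- pool |>
    dplyr::distinct(.data$species_of_origin, .data$chromosome) |>
    dplyr::arrange(.data$species_of_origin, .data$chromosome)

  # per-chromosome R-locus bonus shares, round-robin over wild species
  bonus_share <- function(chrom, sp) {
    if (!chrom %in% quota$r_locus_chromosomes || !sp %in% wild_species) {
      return(0L)
    }
    present <- sort(unique(pool$species_of_origin[
      pool$chromosome == chrom & pool$species_of_origin %in% wild_species
    ]))
    if (!length(present)) {
      return(0L)
    }
    k <- match(sp, present)
    if (is.na(k)) {
      return(0L)
    }
    base <- quota$r_locus_bonus %/% length(present)
    extra <- quota$r_locus_bonus %% length(present)
    as.integer(base + (k <= extra))
  }

  sel_list <- vector("list", nrow(cells))
  cell_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species_of_origin[i]
    ch <- cells$chromosome[i]
    cell <- pool[pool$species_of_origin == sp & pool$chromosome == ch, , drop = FALSE]
    q <- if (sp == quota$vinifera_label) {
      quota$per_chromosome_vinifera
    } else {
      quota$per_chromosome_wild + bonus_share(ch, sp)
    }
    picked <- pick_in_cell(cell, q)
    if (nrow(picked)) picked$rank <- seq_len(nrow(picked))
    sel_list[[i]] <- picked
    cell_rows[[i]] <- tibble::tibble(
      species_of_origin = sp, chromosome = ch, quota = as.integer(q),
      n_available = nrow(cell), n_selected = nrow(picked),
      shortfall = max(0L, as.integer(q) - nrow(picked))
    )
  }
  list(
    selection = dplyr::bind_rows(sel_list),
    cells = dplyr::bind_rows(cell_rows)
  )
}

# rank by score desc; within tied score blocks straddling the cutoff, pick
# greedily for spacing (max min-distance to current picks), ties by
# position then id
pick_in_cell <- function(cell, q) {
  if (q <= 0 || !nrow(cell)) {
    return(cell[0, , drop = FALSE])
  }
  if (nrow(cell) <= q) {
    return(dplyr::arrange(cell, .data$position, .data$variant_id))
  }
  sc <- cell$score
  sc[is.na(sc)] <- -Inf
  ord_groups <- sort(unique(sc), decreasing = TRUE)
  sel_idx <- integer(0)
  remaining <- q
  for (g in ord_groups) {
    idx <- which(sc == g)
    if (length(idx) <= remaining) {
      sel_idx <- c(sel_idx, idx[order(cell$position[idx], cell$variant_id[idx])])
      remaining <- remaining - length(idx)
    } else {
      sel_idx <- c(sel_idx, greedy_spacing_pick(cell, idx, sel_idx, remaining))
      remaining <- 0L
    }
    if (remaining == 0L) break
  }
  out <- cell[sel_idx, , drop = FALSE]
  dplyr::arrange(out, .data$position, .data$variant_id)
}

greedy_spacing_pick <- function(cell, idx, sel_idx, k) {
  pos <- cell$position
  ids <- cell$variant_id
  chosen <- integer(0)
  avail <- idx
  for (step in seq_len(k)) {
    anchors <- c(sel_idx, chosen)
    if (!length(anchors)) {
      # no anchor yet: start from the lowest position
      best <- avail[order(pos[avail], ids[avail])][1]
    } else {
      d <- vapply(avail, function(j) min(abs(pos[j] - pos[anchors])), numeric(1))
      best <- avail[order(-d, pos[avail], ids[avail])][1]
    }
    chosen <- c(chosen, best)
    avail <- setdiff(avail, best)
  }
  chosen
}
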