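# Relationship inference from Mendelian incompatibilities: duplicate
# detection, duo/trio statistics, threshold relaxation against known
# pedigree, iterative marker curation, and the relationship-class PCA.

# genotype compatibility of a trio under gamete pairing, as a lookup table
# over the three called genotype classes (offspring, parent1, parent2)
build_trio_table <- function() {
  lv <- c("AA", "AB", "BB")
  alleles <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
  ok <- array(FALSE, c(3, 3, 3), dimnames = list(lv, lv, lv))
  for (o in lv) {
    for (p1 in lv) {
      for (p2 in lv) {
        target <- paste(sort(alleles[[o]]), collapse = "")
        for (a in alleles[[p1]]) {
          for (b in alleles[[p2]]) {
            if (paste(sort(c(a, b)), collapse = "") == target) ok[o, p1, p2] <- TRUE
          }
        }
      }
    }
  }
  ok
}
TRIO_OK <- build_trio_table()

# vectorised over equal-length call vectors (no NC allowed)
trio_compatible <- function(g_o, g_1, g_2) {
  TRIO_OK[cbind(g_o, g_1, g_2)]
}

#' Pairwise Mendelian-incompatibility statistics for one duo
#'
#' Over markers called in both samples, counts opposing homozygotes
#' (AA against BB, the only duo configuration impossible under shared
#' parentage) and directional heterozygous mismatches (`het_mismatch_A1A2`:
#' first sample AB, second homozygous; `het_mismatch_A2A1`: the reverse).
#' Percentages are relative to the number of compared markers.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample identifiers.
#' @param po_threshold Maximum Mendelian error (percent) for the pair to be
#'   flagged as a candidate parent-offspring duo.
#' @return A one-row tibble: `sample_a`, `sample_b`, `n_compared`,
#'   `n_opposing_hom`, `duo_errors_perc`, `het_mismatch_A1A2`,
#'   `het_mismatch_A2A1`, `perc_mismatches`, `is_candidate_po`, `evaluable`.
#' @export
compute_duo <- function(gm, a, b, po_threshold = 0.5) {
  gm <- as_genotype_matrix(gm)
  ga <- unclass(gm)[a, ]
  gb <- unclass(gm)[b, ]
  ok <- ga != "NC" & gb != "NC"
  n_comp <- sum(ok)
  opp <- sum(ok & ((ga == "AA" & gb == "BB") | (ga == "BB" & gb == "AA")))
  h12 <- sum(ok & ga == "AB" & gb != "AB")
  h21 <- sum(ok & gb == "AB" & ga != "AB")
  err <- if (n_comp > 0) 100 * opp / n_comp else NA_real_
  mism <- if (n_comp > 0) 100 * (h12 + h21) / n_comp else NA_real_
  tibble::tibble(
    sample_a = a, sample_b = b,
    n_compared = as.integer(n_comp),
    n_opposing_hom = as.integer(opp),
    duo_errors_perc = err,
    het_mismatch_A1A2 = as.integer(h12),
    het_mismatch_A2A1 = as.integer(h21),
    perc_mismatches = mism,
    is_candidate_po = !is.na(err) & err <= po_threshold,
    evaluable = n_comp > 0
  )
}

#' All-pairs duo statistics
#'
#' Vectorised computation of [compute_duo()] over every unordered sample
#' pair, via indicator-matrix cross-products. Pairs are reported with
#' `sample_a < sample_b` lexicographically; the two directional
#' heterozygous-mismatch counters are swapped accordingly.
#'
#' @inheritParams compute_duo
#' @return A tibble with one row per unordered pair, columns as in
#'   [compute_duo()].
#' @export
all_duos <- function(gm, po_threshold = 0.5) {
  gm <- as_genotype_matrix(gm)
  ind <- gm_indicators(gm)
  aa <- ind$AA + 0
  ab <- ind$AB + 0
  bb <- ind$BB + 0
  hom <- aa + bb
  called <- ind$called + 0
  opp1 <- tcrossprod(aa, bb)
  n_opp <- opp1 + t(opp1)
  h12 <- tcrossprod(ab, hom)
  n_comp <- tcrossprod(called, called)
  ids <- sample_ids(gm)
  ut <- which(upper.tri(n_comp), arr.ind = TRUE)
  i <- ut[, 1]
  j <- ut[, 2]
  a_id <- ids[i]
  b_id <- ids[j]
  hm12 <- h12[cbind(i, j)]
  hm21 <- h12[cbind(j, i)]
  swap <- a_id > b_id
  tmp <- hm12[swap]
  hm12[swap] <- hm21[swap]
  hm21[swap] <- tmp
  sa <- ifelse(swap, b_id, a_id)
  sb <- ifelse(swap, a_id, b_id)
  nc <- n_comp[cbind(i, j)]
  np <- n_opp[cbind(i, j)]
  err <- ifelse(nc > 0, 100 * np / nc, NA_real_)
  mism <- ifelse(nc > 0, 100 * (hm12 + hm21) / nc, NA_real_)
  tibble::tibble(
    sample_a = sa, sample_b = sb,
    n_compared = as.integer(nc),
    n_opposing_hom = as.integer(np),
    duo_errors_perc = err,
    het_mismatch_A1A2 = as.integer(hm12),
    het_mismatch_A2A1 = as.integer(hm21),
    perc_mismatches = mism,
    is_candidate_po = !is.na(err) & err <= po_threshold,
    evaluable = nc > 0
  )
}

#' Mendelian-incompatibility statistics for one trio
#'
#' A marker is incompatible when the offspring genotype cannot be formed by
#' drawing one allele from each parent's genotype; only markers called in
#' all three members are evaluable.
#'
#' @param gm A [genotype_matrix()].
#' @param offspring,parent1,parent2 Sample identifiers.
#' @param ppo_threshold Maximum trio error (percent) for the candidate flag.
#' @return A one-row tibble: `offspring`, `parent1`, `parent2`,
#'   `n_evaluable`, `n_incompatible`, `trio_errors_perc`,
#'   `is_candidate_ppo`, `evaluable`.
#' @export
compute_trio <- function(gm, offspring, parent1, parent2, ppo_threshold = 1) {
  gm <- as_genotype_matrix(gm)
  m <- unclass(gm)
  g_o <- m[offspring, ]
  g_1 <- m[parent1, ]
  g_2 <- m[parent2, ]
  ok <- g_o != "NC" & g_1 != "NC" & g_2 != "NC"
  n_eval <- sum(ok)
  n_inc <- sum(!trio_compatible(g_o[ok], g_1[ok], g_2[ok]))
  err <- if (n_eval > 0) 100 * n_inc / n_eval else NA_real_
  tibble::tibble(
    offspring = offspring, parent1 = parent1, parent2 = parent2,
    n_evaluable = as.integer(n_eval),
    n_incompatible = as.integer(n_inc),
    trio_errors_perc = err,
    is_candidate_ppo = !is.na(err) & err <= ppo_threshold,
    evaluable = n_eval > 0
  )
}

#' Detect duplicate samples (clones, somatic variants)
#'
#' Reports every unordered sample pair whose call discordance — markers
#' called in both samples with differing genotypes — is at most `max_diff`,
#' sorted by ascending discordance. Somatic variants of the same clone
#' differ at only a handful of markers, far below the discordance of even
#' closely related distinct genotypes.
#'
#' @param gm A [genotype_matrix()].
#' @param max_diff Maximum discordance reported.
#' @return A tibble: `sample_a`, `sample_b`, `n_compared`, `n_diff`.
#' @export
find_duplicates <- function(gm, max_diff = 10) {
  gm <- as_genotype_matrix(gm)
  ind <- gm_indicators(gm)
  same <- tcrossprod(ind$AA + 0) + tcrossprod(ind$AB + 0) + tcrossprod(ind$BB + 0)
  n_comp <- tcrossprod(ind$called + 0)
  diff <- n_comp - same
  ids <- sample_ids(gm)
  ut <- which(upper.tri(diff) & diff <= max_diff, arr.ind = TRUE)
  if (!nrow(ut)) {
    return(tibble::tibble(
      sample_a = character(0), sample_b = character(0),
      n_compared = integer(0), n_diff = integer(0)
    ))
  }
  pr <- order_pair(ids[ut[, 1]], ids[ut[, 2]])
  tibble::tibble(
    sample_a = pr$a, sample_b = pr$b,
    n_compared = as.integer(n_comp[ut]),
    n_diff = as.integer(diff[ut])
  ) |>
    dplyr::arrange(.data$n_diff, .data$sample_a, .data$sample_b)
}

#' Expected relationship classes from a pedigree
#'
#' Classifies every sample pair by pedigree structure — parent-offspring
#' (PO), full siblings (FS), grandparent (GP), half siblings (HS), avuncular
#' (UN: sibling of a parent), everything else OTHER — and reports the
#' numeric relationship coefficient `r` from the additive relationship
#' matrix. Precedence when several hold: PO > FS > GP > HS > UN.
#'
#' @param pedigree Tibble with columns `sample_id`, `mother_id`,
#'   `father_id`; empty string means unknown.
#' @return A tibble: `sample_a`, `sample_b` (lexicographic), `class`, `r`.
#' @export
pedigree_relationships <- function(pedigree) {
  ids <- pedigree$sample_id
  par <- stats::setNames(
    purrr::map2(pedigree$mother_id, pedigree$father_id, function(m, f) {
      setdiff(c(m, f), "")
    }),
    ids
  )
  for (id in setdiff(unique(unlist(par)), ids)) {
    par[[id]] <- character(0)
    ids <- c(ids, id)
  }
  # generation depth for the tabular relationship-matrix recursion
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  get_depth <- function(id) {
    if (!is.na(depth[[id]])) {
      return(depth[[id]])
    }
    d <- if (!length(par[[id]])) 0L else 1L + max(vapply(par[[id]], get_depth, integer(1)))
    depth[[id]] <<- d
    d
  }
  for (id in ids) get_depth(id)
  ord <- ids[order(depth[ids])]
  n <- length(ord)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (k in seq_len(n)) {
    i <- ord[k]
    p <- par[[i]]
    A[i, i] <- 1 + if (length(p) == 2) 0.5 * A[p[1], p[2]] else 0
    if (k > 1) {
      prev <- ord[seq_len(k - 1)]
      if (length(p)) {
        A[i, prev] <- colSums(A[p, prev, drop = FALSE]) / 2
      }
      A[prev, i] <- A[i, prev]
    }
  }

  full_sibs <- function(a, b) {
    length(par[[a]]) == 2 && length(par[[b]]) == 2 &&
      setequal(par[[a]], par[[b]]) && a != b
  }
  gp_of <- function(a, b) {
    any(vapply(par[[b]], function(p) a %in% par[[p]], logical(1)))
  }
  classify <- function(a, b) {
    if (a %in% par[[b]] || b %in% par[[a]]) {
      return("PO")
    }
    if (full_sibs(a, b)) {
      return("FS")
    }
    if (gp_of(a, b) || gp_of(b, a)) {
      return("GP")
    }
    if (length(intersect(par[[a]], par[[b]])) >= 1) {
      return("HS")
    }
    un <- any(vapply(par[[a]], function(p) full_sibs(p, b), logical(1))) ||
      any(vapply(par[[b]], function(p) full_sibs(p, a), logical(1)))
    if (un) {
      return("UN")
    }
    "OTHER"
  }
  pairs <- utils::combn(sort(ids), 2)
  tibble::tibble(
    sample_a = pairs[1, ], sample_b = pairs[2, ],
    class = purrr::map2_chr(pairs[1, ], pairs[2, ], classify),
    r = A[cbind(pairs[1, ], pairs[2, ])]
  )
}

#' Infer parent-offspring duos and trios with threshold relaxation
#'
#' Computes all-pairs duo statistics, then sets the working PO threshold to
#' the maximum Mendelian error observed among pedigree-known PO pairs
#' whenever that maximum exceeds the initial threshold — so that every
#' expected true PO pair is captured — and flags candidate PO duos.
#' Trios are evaluated for every sample against each unordered pair of its
#' candidate-PO partners (recorded parent pairs included); the trio
#' threshold is relaxed analogously against pedigree-known trios.
#'
#' @param gm A [genotype_matrix()].
#' @param pedigree Pedigree tibble (`sample_id`, `mother_id`, `father_id`);
#'   may be incomplete.
#' @param duo_threshold_init Initial duo error threshold (percent).
#' @param trio_threshold_init Initial trio error threshold (percent).
#' @param relax Relax the duo threshold to the maximum known-PO error?
#' @param relax_trios Relax the trio threshold to the maximum known-trio
#'   error?
#' @param max_partner_pairs Skip trio enumeration for samples with more
#'   candidate partners than this (guards pathological inputs).
#' @return A list: `duo_table` (all pairs), `duos` (candidate PO),
#'   `trio_table` (all evaluated trios), `trios` (candidate PPO),
#'   `threshold_used`, `trio_threshold_used`.
#' @export
infer_relationships <- function(gm, pedigree,
                                duo_threshold_init = 0.5,
                                trio_threshold_init = 1,
                                relax = TRUE, relax_trios = TRUE,
                                max_partner_pairs = 2000) {
  gm <- as_genotype_matrix(gm)
  ids <- sample_ids(gm)
  duo_table <- all_duos(gm, po_threshold = duo_threshold_init)

  known_po <- known_po_pairs(pedigree, ids)
  threshold_used <- duo_threshold_init
  if (relax && nrow(known_po)) {
    key <- paste(duo_table$sample_a, duo_table$sample_b)
    kk <- paste(known_po$sample_a, known_po$sample_b)
    known_err <- duo_table$duo_errors_perc[key %in% kk]
    known_err <- known_err[!is.na(known_err)]
    if (length(known_err)) threshold_used <- max(threshold_used, max(known_err))
  }
  duo_table$is_candidate_po <- !is.na(duo_table$duo_errors_perc) &
    duo_table$duo_errors_perc <= threshold_used
  duos <- duo_table[duo_table$is_candidate_po, , drop = FALSE]

  # partner sets from candidate duos
  partners <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(duos))) {
    a <- duos$sample_a[k]
    b <- duos$sample_b[k]
    partners[[a]] <- c(partners[[a]], b)
    partners[[b]] <- c(partners[[b]], a)
  }
  trio_specs <- list()
  for (s in ids) {
    p <- sort(unique(partners[[s]]))
    if (length(p) >= 2 && choose(length(p), 2) <= max_partner_pairs) {
      cmb <- utils::combn(p, 2)
      trio_specs[[s]] <- tibble::tibble(
        offspring = s, parent1 = cmb[1, ], parent2 = cmb[2, ]
      )
    }
  }
  # recorded parent pairs always evaluated
  rec <- pedigree[pedigree$mother_id != "" & pedigree$father_id != "" &
    pedigree$sample_id %in% ids &
    pedigree$mother_id %in% ids & pedigree$father_id %in% ids, , drop = FALSE]
  if (nrow(rec)) {
    pr <- order_pair(rec$mother_id, rec$father_id)
    trio_specs[["recorded"]] <- tibble::tibble(
      offspring = rec$sample_id, parent1 = pr$a, parent2 = pr$b
    )
  }
  trio_table <- dplyr::bind_rows(trio_specs)
  if (nrow(trio_table)) {
    pr <- order_pair(trio_table$parent1, trio_table$parent2)
    trio_table$parent1 <- pr$a
    trio_table$parent2 <- pr$b
    trio_table <- dplyr::distinct(trio_table)
    trio_table <- purrr::pmap_dfr(trio_table, function(offspring, parent1, parent2) {
      compute_trio(gm, offspring, parent1, parent2, ppo_threshold = trio_threshold_init)
    })
  } else {
    trio_table <- compute_trio(gm, ids[1], ids[1], ids[1])[0, ]
  }

  trio_threshold_used <- trio_threshold_init
  if (relax_trios && nrow(rec) && nrow(trio_table)) {
    pr <- order_pair(rec$mother_id, rec$father_id)
    kk <- paste(rec$sample_id, pr$a, pr$b)
    key <- paste(trio_table$offspring, trio_table$parent1, trio_table$parent2)
    known_err <- trio_table$trio_errors_perc[key %in% kk]
    known_err <- known_err[!is.na(known_err)]
    if (length(known_err)) trio_threshold_used <- max(trio_threshold_used, max(known_err))
  }
  if (nrow(trio_table)) {
    trio_table$is_candidate_ppo <- !is.na(trio_table$trio_errors_perc) &
      trio_table$trio_errors_perc <= trio_threshold_used
  }
  list(
    duo_table = duo_table,
    duos = duo_table[duo_table$is_candidate_po, , drop = FALSE],
    trio_table = trio_table,
    trios = trio_table[trio_table$is_candidate_ppo, , drop = FALSE],
    threshold_used = threshold_used,
    trio_threshold_used = trio_threshold_used
  )
}

known_po_pairs <- function(pedigree, ids) {
  long <- dplyr::bind_rows(
    tibble::tibble(parent = pedigree$mother_id, offspring = pedigree$sample_id),
    tibble::tibble(parent = pedigree$father_id, offspring = pedigree$sample_id)
  )
  long <- long[long$parent != "" & long$parent %in% ids & long$offspring %in% ids, ]
  pr <- order_pair(long$parent, long$offspring)
  dplyr::distinct(tibble::tibble(sample_a = pr$a, sample_b = pr$b))
}

#' Iterative relationship inference and Mendelian marker curation
#'
#' Alternates [infer_relationships()] with [filter_mendelian()] — candidate
#' PO duos and PPO trios feed the per-marker Mendelian error filter — until
#' no marker is removed (fixed point) or `max_iter` is reached. After
#' convergence the recomputed error rate of every kept marker is at most
#' `max_error` over the final confirmed relationships.
#'
#' @inheritParams infer_relationships
#' @param max_error Per-marker Mendelian error threshold for removal.
#' @param max_iter Iteration cap; non-convergence at the cap yields a
#'   warning and the partial result.
#' @return A list: `genotypes` (curated matrix), `relationships` (final
#'   [infer_relationships()] result), `removed` (all removed marker ids),
#'   `removed_per_iteration`, `n_iterations`, `converged`.
#' @export
run_iterative_curation <- function(gm, pedigree, max_error = 0.03,
                                   duo_threshold_init = 0.5,
                                   trio_threshold_init = 1,
                                   max_iter = 10) {
  gm <- as_genotype_matrix(gm)
  removed_all <- character(0)
  removed_iter <- list()
  converged <- FALSE
  rel <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    rel <- infer_relationships(
      gm, pedigree,
      duo_threshold_init = duo_threshold_init,
      trio_threshold_init = trio_threshold_init
    )
    duos <- rel$duos[, c("sample_a", "sample_b")]
    trios <- rel$trios[, c("offspring", "parent1", "parent2")]
    fm <- filter_mendelian(gm, duos = duos, trios = trios, max_error = max_error)
    removed_iter[[it]] <- fm$removed
    if (!length(fm$removed)) {
      converged <- TRUE
      break
    }
    removed_all <- c(removed_all, fm$removed)
    gm <- gm[, fm$kept]
  }
  if (!converged) warning("marker curation did not converge within max_iter")
  list(
    genotypes = gm, relationships = rel, removed = removed_all,
    removed_per_iteration = removed_iter, n_iterations = it,
    converged = converged
  )
}

#' Relationship-class PCA with supplementary projection
#'
#' Fits a PCA on the four standardised duo variables (`duo_errors_perc`,
#' `het_mismatch_A1A2`, `het_mismatch_A2A1`, `perc_mismatches`) of the
#' pairs belonging to the primary relationship classes (PO, FS, GP, HS,
#' UN). Pairs labelled OTHER — unknown or heterogeneous relationships whose
#' large variance would dominate the axes — are projected onto the fitted
#' coordinate system as supplementary individuals without influencing the
#' eigendecomposition. Axis signs follow the convention that the variable
#' with the largest absolute loading on each axis loads positively.
#'
#' @param duo_table All-pairs duo tibble (see [all_duos()]).
#' @param labels Tibble `sample_a`, `sample_b`, `class` with classes among
#'   PO, FS, GP, HS, UN, OTHER; unlabelled pairs are treated as OTHER.
#' @return An object of class `relationship_pca`: `pairs` (coordinates,
#'   class, supplementary flag), `var_explained`, `contributions`
#'   (percent, per variable and axis), and the fitted centring/scaling/
#'   rotation.
#' @export
classify_relationships <- function(duo_table, labels) {
  vars <- c(
    "duo_errors_perc", "het_mismatch_A1A2",
    "het_mismatch_A2A1", "perc_mismatches"
  )
  pr <- order_pair(labels$sample_a, labels$sample_b)
  labels <- tibble::tibble(
    sample_a = as.character(pr$a), sample_b = as.character(pr$b),
    class = as.character(labels$class)
  )
  d <- duo_table |>
    dplyr::left_join(labels, by = c("sample_a", "sample_b")) |>
    dplyr::mutate(class = dplyr::coalesce(.data$class, "OTHER")) |>
    dplyr::filter(.data$evaluable)
  active <- d$class != "OTHER"
  if (sum(active) < 3) {
    stop("fewer than 3 non-OTHER pairs: ordination is degenerate", call. = FALSE)
  }
  x <- as.matrix(d[, vars])
  xa <- x[active, , drop = FALSE]
  sds <- apply(xa, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero variance in active pairs for: ",
      paste(vars[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  pc <- stats::prcomp(xa, center = TRUE, scale. = TRUE)
  # deterministic axis orientation
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  scores <- matrix(NA_real_, nrow(d), ncol(pc$rotation),
    dimnames = list(NULL, colnames(pc$rotation))
  )
  scores[active, ] <- pc$x
  if (any(!active)) {
    xs <- scale(x[!active, , drop = FALSE], center = pc$center, scale = pc$scale)
    scores[!active, ] <- xs %*% pc$rotation
  }
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  names(var_expl) <- colnames(pc$rotation)
  contrib <- 100 * pc$rotation^2
  structure(
    list(
      pairs = dplyr::bind_cols(
        d[, c("sample_a", "sample_b", "class")],
        tibble::tibble(supplementary = !active),
        tibble::as_tibble(scores)
      ),
      var_explained = var_expl,
      contributions = contrib,
      rotation = pc$rotation, center = pc$center, scale = pc$scale
    ),
    class = "relationship_pca"
  )
}

#' @export
print.relationship_pca <- function(x, ...) {
  cat(sprintf(
    "<relationship_pca> %d active + %d supplementary pairs\n",
    sum(!x$pairs$supplementary), sum(x$pairs$supplementary)
  ))
  cat("variance explained:", paste(
    sprintf("%s %.1f%%", names(x$var_explained), 100 * x$var_explained),
    collapse = ", "
  ), "\n")
  invisible(x)
}
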