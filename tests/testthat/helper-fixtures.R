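# Shared fixtures: tiny hand-built genotype matrices and a reduced panel
# configuration fast enough for unit tests.

gm_from_rows <- function(rows, marker_prefix = "m") {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0(marker_prefix, seq_len(ncol(m)))
  genotype_matrix(m)
}

# ~15-sample, ~300-marker panel: one cultivated and one wild cluster,
# one generation of crosses, one duplicate pair
tiny_populations <- function() {
  tibble::tibble(
    name = c("vinifera", "riparia"),
    species = c("V. vinifera ssp. sativa", "V. riparia"),
    prefix = c("cv", "rp"),
    fst = c(0.05, 0.35),
    n_founders = c(8L, 4L),
    wild = c(FALSE, TRUE)
  )
}

tiny_crosses <- function() {
  tibble::tibble(
    offspring = sprintf("f1_%02d", 1:6),
    mother = rep(c("cv01", "cv02", "cv03"), each = 2),
    father = rep(c("cv05", "cv06", "cv05"), each = 2)
  )
}

tiny_config <- function(seed = 1, ...) {
  args <- list(
    chromosomes = paste0("chr", 1:5),
    n_markers_per_chromosome = 60,
    populations = tiny_populations(),
    crosses = tiny_crosses(),
    duplicate_sources = "cv08",
    n_duplicate_pairs = 1,
    n_noisy_markers = 10,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# independent brute-force oracle: trio compatibility by explicit gamete
# enumeration over the two parental genotypes
oracle_trio_compatible <- function(o, p1, p2) {
  split_alleles <- function(g) substring(g, 1:2, 1:2)
  target <- paste(sort(split_alleles(o)), collapse = "")
  for (a in split_alleles(p1)) {
    for (b in split_alleles(p2)) {
      if (paste(sort(c(a, b)), collapse = "") == target) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# independent all-pairs proximity oracle
oracle_proximal <- function(variants, window) {
  out <- logical(nrow(variants))
  for (ch in unique(variants$chromosome)) {
    idx <- which(variants$chromosome == ch)
    pos <- variants$position[idx]
    d <- abs(outer(pos, pos, "-"))
    diag(d) <- Inf
    out[idx] <- apply(d, 1, min) <= window
  }
  out
}
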