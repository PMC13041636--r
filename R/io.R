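# Readers and writers for the external representations: genotype-call TSV
# (array export style), candidate VCF, metadata / pedigree CSV, result tables.

NUMERIC_CODES <- c(`-1` = "NC", `0` = "AA", `1` = "AB", `2` = "BB")
LETTER_CODES <- c(
  AA = "AA", AB = "AB", BA = "AB", BB = "BB",
  NC = "NC", NoCall = "NC", `---` = "NC"
)

#' Read a genotype-call matrix from TSV
#'
#' Reads a tab-separated genotype table as exported by array analysis suites.
#' Two dialects are supported: `letters` (`AA`/`AB`/`BB`/`NC`, with `NoCall`
#' and `---` accepted as no-call) and `numeric` (`-1` = NC, `0` = AA,
#' `1` = AB, `2` = BB). Files may be oriented markers-in-rows (the usual
#' export, first header cell `probeset_id` or `marker_id`) or
#' samples-in-rows (first header cell `sample_id`); orientation is
#' auto-detected from that cell and can be overridden.
#'
#' @param path Path to a TSV file whose first column holds row identifiers.
#' @param dialect One of `"auto"`, `"letters"`, `"numeric"`.
#' @param orientation One of `"auto"`, `"markers_in_rows"`, `"samples_in_rows"`.
#' @return A [genotype_matrix()] (always samples x markers).
#' @export
read_genotype_matrix <- function(path,
                                 dialect = c("auto", "letters", "numeric"),
                                 orientation = c("auto", "markers_in_rows", "samples_in_rows")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2 || nrow(df) < 1) stop("genotype table is empty: ", path, call. = FALSE)

  key <- tolower(names(df)[1])
  if (orientation == "auto") {
    orientation <- if (key %in% c("sample_id", "sample", "accession")) {
      "samples_in_rows"
    } else {
      "markers_in_rows"
    }
  }
  row_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- row_ids

  if (dialect == "auto") {
    vals <- unique(as.vector(m))
    dialect <- if (all(vals %in% names(NUMERIC_CODES) | is.na(vals))) "numeric" else "letters"
  }
  codes <- if (dialect == "numeric") NUMERIC_CODES else LETTER_CODES
  mapped <- codes[as.vector(m)]
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[1]
    i <- arrayInd(bad, dim(m))
    stop(sprintf(
      "unknown call code '%s' at row '%s', column '%s'",
      as.vector(m)[bad], rownames(m)[i[1]], colnames(m)[i[2]]
    ), call. = FALSE)
  }
  out <- matrix(mapped, nrow(m), ncol(m), dimnames = dimnames(m))
  if (orientation == "markers_in_rows") out <- t(out)
  genotype_matrix(out)
}

#' Write a genotype-call matrix to TSV
#'
#' Inverse of [read_genotype_matrix()]; the written file round-trips exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param dialect `"letters"` or `"numeric"`.
#' @param orientation `"markers_in_rows"` (default export style) or
#'   `"samples_in_rows"`.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path, dialect = c("letters", "numeric"),
                                  orientation = c("markers_in_rows", "samples_in_rows")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  gm <- as_genotype_matrix(gm)
  m <- unclass(gm)
  if (dialect == "numeric") {
    rev_codes <- stats::setNames(names(NUMERIC_CODES), NUMERIC_CODES)
    m <- matrix(rev_codes[m], nrow(m), ncol(m), dimnames = dimnames(m))
  }
  if (orientation == "markers_in_rows") {
    m <- t(m)
    df <- tibble::as_tibble(m, rownames = "probeset_id")
  } else {
    df <- tibble::as_tibble(m, rownames = "sample_id")
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read candidate variants from a VCF file
#'
#' Parses a multi-sample VCF of candidate variants for array design into a
#' per-record tibble. `QUAL` of `"."` is recorded as missing (`NA`), never as
#' zero. Multiallelic records are preserved; filtering happens downstream in
#' [apply_variant_filters()].
#'
#' @param path Path to an (uncompressed or bgzipped) VCF 4.x file with GT and
#'   DP per-sample fields.
#' @return A tibble with one row per record: `variant_id`, `chromosome`,
#'   `position`, `ref`, `alt` (comma-separated), `n_alleles`, `quality`,
#'   `missing_fraction`, `min_called_depth`, `mean_called_depth`,
#'   `species_of_origin` and `score` (from INFO keys `SP` and `SC` when
#'   present), plus list-columns `depth` and `called` with per-sample detail.
#' @export
read_candidate_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix # CHROM POS ID REF ALT QUAL FILTER INFO
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed coordinate at record ", which(is.na(pos))[1], call. = FALSE)
  }
  if (ncol(vcf@gt) < 2) stop("VCF carries no sample columns", call. = FALSE)
  fmt_keys <- strsplit(vcf@gt[, 1], ":")
  if (!all(vapply(fmt_keys, function(k) "GT" %in% k, logical(1)))) {
    stop("missing GT field in FORMAT", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  called <- !is.na(gt) & !gt %in% c("./.", ".|.", ".")
  n_samp <- ncol(gt)

  alt <- fix[, "ALT"]
  n_alt <- ifelse(is.na(alt) | alt == ".", 0L, stringr::str_count(alt, ",") + 1L)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  sp <- extract_info_key(fix[, "INFO"], "SP")
  sc <- suppressWarnings(as.numeric(extract_info_key(fix[, "INFO"], "SC")))

  depth_list <- lapply(seq_len(nrow(gt)), function(i) unname(dp[i, ]))
  called_list <- lapply(seq_len(nrow(gt)), function(i) unname(called[i, ]))
  min_dp <- vapply(seq_len(nrow(gt)), function(i) {
    d <- dp[i, called[i, ]]
    if (!length(d) || all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
  }, numeric(1))
  mean_dp <- vapply(seq_len(nrow(gt)), function(i) {
    d <- dp[i, called[i, ]]
    if (!length(d) || all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }, numeric(1))

  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", pos[no_id])

  tibble::tibble(
    variant_id = id,
    chromosome = fix[, "CHROM"],
    position = pos,
    ref = fix[, "REF"],
    alt = alt,
    n_alleles = 1L + n_alt,
    quality = qual,
    missing_fraction = unname(rowSums(!called)) / n_samp,
    min_called_depth = min_dp,
    mean_called_depth = mean_dp,
    species_of_origin = sp,
    score = sc,
    depth = depth_list,
    called = called_list
  )
}

extract_info_key <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  m
}

#' Read sample metadata, marker metadata or a pedigree from CSV
#'
#' Thin readers with stable column typing. The pedigree file must carry
#' columns `sample_id`, `mother_id`, `father_id`; empty strings mean an
#' unknown parent.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()), na = "NA")
}

#' @rdname read_sample_metadata
#' @export
read_marker_metadata <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()), na = "NA")
  if ("position" %in% names(df)) df$position <- as.integer(df$position)
  if ("is_plastid" %in% names(df)) df$is_plastid <- as.logical(df$is_plastid)
  df
}

#' @rdname read_sample_metadata
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()), na = "NA")
  need <- c("sample_id", "mother_id", "father_id")
  if (!all(need %in% names(df))) {
    stop("pedigree must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$mother_id[is.na(df$mother_id)] <- ""
  df$father_id[is.na(df$father_id)] <- ""
  df[need]
}

#' Write result tables deterministically
#'
#' Writes each element of a named list of data frames as
#' `<out_dir>/<name>.csv` with a header, columns in their given order and
#' rows sorted by the leading identifier column(s), so that identical inputs
#' produce byte-identical files.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    stopifnot(is.data.frame(df))
    id_cols <- names(df)[vapply(df, function(x) is.character(x) || is.factor(x), logical(1))]
    id_cols <- intersect(names(df)[1:min(2, ncol(df))], id_cols)
    if (length(id_cols) && nrow(df)) {
      df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(id_cols)))
    }
    # list-columns are flattened to comma-joined strings for CSV
    for (cc in names(df)) {
      if (is.list(df[[cc]])) {
        df[[cc]] <- vapply(df[[cc]], function(x) paste(x, collapse = ","), character(1))
      }
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, p, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
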