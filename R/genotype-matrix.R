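# Central container: a dense samples x markers table of diploid array calls.

CALL_LEVELS <- c("AA", "AB", "BB", "NC")

#' Construct a genotype matrix
#'
#' A `genotype_matrix` is a character matrix of diploid biallelic array calls
#' with samples in rows and markers in columns. The only admitted call symbols
#' are `AA`, `AB`, `BB` and `NC` (no-call). Row and column names are the
#' sample and marker identifiers and must be unique.
#'
#' @param calls Character matrix with unique rownames (samples) and colnames
#'   (markers); every cell one of `AA`, `AB`, `BB`, `NC`.
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(matrix(c("AA", "AB", "BB", "NC"), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("m1", "m2"))
#' ))
#' sample_ids(gm)
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("`calls` must be a character matrix", call. = FALSE)
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` must carry sample rownames and marker colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate sample identifiers: ",
      paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(calls))) {
    stop("duplicate marker identifiers: ",
      paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(!calls %in% CALL_LEVELS)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(calls))
    stop(sprintf(
      "unknown call symbol '%s' at sample '%s', marker '%s'",
      calls[bad[1]], rownames(calls)[i[1]], colnames(calls)[i[2]]
    ), call. = FALSE)
  }
  structure(calls, class = c("genotype_matrix", "matrix", "array"))
}

#' Coerce to a genotype matrix
#'
#' @param x A character matrix, or a data frame whose first column holds
#'   sample ids and remaining columns hold marker calls.
#' @return A [genotype_matrix()].
#' @export
as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    return(x)
  }
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[1]])
    return(genotype_matrix(m))
  }
  genotype_matrix(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  genotype_matrix(unclass(x)[i, j, ..., drop = FALSE])
}

#' Sample and marker identifiers of a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(gm) rownames(gm)

#' @rdname sample_ids
#' @export
marker_ids <- function(gm) colnames(gm)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d markers\n", nrow(x), ncol(x)
  ))
  tab <- table(factor(unclass(x), levels = CALL_LEVELS))
  cat("calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Tidy a genotype matrix into long format
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `marker_id`, `call`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    marker_id = rep(colnames(x), each = nrow(x)),
    call = as.vector(unclass(x))
  )
}

# B-allele dosage coding (AA=0, AB=1, BB=2, NC=NA)
gm_dosage <- function(gm) {
  d <- matrix(NA_integer_, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  d[unclass(gm) == "AA"] <- 0L
  d[unclass(gm) == "AB"] <- 1L
  d[unclass(gm) == "BB"] <- 2L
  d
}

# Indicator matrices used by the vectorised pairwise counters.
gm_indicators <- function(gm) {
  m <- unclass(gm)
  list(
    AA = m == "AA", AB = m == "AB", BB = m == "BB",
    called = m != "NC"
  )
}

# dosage matrix (0/1/2, NA for NC) back to calls
dosage_to_calls <- function(d) {
  calls <- matrix("NC", nrow(d), ncol(d), dimnames = dimnames(d))
  calls[!is.na(d) & d == 0] <- "AA"
  calls[!is.na(d) & d == 1] <- "AB"
  calls[!is.na(d) & d == 2] <- "BB"
  calls
}
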