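#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats prcomp setNames rbinom rbeta runif
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# canonical unordered pair ordering used across kinship tables
order_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  list(
    a = ifelse(swap, b, a),
    b = ifelse(swap, a, b)
  )
}
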