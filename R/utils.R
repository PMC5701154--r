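#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted: inputs are expected to be HGNC-style symbols already.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalizeGenes(c(" Brca1", "shh "))
normalizeGenes <- function(x) {
    toupper(trimws(as.character(x)))
}

# normalize + deduplicate, warning when duplicates collapse
.normalizeUnique <- function(x, what = "gene list") {
    x <- normalizeGenes(x)
    x <- x[nzchar(x)]
    if (anyDuplicated(x)) {
        warning(sum(duplicated(x)), " duplicate symbol(s) removed from ",
                what, call. = FALSE)
        x <- unique(x)
    }
    x
}

.checkCount <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
        stop("'", name, "' must contain non-negative integers", call. = FALSE)
}
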