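## Binding-site sequences are short fixed-length words over {A,C,G,T}.
## Internally they are integer vectors in 1:4 so the simulation engine can
## mutate and compare them cheaply; the user-facing API accepts either an
## integer vector or a single character string such as "ACGTACGT".

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Convert a binding-site sequence to its internal integer encoding
#'
#' Binding sites and recognition sequences are fixed-length nucleotide words.
#' Functions in this package accept either a character string (e.g.
#' `"ACGTACGT"`) or an integer vector with values in `1:4` (A=1, C=2, G=3,
#' T=4); this helper performs the conversion and validates the alphabet.
#'
#' @param x A single character string over `{A,C,G,T}`, or an integer vector
#'   with values in `1:4`.
#' @param what Label used in error messages.
#' @return An integer vector with values in `1:4`.
#' @examples
#' asSiteSeq("ACGT")
#' siteToChar(asSiteSeq("ACGT"))
#' @export
asSiteSeq <- function(x, what = "sequence") {
  if (is.character(x)) {
    if (length(x) != 1L) {
      stop("'", what, "' must be a single character string")
    }
    v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], NUCLEOTIDES)
    if (anyNA(v)) {
      stop("'", what, "' contains symbols outside {A,C,G,T}: ", x)
    }
    return(as.integer(v))
  }
  if (is.numeric(x)) {
    v <- as.integer(x)
    if (length(v) == 0L || anyNA(v) || any(v < 1L | v > 4L)) {
      stop("'", what, "' must contain integer codes in 1:4")
    }
    return(v)
  }
  stop("'", what, "' must be a character string or an integer vector")
}

#' @rdname asSiteSeq
#' @export
siteToChar <- function(x) {
  paste(NUCLEOTIDES[asSiteSeq(x)], collapse = "")
}

## mismatch of every row of an integer matrix against one site (proportion)
rowMismatch <- function(mat, site) {
  rowMeans(mat != matrix(site, nrow(mat), length(site), byrow = TRUE))
}
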