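## Dominance ordination from full-diallel data: per-strain array covariances
## per context and their cross-context correlation with a permutation test.
## A strain whose fixed alleles are mostly dominant over the panel has a low
## array covariance; a negative cross-context correlation of the ordinations
## is the polygenic signature of dominance reversal.

#' Construct a DiallelData object
#'
#' @param data Data frame with columns `strain_a`, `strain_b`, `context`,
#'   `replicate`, `phenotype`. Selfs (`strain_a == strain_b`) must be present
#'   for every strain in every context; at least 3 strains are required.
#' @return A [DiallelData-class].
#' @export
diallelData <- function(data) {
  data$strain_a <- as.character(data$strain_a)
  data$strain_b <- as.character(data$strain_b)
  data$context <- as.character(data$context)
  new("DiallelData", data = data)
}

#' @describeIn diallelData Strains present in the diallel.
#' @param x A [DiallelData-class].
#' @export
diallelStrains <- function(x) sort(unique(c(x@data$strain_a, x@data$strain_b)))

#' @describeIn diallelData Contexts present in the diallel.
#' @export
diallelContexts <- function(x) sort(unique(x@data$context))

setMethod("show", "DiallelData", function(object) {
  cat("DiallelData:", length(diallelStrains(object)), "strains,",
      nrow(object@data), "phenotype records, contexts:",
      paste(diallelContexts(object), collapse = ", "), "\n")
})

## matrix of cross means (replicates and reciprocals averaged) per context;
## entry [r, s] = mean phenotype of the r x s cross, diagonal = selfs
crossMeanMatrix <- function(dd, context) {
  d <- dd@data[dd@data$context == context, ]
  if (nrow(d) == 0L) stop("context '", context, "' not present in the diallel")
  strains <- diallelStrains(dd)
  lo <- pmin(d$strain_a, d$strain_b)
  hi <- pmax(d$strain_a, d$strain_b)
  agg <- tapply(d$phenotype, list(lo, hi), mean)
  n <- length(strains)
  m <- matrix(NA_real_, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- agg[strains[i], strains[j]]
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  if (anyNA(m)) {
    stop("diallel is incomplete in context '", context,
         "': every strain pair (including selfs) needs a phenotype")
  }
  m
}

#' Array covariance of one strain
#'
#' Covariance, across the panel, between strain `r`'s array of cross means
#' (replicates and reciprocals averaged; the self cross included as the
#' cross of `r` with itself) and the partners' self values:
#' `W_r = cov(cross(r, s), self(s))` over all strains `s`, with the usual
#' `n - 1` denominator. For a purely additive diallel
#' (`cross = midparent`), `W_r = var(selfs) / 2` identically for every
#' strain; a fully dominant strain has `W_r = 0`.
#'
#' @param dd A [DiallelData-class].
#' @param strain Strain label.
#' @param context Context label.
#' @return The array covariance (a real number).
#' @export
arrayCovariance <- function(dd, strain, context) {
  m <- crossMeanMatrix(dd, context)
  if (!strain %in% rownames(m)) stop("unknown strain: ", strain)
  if (nrow(m) < 3L) stop("array covariance needs at least 3 strains")
  cov(m[strain, ], diag(m))
}

#' Cross-context dominance ordination
#'
#' Computes the vector of array covariances per context, then the Pearson
#' correlation of the two vectors across strains. Under the null (alleles
#' unconditionally dominant or recessive) strains keep approximately the same
#' dominance order in both contexts and the correlation is positive; a
#' negative correlation indicates strains fixed for alleles that are dominant
#' in one context but recessive in the other -- dominance reversal. The
#' p-value is a two-sided permutation test shuffling the strain labels of one
#' context's W vector. Perfectly additive data make the W vectors constant;
#' such degenerate inputs are flagged rather than raised.
#'
#' @param dd A [DiallelData-class].
#' @param contexts Length-2 character vector (default: the two contexts in
#'   the data).
#' @param nPerm Number of label permutations.
#' @param seed Optional integer seed for the permutation draw.
#' @param tol Relative tolerance declaring a W vector constant.
#' @return An [OrdinationResult-class].
#' @examples
#' dia <- simulateDiallel(nStrains = 8, seed = 1)$data
#' dominanceOrdination(dia, nPerm = 500, seed = 1)
#' @export
dominanceOrdination <- function(dd, contexts = NULL, nPerm = 10000,
                                seed = NULL, tol = 1e-8) {
  if (is.null(contexts)) {
    contexts <- diallelContexts(dd)
    if (length(contexts) != 2L) {
      stop("data contain ", length(contexts),
           " contexts; supply the two to compare")
    }
  }
  strains <- diallelStrains(dd)
  W <- vapply(contexts, function(ctx) {
    m <- crossMeanMatrix(dd, ctx)
    selfs <- diag(m)
    apply(m, 1L, cov, y = selfs)
  }, numeric(length(strains)))
  dimnames(W) <- list(strains, contexts)
  scale <- pmax(1, apply(abs(W), 2L, max))
  degenerate <- any(apply(W, 2L, sd) <= tol * scale)
  if (degenerate) {
    return(new("OrdinationResult", W = W, r = NA_real_, pValue = NA_real_,
               nPerm = as.integer(nPerm), degenerate = TRUE))
  }
  x <- W[, 1L] - mean(W[, 1L])
  y <- W[, 2L] - mean(W[, 2L])
  denom <- sqrt(sum(x^2) * sum(y^2))
  r <- sum(x * y) / denom
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    rp <- sum(x * y[sample.int(n)]) / denom
    if (abs(rp) >= abs(r) - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (nPerm + 1)
  new("OrdinationResult", W = W, r = r, pValue = p,
      nPerm = as.integer(nPerm), degenerate = FALSE)
}

setMethod("show", "OrdinationResult", function(object) {
  if (object@degenerate) {
    cat("OrdinationResult: degenerate (constant array covariances)\n")
  } else {
    cat("OrdinationResult: r =", round(object@r, 4),
        " permutation p =", signif(object@pValue, 4),
        "(", object@nPerm, "permutations )\n")
  }
})

#' Read / write diallel phenotype tables
#'
#' TSV dialect: columns `strain_a`, `strain_b`, `context`, `replicate`,
#' `phenotype`; selfs have `strain_a == strain_b`.
#'
#' @param path File path.
#' @param dd A [DiallelData-class].
#' @return `readDiallelTSV` returns a [DiallelData-class];
#'   `writeDiallelTSV` returns `path` invisibly.
#' @export
readDiallelTSV <- function(path) {
  diallelData(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readDiallelTSV
#' @export
writeDiallelTSV <- function(dd, path) {
  write.table(dd@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
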