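## Allele-specific expression: per-context exact binomial imbalance tests and
## the reversal decision rule. A gene is called a reversal only when its
## allelic imbalance is significant in both contexts independently AND the
## imbalance points in opposite directions; one-context significance is
## context-dependent dominance, not a reversal.

#' Exact binomial test of allelic imbalance
#'
#' Estimate `a1 / (a1 + a2)` with a two-sided exact binomial p-value against
#' the balanced null of 0.5. Zero total depth yields a missing result.
#'
#' @param a1,a2 Non-negative integer read counts of the two alleles.
#' @return A list with `estimate` and `pValue` (both `NA` at zero depth).
#' @examples
#' aseImbalanceTest(90, 10)
#' @export
aseImbalanceTest <- function(a1, a2) {
  if (length(a1) != 1L || length(a2) != 1L || a1 < 0 || a2 < 0 ||
      a1 != round(a1) || a2 != round(a2)) {
    stop("a1 and a2 must be single non-negative integer counts")
  }
  n <- a1 + a2
  if (n == 0) return(list(estimate = NA_real_, pValue = NA_real_))
  list(estimate = a1 / n, pValue = binom.test(a1, n, p = 0.5)$p.value)
}

#' Classify genes by allele-specific expression pattern across two contexts
#'
#' Per gene and context, the allele-1 fraction is tested against 0.5 with an
#' exact binomial test; p-values are adjusted across genes within each
#' context. Classification:
#' \describe{
#'   \item{reversal}{significant in both contexts with opposite imbalance
#'     directions (one estimate above 0.5, the other below).}
#'   \item{consistent_imbalance}{significant in both contexts, same
#'     direction.}
#'   \item{context_dependent}{significant in exactly one context.}
#'   \item{none}{significant in neither.}
#' }
#' A reversal call is never issued for same-direction imbalances, regardless
#' of p-values. Genes lacking counts (zero depth) in a context are skipped
#' with a reason.
#'
#' @param counts Data frame with columns `gene`, `context`, `allele1_count`,
#'   `allele2_count` (two rows per gene, one per context).
#' @param alpha Per-context significance level applied to adjusted p-values.
#' @param mtMethod Multiple-testing adjustment within context: `"bh"`
#'   (Benjamini-Hochberg, default), `"bonferroni"` or `"none"`.
#' @return A data frame with one row per gene: per-context estimates, raw and
#'   adjusted p-values, `classification`, and `skipReason` (`NA` for tested
#'   genes). The two context labels are stored in the `contexts` attribute.
#' @examples
#' tab <- data.frame(gene = c("g1", "g1"), context = c("c1", "c2"),
#'                   allele1_count = c(90, 10), allele2_count = c(10, 90))
#' classifyAseReversal(tab)
#' @export
classifyAseReversal <- function(counts, alpha = 0.05,
                                mtMethod = c("bh", "bonferroni", "none")) {
  mtMethod <- match.arg(mtMethod)
  adjust <- c(bh = "BH", bonferroni = "bonferroni", none = "none")[mtMethod]
  need <- c("gene", "context", "allele1_count", "allele2_count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  ctxs <- sort(unique(as.character(counts$context)))
  if (length(ctxs) != 2L) {
    stop("exactly two contexts are required, found ", length(ctxs))
  }
  genes <- unique(as.character(counts$gene))
  key <- paste(counts$gene, counts$context)
  est <- p <- matrix(NA_real_, length(genes), 2L,
                     dimnames = list(genes, ctxs))
  skip <- rep(NA_character_, length(genes))
  for (gi in seq_along(genes)) {
    for (ci in 1:2) {
      row <- match(paste(genes[gi], ctxs[ci]), key)
      if (is.na(row)) {
        skip[gi] <- paste0("missing context '", ctxs[ci], "'")
        next
      }
      tst <- aseImbalanceTest(counts$allele1_count[row],
                              counts$allele2_count[row])
      if (is.na(tst$pValue)) {
        skip[gi] <- paste0("zero depth in context '", ctxs[ci], "'")
      } else {
        est[gi, ci] <- tst$estimate
        p[gi, ci] <- tst$pValue
      }
    }
  }
  testable <- is.na(skip)
  padj <- p
  padj[testable, 1L] <- p.adjust(p[testable, 1L], method = adjust)
  padj[testable, 2L] <- p.adjust(p[testable, 2L], method = adjust)
  padj[!testable, ] <- NA_real_
  sig <- padj <= alpha
  opposite <- (est[, 1L] - 0.5) * (est[, 2L] - 0.5) < 0
  classification <- rep(NA_character_, length(genes))
  both <- testable & sig[, 1L] & sig[, 2L]
  classification[testable] <- "none"
  classification[testable & xor(sig[, 1L], sig[, 2L])] <- "context_dependent"
  classification[both & opposite] <- "reversal"
  classification[both & !opposite] <- "consistent_imbalance"
  out <- data.frame(
    gene = genes,
    estimate_1 = est[, 1L], estimate_2 = est[, 2L],
    p_1 = p[, 1L], p_2 = p[, 2L],
    padj_1 = padj[, 1L], padj_2 = padj[, 2L],
    classification = classification, skipReason = skip,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "contexts") <- ctxs
  attr(out, "alpha") <- alpha
  attr(out, "mtMethod") <- mtMethod
  out
}

#' Read / write allele-specific count tables
#'
#' TSV dialect: columns `gene`, `context`, `allele1_count`, `allele2_count`.
#'
#' @param path File path.
#' @param counts A counts data frame.
#' @return `readAseCountsTSV` returns the counts data frame;
#'   `writeAseCountsTSV` returns `path` invisibly.
#' @export
readAseCountsTSV <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readAseCountsTSV
#' @export
writeAseCountsTSV <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
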