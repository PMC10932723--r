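## The biophysical dominance-modifier network: mismatch-dependent binding of
## the sex-limited stimulus D to the cis-regulatory alpha sites of Gene A,
## allele-specific concentration of the A product, competitive occupancy of
## the downstream beta sites of Gene B, and the standardized expression
## phenotype phi.

#' Construct regulatory-network parameters
#'
#' Defaults give an 8-nt binding-site alphabet with sex-specific stimulus
#' recognition sequences that differ at 4/8 positions, a founding alpha site
#' equidistant (2/8 mismatches) from both, and a founding beta site matched
#' exactly by the A2 product but mismatched at 2/8 positions by A1 -- so A2 is
#' intrinsically dominant at the beta site while neither coding allele starts
#' with a sex-biased cis advantage upstream.
#'
#' The default `k = 256` corresponds to a twofold change in the dissociation
#' constant per mismatched nucleotide (`2^8` in the mismatch-proportion form
#' used by [fractionalOccupancy()]).
#'
#' @param k Stepwise dissociation-constant multiplier (> 1), applied as
#'   `k^m` with `m` the mismatch proportion.
#' @param Dconc Concentration of the regulatory stimulus D.
#' @param Amax Proportionality constant mapping occupancy to `[A_i]`.
#' @param effectA1,effectA2 Contributions of bound A1/A2 to `[B]`
#'   (`effectA1 < effectA2`).
#' @param Lsite Binding-site length (nt).
#' @param stimF,stimM,recogA1,recogA2,alpha0,beta0 Sequences (character or
#'   integer-encoded), each of length `Lsite`.
#' @return A [RegNetParams-class] object.
#' @examples
#' p <- regNetParams()
#' networkBMax(p)
#' @export
regNetParams <- function(k = 256, Dconc = 1, Amax = 1,
                         effectA1 = 0, effectA2 = 1, Lsite = 8L,
                         stimF = "AAAAAAAA", stimM = "CCCCAAAA",
                         recogA1 = "TGGGGGGG", recogA2 = "GGGGGGGG",
                         alpha0 = "AACCAAAA", beta0 = "GGGGGGGG") {
  new("RegNetParams",
    k = as.numeric(k), Dconc = as.numeric(Dconc), Amax = as.numeric(Amax),
    effectA1 = as.numeric(effectA1), effectA2 = as.numeric(effectA2),
    Lsite = as.integer(Lsite),
    stimF = asSiteSeq(stimF, "stimF"), stimM = asSiteSeq(stimM, "stimM"),
    recogA1 = asSiteSeq(recogA1, "recogA1"),
    recogA2 = asSiteSeq(recogA2, "recogA2"),
    alpha0 = asSiteSeq(alpha0, "alpha0"), beta0 = asSiteSeq(beta0, "beta0")
  )
}

setMethod("show", "RegNetParams", function(object) {
  cat("RegNetParams: L =", object@Lsite, " k =", object@k,
      " [D] =", object@Dconc, " Amax =", object@Amax, "\n")
  cat("  stimulus  F:", siteToChar(object@stimF),
      " M:", siteToChar(object@stimM), "\n")
  cat("  A1 recog:", siteToChar(object@recogA1),
      " (effect", object@effectA1, ")  A2 recog:",
      siteToChar(object@recogA2), " (effect", object@effectA2, ")\n")
  cat("  founding alpha:", siteToChar(object@alpha0),
      " beta:", siteToChar(object@beta0), "\n")
})

#' Construct a diploid network genotype
#'
#' @param sex `"female"` or `"male"`.
#' @param coding Character vector of length 2 over `{"A1","A2"}`.
#' @param params A [RegNetParams-class]; supplies founding sequences when
#'   `alpha`/`beta` are not given.
#' @param alpha,beta Optional lists of two sequences (character or integer).
#' @return A [RegNetGenotype-class].
#' @examples
#' g <- regNetGenotype("male", c("A1", "A2"))
#' expressionB(g, regNetParams())
#' @export
regNetGenotype <- function(sex, coding = c("A1", "A2"),
                           params = regNetParams(),
                           alpha = NULL, beta = NULL) {
  toMat <- function(x, default) {
    if (is.null(x)) {
      matrix(rep(default, 2), nrow = 2, byrow = TRUE)
    } else {
      stopifnot(length(x) == 2L)
      rbind(asSiteSeq(x[[1L]], "site"), asSiteSeq(x[[2L]], "site"))
    }
  }
  new("RegNetGenotype", sex = sex, coding = coding,
      alpha = toMat(alpha, params@alpha0), beta = toMat(beta, params@beta0))
}

setMethod("show", "RegNetGenotype", function(object) {
  cat("RegNetGenotype (", object@sex, ")\n", sep = "")
  for (i in 1:2) {
    cat("  hap", i, ": alpha ", siteToChar(object@alpha[i, ]), " - ",
        object@coding[i], " | beta ", siteToChar(object@beta[i, ]), "\n",
        sep = "")
  }
})

#' Proportion of mismatched nucleotides between two sites
#'
#' The Hamming distance between two equal-length binding sites divided by
#' their length; symmetric in its arguments.
#'
#' @param site,probe Sequences (character strings or integer codes) of equal
#'   length.
#' @return A proportion in `[0, 1]`.
#' @examples
#' mismatchProportion("AAAAAAAA", "AACCAAAA") # 0.25
#' @export
mismatchProportion <- function(site, probe) {
  a <- asSiteSeq(site, "site")
  b <- asSiteSeq(probe, "probe")
  if (length(a) != length(b)) {
    stop("binding sites differ in length: ", length(a), " vs ", length(b))
  }
  mean(a != b)
}

#' Fractional occupancy of a cis-regulatory site by the stimulus
#'
#' Equilibrium occupancy of one allelic copy of an alpha site by the
#' regulatory stimulus at concentration `Dconc`, with binding weakened by a
#' factor `k` per unit mismatch proportion `m`:
#' \deqn{occ = \frac{[D]/k^m}{1 + 2[D]/k^m}.}
#' The 2 in the denominator reflects the two diploid copies of the regulated
#' gene competing for the stimulus, so occupancy is bounded above by 0.5.
#'
#' @param Dconc Stimulus concentration (>= 0); vectorized.
#' @param k Dissociation-constant step (> 1).
#' @param m Mismatch proportion in `[0, 1]`; vectorized.
#' @return Occupancy values in `[0, 0.5)`.
#' @examples
#' fractionalOccupancy(0.5, 2, 0)    # 0.25
#' fractionalOccupancy(1, 2, 0.5)    # ~0.2929
#' @export
fractionalOccupancy <- function(Dconc, k, m) {
  if (any(k <= 1)) stop("k must be > 1")
  if (any(m < 0 | m > 1)) stop("mismatch proportion m must be in [0, 1]")
  if (any(Dconc < 0)) stop("Dconc must be >= 0")
  x <- Dconc / k^m
  x / (1 + 2 * x)
}

#' Allele-specific concentration of an A product
#'
#' `[A_i] = Amax * occ([D], k, m)` where the mismatch `m` is computed between
#' the haplotype's alpha site and the stimulus recognition sequence of the
#' individual's sex. Mutations in the alpha site linked to one coding allele
#' that lower its mismatch in one sex raise that allele's concentration in
#' that sex -- the dominance-modifier mechanism.
#'
#' @param alphaSite The haplotype's alpha site (character or integer codes).
#' @param sex `"female"` or `"male"`.
#' @param params A [RegNetParams-class].
#' @return A non-negative concentration.
#' @examples
#' p <- regNetParams(Dconc = 0.5)
#' alleleConcentration(p@stimM, "male", p) # perfect match: 0.25 * Amax
#' @export
alleleConcentration <- function(alphaSite, sex, params) {
  if (!sex %in% c("female", "male")) stop("sex must be 'female' or 'male'")
  stim <- if (sex == "female") params@stimF else params@stimM
  m <- mismatchProportion(alphaSite, stim)
  params@Amax * fractionalOccupancy(params@Dconc, params@k, m)
}

#' Competitive occupancy of a binding site by several transcription factors
#'
#' Thermodynamic competition of `n` factors for one site:
#' \deqn{occ_i = \frac{c_i/k^{m_i}}{1 + \sum_j c_j/k^{m_j}},}
#' with `m_i` the mismatch proportion between factor `i`'s recognition
#' sequence and the site. Occupancies are in `[0, 1)` and sum to < 1; with a
#' single factor the expression reduces to the Michaelis-like form
#' `c / (k^m + c)`.
#'
#' @param beta The binding site.
#' @param conc Numeric vector of factor concentrations (>= 0).
#' @param recog List of recognition sequences, one per factor.
#' @param k Dissociation-constant step (> 1).
#' @return Numeric vector of per-factor occupancies.
#' @examples
#' competitiveSiteOccupancy("AAAA", c(1, 1), list("AAAA", "CCCC"), k = 2)
#' @export
competitiveSiteOccupancy <- function(beta, conc, recog, k) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (length(conc) != length(recog)) {
    stop("one recognition sequence is required per concentration")
  }
  m <- vapply(recog, function(r) mismatchProportion(beta, r), numeric(1))
  w <- conc / k^m
  w / (1 + sum(w))
}

#' Expression level of the downstream Gene B
#'
#' Each of the genotype's two beta sites is competitively bound by the two A
#' products (at their sex- and alpha-dependent concentrations, via
#' [competitiveSiteOccupancy()]); the site's contribution to `[B]` is the
#' allelic effect of whatever is bound, i.e. the normalized-occupancy
#' (bound-fraction share) average of the two allele effects:
#' \deqn{[B] = \sum_{sites} \sum_i \frac{occ_i}{\sum_j occ_j}\; e_i.}
#' Homozygote expression therefore depends only on the coding alleles (A1A1
#' gives `2 * effectA1`, A2A2 gives `2 * effectA2` whenever any product is
#' present), while heterozygote expression tracks the *relative* allelic
#' occupancies -- cis-regulatory variation acts as a dominance modifier, not
#' as an expression switch. A silent network (all concentrations zero)
#' gives `[B] = 0`. Deterministic given the genotype and parameters; bounded
#' by twice the maximal allele effect.
#'
#' @param g A [RegNetGenotype-class].
#' @param params A [RegNetParams-class].
#' @return `[B] >= 0`.
#' @export
expressionB <- function(g, params) {
  conc <- vapply(1:2, function(i) {
    alleleConcentration(g@alpha[i, ], g@sex, params)
  }, numeric(1))
  recog <- lapply(g@coding, function(cd) {
    if (cd == "A2") params@recogA2 else params@recogA1
  })
  eff <- ifelse(g@coding == "A2", params@effectA2, params@effectA1)
  B <- 0
  for (s in 1:2) {
    occ <- competitiveSiteOccupancy(g@beta[s, ], conc, recog, params@k)
    tot <- sum(occ)
    if (tot > 0) B <- B + sum(occ / tot * eff)
  }
  B
}

#' Network-maximal expression of Gene B
#'
#' `[B]` of the all-A2 genotype with an active stimulus (both sites fully
#' allocated to the strong allele): `2 * effectA2`. This deterministic,
#' run-independent scale is used to standardize phi.
#'
#' @param params A [RegNetParams-class].
#' @return The analytic maximum of `[B]`.
#' @export
networkBMax <- function(params) {
  2 * params@effectA2
}

#' Standardized expression phenotype phi
#'
#' `phi = min(1, B / Bmax)` with `Bmax` the analytic network maximum; phi is
#' the trait under (sexually) antagonistic selection. When the stimulus
#' concentration is zero the network is silent and phi is 0 by convention.
#'
#' @param B Expression level of Gene B (>= 0); vectorized.
#' @param params A [RegNetParams-class].
#' @return Values in `[0, 1]`.
#' @export
phiFromB <- function(B, params) {
  if (any(B < 0)) stop("B must be >= 0")
  Bmax <- networkBMax(params)
  if (Bmax == 0) return(rep(0, length(B)))
  pmin(1, B / Bmax)
}

#' Phenotype of a single genotype
#'
#' Convenience composition `phiFromB(expressionB(g, params), params)`.
#'
#' @inheritParams expressionB
#' @return phi in `[0, 1]`.
#' @export
genotypePhi <- function(g, params) {
  phiFromB(expressionB(g, params), params)
}
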