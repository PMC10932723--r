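## S4 class definitions for the package's central containers.

setClassUnion("integerOrNA", c("integer", "logical"))

#' Parameters of the three-part regulatory network
#'
#' Holds the biophysical constants and the fixed sequences of the
#' dominance-modifier network: the sex-limited stimulus D binds the mutable
#' cis-regulatory site alpha_i of Gene A, whose protein product competes for
#' the mutable site beta_i of the downstream Gene B. Binding strength decays
#' with sequence mismatch by a factor `k` per unit mismatch proportion.
#'
#' @slot k Stepwise change in the dissociation constant (> 1); each unit of
#'   mismatch proportion weakens binding by this factor.
#' @slot Dconc Concentration of the regulatory stimulus D (>= 0).
#' @slot Amax Proportionality constant converting fractional occupancy of an
#'   alpha site into allele-specific protein concentration.
#' @slot effectA1,effectA2 Per-unit-occupancy contribution of the A1 and A2
#'   protein variants to the expression of Gene B, in `[0, 1]` with
#'   `effectA1 < effectA2` (A1 decreases, A2 increases `[B]`).
#' @slot Lsite Binding-site length in nucleotides.
#' @slot stimF,stimM Sex-specific recognition sequences of the stimulus D
#'   (integer-encoded); equal sequences remove all sex specificity.
#' @slot recogA1,recogA2 Fixed recognition sequences of the A1 and A2 protein
#'   variants for the beta sites; A2 starts with the lower mismatch to the
#'   initial beta site (its intrinsic dominance).
#' @slot alpha0,beta0 Initial alpha and beta site sequences used when
#'   populations are founded.
#' @export
setClass("RegNetParams",
  representation(
    k = "numeric", Dconc = "numeric", Amax = "numeric",
    effectA1 = "numeric", effectA2 = "numeric", Lsite = "integer",
    stimF = "integer", stimM = "integer",
    recogA1 = "integer", recogA2 = "integer",
    alpha0 = "integer", beta0 = "integer"
  )
)

setValidity("RegNetParams", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k <= 1) {
    msg <- c(msg, "k must be a single value > 1 (mismatches must weaken binding)")
  }
  if (length(object@Dconc) != 1L || object@Dconc < 0) {
    msg <- c(msg, "Dconc must be >= 0")
  }
  if (length(object@Amax) != 1L || object@Amax <= 0) {
    msg <- c(msg, "Amax must be > 0")
  }
  if (object@effectA1 < 0 || object@effectA2 > 1 ||
      object@effectA1 >= object@effectA2) {
    msg <- c(msg, "effects must satisfy 0 <= effectA1 < effectA2 <= 1")
  }
  L <- object@Lsite
  for (s in c("stimF", "stimM", "recogA1", "recogA2", "alpha0", "beta0")) {
    v <- slot(object, s)
    if (length(v) != L) msg <- c(msg, paste0(s, " must have length Lsite = ", L))
    if (any(v < 1L | v > 4L)) msg <- c(msg, paste0(s, " must be encoded in 1:4"))
  }
  if (length(msg)) msg else TRUE
})

#' Diploid genotype of the regulatory network
#'
#' One individual's state: a sex, two alpha-A haplotypes (mutable alpha site
#' fully linked to an immutable coding allele A1 or A2) and two beta-B
#' haplotypes (mutable beta site; the coding domain of B carries no allelic
#' variation). Genes D, A and B are unlinked.
#'
#' @slot sex `"female"` or `"male"`.
#' @slot coding Character vector of length 2, each `"A1"` or `"A2"`.
#' @slot alpha Integer matrix (2 x Lsite), one alpha site per A haplotype.
#' @slot beta Integer matrix (2 x Lsite), one beta site per B haplotype.
#' @export
setClass("RegNetGenotype",
  representation(sex = "character", coding = "character",
                 alpha = "matrix", beta = "matrix")
)

setValidity("RegNetGenotype", function(object) {
  msg <- character()
  if (!object@sex %in% c("female", "male")) msg <- c(msg, "sex must be 'female' or 'male'")
  if (length(object@coding) != 2L || !all(object@coding %in% c("A1", "A2"))) {
    msg <- c(msg, "coding must be two values in {'A1','A2'}")
  }
  if (nrow(object@alpha) != 2L || nrow(object@beta) != 2L) {
    msg <- c(msg, "alpha and beta must each hold exactly two haplotype rows")
  }
  if (ncol(object@alpha) != ncol(object@beta)) {
    msg <- c(msg, "alpha and beta sites must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' Full parameterization of a simulation run
#'
#' @slot N Population size (even; N/2 individuals of each sex).
#' @slot nGenerations Number of discrete generations to simulate.
#' @slot muSite Per-nucleotide, per-generation mutation rate at alpha and beta
#'   sites.
#' @slot fitnessShape `"linear"` or `"gaussian"` phenotype-fitness map.
#' @slot sF,sM Linear selection coefficients (selection favouring high phi in
#'   females, low phi in males).
#' @slot thetaF,thetaM,omega Gaussian optima per sex and shared width (used
#'   when `fitnessShape == "gaussian"`).
#' @slot net A [RegNetParams-class] object.
#' @slot initFreqA2 Initial frequency of the female-benefit coding allele A2.
#' @slot modifierEnabled When `FALSE`, alpha sites never mutate (the
#'   dominance modifier is switched off); beta sites still mutate.
#' @slot equalizeStimulus When `TRUE` the male recognition sequence of D is
#'   replaced by the female one (sex-equalized control, removing the network's
#'   sex-specific comparison target).
#' @slot recordEvery Trajectory thinning interval (1 records every
#'   generation; the initial, final and loss generations are always recorded).
#' @slot seed Integer seed (NA leaves the RNG state untouched).
#' @export
setClass("SimConfig",
  representation(
    N = "integer", nGenerations = "integer", muSite = "numeric",
    fitnessShape = "character", sF = "numeric", sM = "numeric",
    thetaF = "numeric", thetaM = "numeric", omega = "numeric",
    net = "RegNetParams", initFreqA2 = "numeric",
    modifierEnabled = "logical", equalizeStimulus = "logical",
    recordEvery = "integer", seed = "integerOrNA"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@N < 2L || object@N %% 2L != 0L) {
    msg <- c(msg, "N must be even (equal numbers of females and males)")
  }
  if (object@nGenerations < 0L) msg <- c(msg, "nGenerations must be >= 0")
  if (object@muSite < 0 || object@muSite > 1) msg <- c(msg, "muSite must be in [0, 1]")
  if (!object@fitnessShape %in% c("linear", "gaussian")) {
    msg <- c(msg, "fitnessShape must be 'linear' or 'gaussian'")
  }
  if (object@sF < 0 || object@sF >= 1 || object@sM < 0 || object@sM >= 1) {
    msg <- c(msg, "selection coefficients must be in [0, 1)")
  }
  if (object@omega <= 0) msg <- c(msg, "omega must be > 0")
  if (object@initFreqA2 < 0 || object@initFreqA2 > 1) {
    msg <- c(msg, "initFreqA2 must be in [0, 1]")
  }
  if (object@recordEvery < 1L) msg <- c(msg, "recordEvery must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A simulated population of network genotypes
#'
#' Column-compact representation of N diploid individuals: per-haplotype
#' coding-allele indicators and integer site matrices. Haplotype 1 is the
#' maternally inherited copy after the first generation.
#'
#' @slot female Logical vector of length N.
#' @slot cod1,cod2 Logical vectors: `TRUE` when the haplotype carries A2.
#' @slot alpha1,alpha2,beta1,beta2 Integer N x Lsite site matrices.
#' @slot generation Generation counter (0 at founding).
#' @export
setClass("RegNetPopulation",
  representation(
    female = "logical", cod1 = "logical", cod2 = "logical",
    alpha1 = "matrix", alpha2 = "matrix",
    beta1 = "matrix", beta2 = "matrix", generation = "integer"
  )
)

setValidity("RegNetPopulation", function(object) {
  n <- length(object@female)
  dims <- vapply(list(object@cod1, object@cod2), length, 1L)
  rows <- vapply(
    list(object@alpha1, object@alpha2, object@beta1, object@beta2), nrow, 1L
  )
  if (any(dims != n) || any(rows != n)) {
    return("all per-individual structures must have N rows")
  }
  TRUE
})

#' Per-generation record of a simulation run
#'
#' @slot records Data frame with one row per recorded generation: allele
#'   frequency, mean phi by sex and A-locus genotype, mean fitness by sex,
#'   heterozygote allele-specific expression ratio by sex, mean stimulus
#'   mismatch by sex and linked allele, heterozygote counts.
#' @slot config The [SimConfig-class] that produced the run.
#' @slot lossGeneration Generation at which the A1/A2 polymorphism was lost
#'   (fixation of either coding allele), or `NA` if retained throughout.
#' @slot engine `"cpp"` or `"R"`.
#' @export
setClass("Trajectory",
  representation(records = "data.frame", config = "SimConfig",
                 lossGeneration = "integerOrNA", engine = "character")
)

#' Two-sex selection regime at a single antagonistic locus
#'
#' Fitness parameterization of the deterministic model: in females the
#' male-benefit allele's homozygote pays `sF` and the heterozygote
#' `hF * sF`; in males the female-benefit allele's homozygote pays `sM` and
#' the heterozygote `hM * sM`. `h = 0.5` is the additive reference; `h < 0.5`
#' in both sexes is a beneficial dominance reversal.
#'
#' @slot sF,sM Selection coefficients in `[0, 1)`.
#' @slot hF,hM Dominance of the locally deleterious allele in each sex, in
#'   `[0, 1]`.
#' @export
setClass("SelectionRegime",
  representation(sF = "numeric", sM = "numeric", hF = "numeric", hM = "numeric")
)

setValidity("SelectionRegime", function(object) {
  n <- length(object@sF)
  if (any(vapply(list(object@sM, object@hF, object@hM), length, 1L) != n)) {
    return("sF, sM, hF, hM must have equal length")
  }
  if (any(object@sF < 0 | object@sF >= 1 | object@sM < 0 | object@sM >= 1)) {
    return("selection coefficients must be in [0, 1)")
  }
  if (any(object@hF < 0 | object@hF > 1 | object@hM < 0 | object@hM > 1)) {
    return("dominance coefficients must be in [0, 1]")
  }
  TRUE
})

#' Genotype-phenotype map for two contexts
#'
#' Trait values of the three genotypes (AA, Aa, aa) in each of two abstract
#' contexts (sexes, environments or generations). By convention context `c1`
#' favours high trait values and `c2` low ones; the `dominance_reversed` mode
#' places the heterozygote nearer the context-beneficial homozygote in each
#' context.
#'
#' @slot traits Numeric 2 x 3 matrix (rows `c1`, `c2`; columns `AA`, `Aa`,
#'   `aa`).
#' @slot mode `"additive"`, `"dominance_reversed"` or `"custom"`.
#' @export
setClass("PhenotypeMap",
  representation(traits = "matrix", mode = "character")
)

#' Phenotype-fitness map for two contexts
#'
#' @slot shape `"linear"` or `"gaussian"`.
#' @slot s Linear selection coefficients (length 2, one per context; slopes
#'   have opposite sign between contexts by construction).
#' @slot theta Gaussian optima (length 2, one per context).
#' @slot omega Shared gaussian width (> 0).
#' @export
setClass("FitnessFunction",
  representation(shape = "character", s = "numeric",
                 theta = "numeric", omega = "numeric")
)

#' Genotype-fitness panel resulting from map composition
#'
#' @slot w Numeric 2 x 3 fitness matrix (contexts x genotypes).
#' @slot hEff Effective dominance of the locally deleterious allele per
#'   context (unclipped; < 0.5 means the locally beneficial allele is
#'   dominant).
#' @slot classification One of `"additive"`, `"reversal_from_phenotype"`,
#'   `"reversal_from_fitness"`, `"reversal_combined"`, `"underdominant"`,
#'   `"other"`.
#' @slot panel Roman panel code i-iv where applicable, else `NA`.
#' @slot underdominant `TRUE` when the marginal (cross-context mean)
#'   heterozygote fitness falls below both marginal homozygote means.
#' @slot marginalW Marginal mean fitness of the three genotypes.
#' @export
setClass("GenotypeFitnessPanel",
  representation(w = "matrix", hEff = "numeric", classification = "character",
                 panel = "character", underdominant = "logical",
                 marginalW = "numeric")
)

#' Full-diallel phenotype data
#'
#' Phenotypes of all ordered strain pairs, including selfs, per context and
#' replicate.
#'
#' @slot data Data frame with columns `strain_a`, `strain_b`, `context`,
#'   `replicate`, `phenotype`; selfs have `strain_a == strain_b`.
#' @export
setClass("DiallelData", representation(data = "data.frame"))

setValidity("DiallelData", function(object) {
  d <- object@data
  need <- c("strain_a", "strain_b", "context", "replicate", "phenotype")
  if (!all(need %in% names(d))) {
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  }
  strains <- sort(unique(c(d$strain_a, d$strain_b)))
  if (length(strains) < 3L) return("a diallel needs at least 3 strains")
  for (ctx in unique(d$context)) {
    dc <- d[d$context == ctx, ]
    selfed <- unique(dc$strain_a[dc$strain_a == dc$strain_b])
    if (!all(strains %in% selfed)) {
      return(paste0("missing self crosses in context '", ctx,
                    "' (selfs are required for array covariances)"))
    }
  }
  TRUE
})

#' Result of a cross-context dominance ordination
#'
#' @slot W Numeric strains x 2 matrix of array covariances (one column per
#'   context).
#' @slot r Pearson correlation of the two W vectors across strains (`NA` when
#'   degenerate).
#' @slot pValue Two-sided permutation p-value (`NA` when degenerate).
#' @slot nPerm Number of permutations used.
#' @slot degenerate `TRUE` when either W vector has (numerically) zero
#'   variance, as for perfectly additive data.
#' @export
setClass("OrdinationResult",
  representation(W = "matrix", r = "numeric", pValue = "numeric",
                 nPerm = "integer", degenerate = "logical")
)
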