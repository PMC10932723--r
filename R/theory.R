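## Deterministic single-locus, two-sex viability model. The female-benefit
## allele F segregates against the male-benefit allele M; viability selection
## acts within each sex before random mating. Invasion conditions and the
## exact recursion quantify how dominance reversal (h < 0.5 in both sexes)
## expands the parameter space of protected polymorphism.

#' Construct a two-sex selection regime
#'
#' All four arguments are vectorized (recycled to a common length), so a
#' regime object can hold a whole parameter grid.
#'
#' @param sF Selection against the male-benefit homozygote in females,
#'   `[0, 1)`.
#' @param sM Selection against the female-benefit homozygote in males.
#' @param hF,hM Dominance of the locally deleterious allele in each sex
#'   (`0.5` = additive; `< 0.5` = beneficial dominance reversal).
#' @return A [SelectionRegime-class].
#' @examples
#' selectionRegime(0.1, 0.1, hF = 0.25, hM = 0.25)
#' @export
selectionRegime <- function(sF, sM, hF = 0.5, hM = 0.5) {
  n <- max(length(sF), length(sM), length(hF), length(hM))
  new("SelectionRegime",
      sF = rep_len(as.numeric(sF), n), sM = rep_len(as.numeric(sM), n),
      hF = rep_len(as.numeric(hF), n), hM = rep_len(as.numeric(hM), n))
}

setMethod("show", "SelectionRegime", function(object) {
  n <- length(object@sF)
  cat("SelectionRegime with", n, "parameter combination(s)\n")
  k <- min(n, 5L)
  print(data.frame(sF = object@sF[1:k], sM = object@sM[1:k],
                   hF = object@hF[1:k], hM = object@hM[1:k]))
  if (n > k) cat("...", n - k, "more\n")
})

#' Genotype fitnesses implied by a selection regime
#'
#' Females: `w(FF) = 1`, `w(FM) = 1 - hF sF`, `w(MM) = 1 - sF`.
#' Males: `w(MM) = 1`, `w(FM) = 1 - hM sM`, `w(FF) = 1 - sM`.
#'
#' @param regime A [SelectionRegime-class] (first element used if vectorized).
#' @return A list with numeric triples `female` and `male`, named FF, FM, MM.
#' @export
genotypeFitnesses <- function(regime) {
  list(
    female = c(FF = 1, FM = 1 - regime@hF[1] * regime@sF[1],
               MM = 1 - regime@sF[1]),
    male = c(FF = 1 - regime@sM[1], FM = 1 - regime@hM[1] * regime@sM[1],
             MM = 1)
  )
}

#' One generation of the two-sex viability recursion
#'
#' Zygotes form by random union of female gametes (allele F at frequency
#' `pF`) and male gametes (frequency `pM`); sex-specific viability selection
#' acts; the function returns post-selection gamete frequencies for each sex.
#' Fixed points at (0, 0) and (1, 1). All arguments vectorized.
#'
#' @param pF,pM Frequencies of the female-benefit allele among female and
#'   male gametes.
#' @param regime A [SelectionRegime-class].
#' @return A list with elements `pF` and `pM`.
#' @export
recursionStep <- function(pF, pM, regime) {
  if (any(pF < 0 | pF > 1 | pM < 0 | pM > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  zFF <- pF * pM
  zFM <- pF * (1 - pM) + pM * (1 - pF)
  zMM <- (1 - pF) * (1 - pM)
  wfFM <- 1 - regime@hF * regime@sF
  wfMM <- 1 - regime@sF
  wmFF <- 1 - regime@sM
  wmFM <- 1 - regime@hM * regime@sM
  Tf <- zFF + zFM * wfFM + zMM * wfMM
  Tm <- zFF * wmFF + zFM * wmFM + zMM
  list(pF = (zFF + 0.5 * zFM * wfFM) / Tf,
       pM = (zFF * wmFF + 0.5 * zFM * wmFM) / Tm)
}

#' Iterate the recursion to an equilibrium
#'
#' Runs the deterministic recursion until per-step changes fall below `tol`
#' in both sexes or `maxGen` is reached, then classifies the outcome.
#' "Polymorphic" requires both converged frequencies bounded away from 0 and
#' 1; frequencies within `boundaryTol` of a boundary are classified as
#' fixation. Non-convergence is flagged in the outcome, not raised.
#' Vectorized over regimes.
#'
#' @param regime A [SelectionRegime-class] (possibly a grid).
#' @param pF0,pM0 Starting frequencies.
#' @param tol Convergence tolerance on per-generation change.
#' @param maxGen Iteration cap.
#' @param boundaryTol Distance from 0/1 below which the state counts as
#'   fixation.
#' @return A data frame with columns `pF`, `pM`, `generations`, `converged`
#'   and `outcome` (one of `"polymorphic"`, `"fixation_female_benefit"`,
#'   `"fixation_male_benefit"`, `"no_convergence"`).
#' @examples
#' iterateToEquilibrium(selectionRegime(0.1, 0.1), maxGen = 1e5)
#' @export
iterateToEquilibrium <- function(regime, pF0 = 0.5, pM0 = pF0,
                                 tol = 1e-12, maxGen = 1e6,
                                 boundaryTol = 1e-6) {
  n <- length(regime@sF)
  pF <- rep_len(pF0, n)
  pM <- rep_len(pM0, n)
  doneGen <- rep_len(NA_integer_, n)
  active <- rep_len(TRUE, n)
  gen <- 0L
  while (any(active) && gen < maxGen) {
    gen <- gen + 1L
    idx <- which(active)
    sub <- selectionRegime(regime@sF[idx], regime@sM[idx],
                           regime@hF[idx], regime@hM[idx])
    stepped <- recursionStep(pF[idx], pM[idx], sub)
    dmax <- pmax(abs(stepped$pF - pF[idx]), abs(stepped$pM - pM[idx]))
    pF[idx] <- stepped$pF
    pM[idx] <- stepped$pM
    conv <- dmax < tol |
      (pmax(pF[idx], pM[idx]) < boundaryTol * 1e-3) |
      (pmin(pF[idx], pM[idx]) > 1 - boundaryTol * 1e-3)
    doneGen[idx[conv]] <- gen
    active[idx[conv]] <- FALSE
  }
  converged <- !is.na(doneGen)
  outcome <- ifelse(!converged, "no_convergence",
    ifelse(pF < boundaryTol & pM < boundaryTol, "fixation_male_benefit",
      ifelse(pF > 1 - boundaryTol & pM > 1 - boundaryTol,
             "fixation_female_benefit", "polymorphic")))
  data.frame(pF = pF, pM = pM,
             generations = ifelse(converged, doneGen, gen),
             converged = converged, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Invasion conditions for both alleles
#'
#' Leading eigenvalues of the boundary linearizations: the female-benefit
#' allele F invades an M-fixed population when
#' `lambdaF = ((1 - hF sF)/(1 - sF) + (1 - hM sM)) / 2 > 1`, and the
#' male-benefit allele invades an F-fixed population when
#' `lambdaM = ((1 - hF sF) + (1 - hM sM)/(1 - sM)) / 2 > 1`. The polymorphism
#' is protected when both exceed 1; values within `tol` of 1 are flagged as
#' boundary cases and not counted as protected.
#'
#' @param regime A [SelectionRegime-class] (vectorized).
#' @param tol Strictness tolerance at the `lambda = 1` boundary.
#' @return A data frame with columns `lambdaF`, `lambdaM`, `protected`,
#'   `boundary`.
#' @examples
#' invasionConditions(selectionRegime(0.1, 0.1)) # lambda ~ 1.0028, protected
#' @export
invasionConditions <- function(regime, tol = 1e-12) {
  wfFM <- 1 - regime@hF * regime@sF
  wmFM <- 1 - regime@hM * regime@sM
  lambdaF <- 0.5 * (wfFM / (1 - regime@sF) + wmFM)
  lambdaM <- 0.5 * (wfFM + wmFM / (1 - regime@sM))
  boundary <- abs(lambdaF - 1) <= tol | abs(lambdaM - 1) <= tol
  protected <- lambdaF > 1 + tol & lambdaM > 1 + tol
  data.frame(lambdaF = lambdaF, lambdaM = lambdaM,
             protected = protected, boundary = boundary)
}

#' Fraction of a selection grid that is protected
#'
#' Evaluates [invasionConditions()] over a grid of `(sF, sM)` pairs at fixed
#' dominance coefficients and returns the protected fraction. Even a partial
#' dominance reversal (h < 0.5) expands this fraction drastically; at
#' `h = 0` every grid point with `s < 1` is protected.
#'
#' @param hF,hM Dominance coefficients.
#' @param sF,sM Grid margins (defaults: 41 values over 0.005..0.5).
#' @return Protected fraction in `[0, 1]`.
#' @examples
#' protectedRegionFraction(0, 0, seq(0.01, 0.3, by = 0.05))
#' @export
protectedRegionFraction <- function(hF, hM,
                                    sF = seq(0.005, 0.5, length.out = 41),
                                    sM = sF) {
  if (length(sF) == 0L || length(sM) == 0L) stop("selection grid is empty")
  grid <- expand.grid(sF = sF, sM = sM)
  inv <- invasionConditions(selectionRegime(grid$sF, grid$sM, hF, hM))
  mean(inv$protected)
}

#' Scan a selection grid and tabulate the protection classification
#'
#' @param hF,hM Dominance coefficients.
#' @param sF,sM Grid margins.
#' @return A data frame with columns `s_f`, `s_m`, `h_f`, `h_m`, `lambda_F`,
#'   `lambda_M`, `protected` (TSV-ready; the CLI `theory-scan` subcommand
#'   writes exactly this table).
#' @export
theoryScan <- function(hF = 0.5, hM = hF,
                       sF = seq(0.005, 0.5, length.out = 41), sM = sF) {
  grid <- expand.grid(sF = sF, sM = sM)
  inv <- invasionConditions(selectionRegime(grid$sF, grid$sM, hF, hM))
  data.frame(s_f = grid$sF, s_m = grid$sM, h_f = hF, h_m = hM,
             lambda_F = inv$lambdaF, lambda_M = inv$lambdaM,
             protected = inv$protected)
}
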