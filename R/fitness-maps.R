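## Composition of genotype-phenotype and phenotype-fitness maps in two
## antagonistic contexts, and classification of the resulting genotype-fitness
## dominance. Contexts are abstract labels: by convention "c1" favours high
## trait values and "c2" favours low ones.

#' Construct a two-context genotype-phenotype map
#'
#' In `"additive"` mode the heterozygote sits exactly at the homozygote
#' midpoint in both contexts. In `"dominance_reversed"` mode it is displaced a
#' fraction `d` of the half-range toward the context-beneficial homozygote in
#' each context (the high-trait homozygote in `c1`, the low-trait one in
#' `c2`); `d = 1` is a complete reversal. `"custom"` takes an explicit 2 x 3
#' trait matrix.
#'
#' @param zAA,zaa Homozygote trait values (shared across contexts).
#' @param mode `"additive"`, `"dominance_reversed"` or `"custom"`.
#' @param d Dominance displacement as a fraction of the half-range, in
#'   `(0, 1]`; used only in reversed mode.
#' @param traits 2 x 3 matrix (rows contexts, columns AA, Aa, aa) for
#'   `"custom"`.
#' @return A [PhenotypeMap-class].
#' @examples
#' phenotypeMap(0, 1, mode = "dominance_reversed", d = 1)
#' @export
phenotypeMap <- function(zAA = 0, zaa = 1,
                         mode = c("additive", "dominance_reversed", "custom"),
                         d = 1, traits = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    if (is.null(traits) || !is.matrix(traits) || any(dim(traits) != c(2, 3))) {
      stop("custom mode requires a 2 x 3 'traits' matrix")
    }
    tr <- traits
  } else {
    mid <- (zAA + zaa) / 2
    if (mode == "additive") {
      het <- c(mid, mid)
    } else {
      if (d <= 0 || d > 1) stop("d must be in (0, 1]")
      zHigh <- max(zAA, zaa)
      zLow <- min(zAA, zaa)
      het <- c(mid + d * (zHigh - mid), mid + d * (zLow - mid))
    }
    tr <- rbind(c(zAA, het[1], zaa), c(zAA, het[2], zaa))
  }
  dimnames(tr) <- list(c("c1", "c2"), c("AA", "Aa", "aa"))
  new("PhenotypeMap", traits = tr, mode = mode)
}

setMethod("show", "PhenotypeMap", function(object) {
  cat("PhenotypeMap (", object@mode, ")\n", sep = "")
  print(round(object@traits, 4))
})

#' Construct a two-context phenotype-fitness map
#'
#' Linear maps implement additive antagonistic selection on a trait in
#' `[0, 1]`: `w_c1 = 1 - s1 * (1 - z)` and `w_c2 = 1 - s2 * z`, so the two
#' contexts have slopes of opposite sign. Gaussian maps implement curved
#' selection toward context-specific optima with shared width.
#'
#' @param shape `"linear"` or `"gaussian"`.
#' @param s1,s2 Linear selection coefficients in `[0, 1)`.
#' @param theta Gaussian optima, length 2 (contexts c1, c2).
#' @param omega Gaussian width (> 0).
#' @return A [FitnessFunction-class].
#' @export
fitnessFunction <- function(shape = c("linear", "gaussian"),
                            s1 = 0.2, s2 = 0.2,
                            theta = c(1, 0), omega = 0.5) {
  shape <- match.arg(shape)
  if (shape == "linear" && (s1 < 0 || s1 >= 1 || s2 < 0 || s2 >= 1)) {
    stop("linear selection coefficients must be in [0, 1)")
  }
  if (shape == "gaussian" && omega <= 0) stop("omega must be > 0")
  new("FitnessFunction", shape = shape, s = c(s1, s2),
      theta = as.numeric(theta), omega = as.numeric(omega))
}

#' Linear (additive) antagonistic fitness
#'
#' The female-like context favours high phi, the male-like context low phi:
#' `w = 1 - sF * (1 - phi)` and `w = 1 - sM * phi` respectively.
#'
#' @param phi Trait value in `[0, 1]`; vectorized.
#' @param context `"female-like"` or `"male-like"`.
#' @param sF,sM Selection coefficients in `[0, 1)`.
#' @return Fitness in `(0, 1]`.
#' @examples
#' linearFitness(0.5, "male-like", sM = 0.2) # 0.9
#' @export
linearFitness <- function(phi, context = c("female-like", "male-like"),
                          sF = 0.2, sM = 0.2) {
  context <- match.arg(context)
  if (sF < 0 || sF >= 1 || sM < 0 || sM >= 1) {
    stop("selection coefficients must be in [0, 1)")
  }
  if (context == "female-like") 1 - sF * (1 - phi) else 1 - sM * phi
}

#' Gaussian stabilizing fitness around a context-specific optimum
#'
#' `w = exp(-(z - theta)^2 / (2 omega^2))`: maximal (1) at the optimum,
#' concave within one width of it and convex beyond.
#'
#' @param z Trait value; vectorized.
#' @param theta Optimum.
#' @param omega Width (> 0).
#' @return Fitness in `(0, 1]`.
#' @export
gaussianFitness <- function(z, theta, omega) {
  if (omega <= 0) stop("omega must be > 0")
  exp(-(z - theta)^2 / (2 * omega^2))
}

evalFitness <- function(ff, z, contextIndex) {
  if (ff@shape == "linear") {
    if (contextIndex == 1L) 1 - ff@s[1] * (1 - z) else 1 - ff@s[2] * z
  } else {
    gaussianFitness(z, ff@theta[contextIndex], ff@omega)
  }
}

#' Effective dominance of the locally deleterious allele
#'
#' `hEff = (wBest - wHet) / (wBest - wWorst)` where best/worst are the
#' homozygote fitnesses. `hEff = 0.5` is additivity; `hEff < 0.5` means the
#' locally beneficial allele is dominant; values are reported unclipped, so
#' `hEff < 0` encodes overdominance and `hEff > 1` underdominance within the
#' context. Undefined (NA) when the homozygotes are equally fit.
#'
#' @param wAA,wAa,waa Genotype fitnesses; vectorized.
#' @return Unclipped effective dominance (NA where undefined).
#' @examples
#' effectiveDominance(1.0, 0.98, 0.9) # 0.2
#' @export
effectiveDominance <- function(wAA, wAa, waa) {
  best <- pmax(wAA, waa)
  worst <- pmin(wAA, waa)
  out <- (best - wAa) / (best - worst)
  out[wAA == waa] <- NA_real_
  out
}

#' Compose a phenotype map with a fitness function
#'
#' Evaluates the fitness of all three genotypes in both contexts, computes the
#' effective dominance per context, and classifies the panel: additive map +
#' linear fitness gives exact additivity for fitness; a reversed map or a
#' curved fitness function (with the heterozygote inside both concave
#' regions), or both, gives a dominance reversal for fitness; widely separated
#' gaussian optima can instead produce net (marginal) underdominance.
#'
#' @param pm A [PhenotypeMap-class].
#' @param ff A [FitnessFunction-class].
#' @param tol Tolerance used for the `hEff = 0.5` boundary and the concavity
#'   check.
#' @return A [GenotypeFitnessPanel-class].
#' @examples
#' composePanel(phenotypeMap(0, 1, "additive"), fitnessFunction("linear"))
#' @export
composePanel <- function(pm, ff, tol = 1e-9) {
  w <- pm@traits
  for (cx in 1:2) w[cx, ] <- evalFitness(ff, pm@traits[cx, ], cx)
  hEff <- c(
    effectiveDominance(w[1, 1], w[1, 2], w[1, 3]),
    effectiveDominance(w[2, 1], w[2, 2], w[2, 3])
  )
  names(hEff) <- rownames(w)
  marginal <- colMeans(w)
  under <- marginal["Aa"] < min(marginal["AA"], marginal["aa"]) - tol
  cls <- "other"
  panel <- NA_character_
  if (under) {
    cls <- "underdominant"
  } else if (pm@mode == "additive" && ff@shape == "linear") {
    cls <- "additive"; panel <- "i"
  } else if (pm@mode == "dominance_reversed" && ff@shape == "linear") {
    cls <- "reversal_from_phenotype"; panel <- "ii"
  } else if (pm@mode == "additive" && ff@shape == "gaussian") {
    hetInConcave <- all(abs(pm@traits[, "Aa"] - ff@theta) < ff@omega - tol)
    if (hetInConcave) {
      cls <- "reversal_from_fitness"; panel <- "iii"
    }
  } else if (pm@mode == "dominance_reversed" && ff@shape == "gaussian") {
    cls <- "reversal_combined"; panel <- "iv"
  }
  new("GenotypeFitnessPanel", w = w, hEff = hEff, classification = cls,
      panel = panel, underdominant = unname(under), marginalW = marginal)
}

setMethod("show", "GenotypeFitnessPanel", function(object) {
  cat("GenotypeFitnessPanel:", object@classification,
      if (!is.na(object@panel)) paste0("(panel ", object@panel, ")"), "\n")
  print(round(object@w, 4))
  cat("hEff:", paste(names(object@hEff), round(object@hEff, 4),
                     sep = " = ", collapse = ", "),
      " underdominant:", object@underdominant, "\n")
})

#' Search a gaussian parameter grid for net underdominance
#'
#' Scans combinations of optimum separation and width for an additive
#' phenotype map under gaussian antagonistic selection whose fitness
#' composition yields a marginally underdominant panel (fitness functions
#' overlapping in their convex vicinities).
#'
#' @param separations Candidate distances between the two optima.
#' @param omegas Candidate gaussian widths.
#' @return A data frame of all scanned parameterizations with their
#'   classification and marginal heterozygote deficit.
#' @export
scanUnderdominance <- function(separations = seq(0.5, 3, by = 0.5),
                               omegas = seq(0.1, 1, by = 0.1)) {
  grid <- expand.grid(separation = separations, omega = omegas)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sep <- grid$separation[i]
    pm <- phenotypeMap(0, sep, mode = "additive")
    ff <- fitnessFunction("gaussian", theta = c(sep, 0),
                          omega = grid$omega[i])
    panel <- composePanel(pm, ff)
    data.frame(
      separation = sep, omega = grid$omega[i],
      classification = panel@classification,
      underdominant = panel@underdominant,
      hetDeficit = min(panel@marginalW["AA"], panel@marginalW["aa"]) -
        panel@marginalW["Aa"]
    )
  })
  do.call(rbind, res)
}
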