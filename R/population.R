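## Individual-based population operations: founding, site mutation, fitness,
## Wright-Fisher reproduction and per-generation metrics. These are the
## reference implementations; runSimulation() dispatches to a compiled engine
## that mirrors them exactly (equivalence is tested).

#' Construct a simulation configuration
#'
#' Defaults follow the study conditions used throughout the package: N = 500,
#' 8-nt sites, per-nucleotide mutation rate 1e-3, `[D]` = 1, k = 2, linear
#' sexually antagonistic selection with `sF = sM = 0.2`, initial A2 frequency
#' 0.5, 5000 generations.
#'
#' @param N Population size (even).
#' @param nGenerations Generations to simulate.
#' @param muSite Per-nucleotide per-generation mutation rate at alpha and
#'   beta sites.
#' @param fitnessShape `"linear"` or `"gaussian"`.
#' @param sF,sM Linear selection coefficients.
#' @param thetaF,thetaM,omega Gaussian optima and width.
#' @param net A [RegNetParams-class] (default [regNetParams()]).
#' @param initFreqA2 Initial frequency of the female-benefit allele A2.
#' @param modifierEnabled Mutate alpha sites? (`FALSE` freezes the modifier.)
#' @param equalizeStimulus Replace the male recognition sequence of D with
#'   the female one (network-dependence control).
#' @param recordEvery Trajectory thinning interval.
#' @param seed Integer seed or `NA`.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(N = 100, nGenerations = 50, seed = 1)
#' @export
simConfig <- function(N = 500, nGenerations = 5000, muSite = 1e-3,
                      fitnessShape = c("linear", "gaussian"),
                      sF = 0.2, sM = 0.2,
                      thetaF = 1, thetaM = 0, omega = 0.5,
                      net = regNetParams(),
                      initFreqA2 = 0.5, modifierEnabled = TRUE,
                      equalizeStimulus = FALSE, recordEvery = 1L,
                      seed = NA_integer_) {
  fitnessShape <- match.arg(fitnessShape)
  if (equalizeStimulus) net@stimM <- net@stimF
  new("SimConfig",
    N = as.integer(N), nGenerations = as.integer(nGenerations),
    muSite = as.numeric(muSite), fitnessShape = fitnessShape,
    sF = as.numeric(sF), sM = as.numeric(sM),
    thetaF = as.numeric(thetaF), thetaM = as.numeric(thetaM),
    omega = as.numeric(omega), net = net,
    initFreqA2 = as.numeric(initFreqA2),
    modifierEnabled = isTRUE(modifierEnabled),
    equalizeStimulus = isTRUE(equalizeStimulus),
    recordEvery = as.integer(recordEvery),
    seed = if (is.na(seed)) NA_integer_ else as.integer(seed)
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: N =", object@N, " generations =", object@nGenerations,
      " mu =", object@muSite, "\n")
  cat("  fitness:", object@fitnessShape,
      if (object@fitnessShape == "linear") {
        paste0("(sF = ", object@sF, ", sM = ", object@sM, ")")
      } else {
        paste0("(thetaF = ", object@thetaF, ", thetaM = ", object@thetaM,
               ", omega = ", object@omega, ")")
      }, "\n")
  cat("  initFreqA2 =", object@initFreqA2,
      " modifier =", object@modifierEnabled,
      " equalizeStimulus =", object@equalizeStimulus,
      " seed =", object@seed, "\n")
})

#' Found a population
#'
#' N individuals, half of each sex; each A haplotype carries A2 independently
#' with probability `initFreqA2`; all alpha sites start at the founding
#' sequence (equidistant from both sex-specific stimulus sequences, so
#' neither coding allele begins with a sex-biased cis advantage) and all beta
#' sites at the founding beta sequence (matched by A2). Consumes RNG draws
#' unless `initFreqA2` is 0 or 1.
#'
#' @param config A [SimConfig-class].
#' @return A [RegNetPopulation-class] at generation 0.
#' @export
initPopulation <- function(config) {
  N <- config@N
  if (N %% 2L != 0L) stop("N must be even")
  net <- config@net
  L <- net@Lsite
  f <- config@initFreqA2
  drawCod <- function() {
    if (f == 0) rep(FALSE, N) else if (f == 1) rep(TRUE, N) else runif(N) < f
  }
  new("RegNetPopulation",
    female = rep(c(TRUE, FALSE), length.out = N),
    cod1 = drawCod(), cod2 = drawCod(),
    alpha1 = matrix(net@alpha0, N, L, byrow = TRUE),
    alpha2 = matrix(net@alpha0, N, L, byrow = TRUE),
    beta1 = matrix(net@beta0, N, L, byrow = TRUE),
    beta2 = matrix(net@beta0, N, L, byrow = TRUE),
    generation = 0L
  )
}

setMethod("show", "RegNetPopulation", function(object) {
  N <- length(object@female)
  cat("RegNetPopulation: N =", N, " generation =", object@generation, "\n")
  cat("  freq(A2) =", mean(c(object@cod1, object@cod2)),
      " females =", sum(object@female), "\n")
})

#' Frequency of the female-benefit coding allele A2
#'
#' @param pop A [RegNetPopulation-class].
#' @return Frequency in `[0, 1]`.
#' @export
freqA2 <- function(pop) {
  mean(c(pop@cod1, pop@cod2))
}

## Allele-specific state of every individual: concentrations of the two A
## haplotype products (given each carrier's sex), own-sex stimulus
## mismatches, [B] and phi. Mirrors the compiled engine.
popState <- function(pop, net) {
  mF1 <- rowMismatch(pop@alpha1, net@stimF)
  mM1 <- rowMismatch(pop@alpha1, net@stimM)
  mF2 <- rowMismatch(pop@alpha2, net@stimF)
  mM2 <- rowMismatch(pop@alpha2, net@stimM)
  m1 <- ifelse(pop@female, mF1, mM1)
  m2 <- ifelse(pop@female, mF2, mM2)
  c1 <- net@Amax * fractionalOccupancy(net@Dconc, net@k, m1)
  c2 <- net@Amax * fractionalOccupancy(net@Dconc, net@k, m2)
  mb <- function(beta, cod) {
    ifelse(cod, rowMismatch(beta, net@recogA2), rowMismatch(beta, net@recogA1))
  }
  eff1 <- ifelse(pop@cod1, net@effectA2, net@effectA1)
  eff2 <- ifelse(pop@cod2, net@effectA2, net@effectA1)
  B <- 0
  for (beta in list(pop@beta1, pop@beta2)) {
    w1 <- c1 / net@k^mb(beta, pop@cod1)
    w2 <- c2 / net@k^mb(beta, pop@cod2)
    tot <- w1 + w2
    B <- B + ifelse(tot > 0, (w1 * eff1 + w2 * eff2) / tot, 0)
  }
  phi <- phiFromB(B, net)
  list(conc1 = c1, conc2 = c2, mStim1 = m1, mStim2 = m2, B = B, phi = phi)
}

#' Fitness of every individual
#'
#' phi via the regulatory network, then the configured phenotype-fitness map
#' with each individual's sex (females favour high phi, males low phi).
#'
#' @param pop A [RegNetPopulation-class].
#' @param config A [SimConfig-class].
#' @return Numeric vector of fitnesses in `(0, 1]`.
#' @export
individualFitness <- function(pop, config) {
  phi <- popState(pop, config@net)$phi
  if (config@fitnessShape == "linear") {
    ifelse(pop@female, 1 - config@sF * (1 - phi), 1 - config@sM * phi)
  } else {
    theta <- ifelse(pop@female, config@thetaF, config@thetaM)
    exp(-(phi - theta)^2 / (2 * config@omega^2))
  }
}

#' Mutate the cis-regulatory sites of a population
#'
#' Each nucleotide of each beta site -- and of each alpha site when the
#' modifier is enabled -- mutates independently with probability `muSite` to
#' a uniformly chosen different symbol. Coding domains and stimulus sequences
#' never change.
#'
#' @param pop A [RegNetPopulation-class].
#' @param muSite Per-nucleotide mutation probability.
#' @param modifierEnabled Mutate alpha sites?
#' @return The mutated population.
#' @export
mutateSites <- function(pop, muSite, modifierEnabled = TRUE) {
  if (muSite <= 0) return(pop)
  mut <- function(m) {
    hit <- which(runif(length(m)) < muSite)
    if (length(hit)) {
      m[hit] <- (m[hit] - 1L + sample(3L, length(hit), replace = TRUE)) %% 4L + 1L
    }
    m
  }
  if (modifierEnabled) {
    pop@alpha1 <- mut(pop@alpha1)
    pop@alpha2 <- mut(pop@alpha2)
  }
  pop@beta1 <- mut(pop@beta1)
  pop@beta2 <- mut(pop@beta2)
  pop
}

## subset rows from hap1/hap2 matrices according to a per-offspring pick
pickRows <- function(m1, m2, fromSecond, idx) {
  out <- m1[idx, , drop = FALSE]
  sw <- which(fromSecond)
  if (length(sw)) out[sw, ] <- m2[idx[sw], , drop = FALSE]
  out
}

#' Produce the next generation
#'
#' Soft selection within sexes: each of the N offspring draws a mother and a
#' father with replacement, with probability proportional to fitness within
#' their sex; one random haplotype per gene per parent is transmitted (alpha-A
#' and beta-B as linked units, the A and B genes assorting independently);
#' offspring sexes are a random permutation of N/2 females and N/2 males;
#' finally sites mutate. Haplotype 1 of each offspring is maternal.
#'
#' @param pop A [RegNetPopulation-class].
#' @param config A [SimConfig-class].
#' @return The next [RegNetPopulation-class].
#' @export
nextGeneration <- function(pop, config) {
  N <- length(pop@female)
  w <- individualFitness(pop, config)
  fi <- which(pop@female)
  mi <- which(!pop@female)
  if (sum(w[fi]) <= 0 || sum(w[mi]) <= 0) {
    stop("degenerate selection: total fitness is zero in one sex")
  }
  mothers <- sample(fi, N, replace = TRUE, prob = w[fi])
  fathers <- sample(mi, N, replace = TRUE, prob = w[mi])
  pickAm <- runif(N) < 0.5   # maternal A haplotype: hap2 when TRUE
  pickAp <- runif(N) < 0.5
  pickBm <- runif(N) < 0.5
  pickBp <- runif(N) < 0.5
  child <- new("RegNetPopulation",
    female = sample(rep(c(TRUE, FALSE), each = N / 2L)),
    cod1 = ifelse(pickAm, pop@cod2[mothers], pop@cod1[mothers]),
    cod2 = ifelse(pickAp, pop@cod2[fathers], pop@cod1[fathers]),
    alpha1 = pickRows(pop@alpha1, pop@alpha2, pickAm, mothers),
    alpha2 = pickRows(pop@alpha1, pop@alpha2, pickAp, fathers),
    beta1 = pickRows(pop@beta1, pop@beta2, pickBm, mothers),
    beta2 = pickRows(pop@beta1, pop@beta2, pickBp, fathers),
    generation = pop@generation + 1L
  )
  mutateSites(child, config@muSite, config@modifierEnabled)
}

#' Heterozygote allele-specific expression ratio by sex
#'
#' Mean over A1A2 heterozygotes of `[A1] / ([A1] + [A2])`, computed from the
#' allele-specific concentrations in each carrier's own sex. A ratio above
#' 0.5 in males and below 0.5 in females is the reversed allele-specific
#' expression signature of the evolved dominance modifier. `NA` where a sex
#' has no heterozygotes (or all concentrations are zero, e.g. `[D] = 0`).
#'
#' @param pop A [RegNetPopulation-class].
#' @param config A [SimConfig-class].
#' @return Named numeric vector `c(female = ..., male = ...)`.
#' @export
aseRatioHeterozygotes <- function(pop, config) {
  st <- popState(pop, config@net)
  het <- pop@cod1 != pop@cod2
  cA1 <- ifelse(pop@cod1, st$conc2, st$conc1)
  cA2 <- ifelse(pop@cod1, st$conc1, st$conc2)
  tot <- cA1 + cA2
  ratio <- ifelse(tot > 0, cA1 / tot, NA_real_)
  out <- c(female = NA_real_, male = NA_real_)
  for (sex in c(TRUE, FALSE)) {
    sel <- het & (pop@female == sex) & !is.na(ratio)
    if (any(sel)) out[if (sex) "female" else "male"] <- mean(ratio[sel])
  }
  out
}

trajectoryColumns <- function() {
  c("generation", "freq_A2",
    "phi_f_A1A1", "phi_f_A1A2", "phi_f_A2A2",
    "phi_m_A1A1", "phi_m_A1A2", "phi_m_A2A2",
    "fitness_f", "fitness_m", "ase_f", "ase_m",
    "m_f_A1", "m_f_A2", "m_m_A1", "m_m_A2",
    "n_het_f", "n_het_m")
}

#' Per-generation metrics of a population
#'
#' One trajectory row: A2 frequency; mean phi by sex and A-locus genotype;
#' mean fitness by sex; heterozygote allele-specific expression ratio by sex;
#' mean own-sex stimulus mismatch of alpha sites by sex and linked coding
#' allele; heterozygote counts.
#'
#' @param pop A [RegNetPopulation-class].
#' @param config A [SimConfig-class].
#' @return A named numeric vector (see [trajectoryColumns][runSimulation]).
#' @export
popMetrics <- function(pop, config) {
  st <- popState(pop, config@net)
  w <- individualFitness(pop, config)
  n2 <- pop@cod1 + pop@cod2
  grpMean <- function(x, sel) if (any(sel)) mean(x[sel]) else NA_real_
  phiBy <- unlist(lapply(c(TRUE, FALSE), function(sex) {
    vapply(0:2, function(k) {
      grpMean(st$phi, pop@female == sex & n2 == k)
    }, numeric(1))
  }))
  ase <- aseRatioHeterozygotes(pop, config)
  hapM <- c(st$mStim1, st$mStim2)
  hapCod <- c(pop@cod1, pop@cod2)
  hapFem <- c(pop@female, pop@female)
  mBy <- unlist(lapply(c(TRUE, FALSE), function(sex) {
    vapply(c(FALSE, TRUE), function(isA2) {
      grpMean(hapM, hapFem == sex & hapCod == isA2)
    }, numeric(1))
  }))
  out <- c(pop@generation, freqA2(pop), phiBy,
           grpMean(w, pop@female), grpMean(w, !pop@female),
           ase["female"], ase["male"], mBy,
           sum(pop@female & n2 == 1L), sum(!pop@female & n2 == 1L))
  names(out) <- trajectoryColumns()
  out
}
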