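## Running simulations and replicate experiments.

#' Run a forward-time simulation of the dominance-modifier network
#'
#' Founds a population from `config`, iterates Wright-Fisher generations under
#' sexually antagonistic selection on phi, and records per-generation metrics
#' until `nGenerations` or until the A1/A2 coding polymorphism is lost. The
#' initial, final and loss generations are always recorded; intermediate
#' generations every `recordEvery`. Fully reproducible from `(config, seed)`.
#'
#' @param config A [SimConfig-class].
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference composition
#'   of [initPopulation()], [nextGeneration()] and [popMetrics()]); both
#'   implement the identical model.
#' @return A [Trajectory-class].
#' @examples
#' traj <- runSimulation(simConfig(N = 50, nGenerations = 20, seed = 1))
#' head(records(traj))
#' @export
runSimulation <- function(config, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  pop <- initPopulation(config)
  net <- config@net
  if (engine == "cpp") {
    res <- .cppSimulate(
      pop@alpha1, pop@alpha2, pop@beta1, pop@beta2,
      pop@cod1, pop@cod2, pop@female,
      net@stimF, net@stimM, net@recogA1, net@recogA2,
      net@Dconc, net@k, net@Amax, net@effectA1, net@effectA2,
      networkBMax(net),
      if (config@fitnessShape == "linear") 0L else 1L,
      config@sF, config@sM, config@thetaF, config@thetaM, config@omega,
      config@muSite, config@modifierEnabled,
      config@nGenerations, config@recordEvery
    )
    rec <- as.data.frame(res$records)
    names(rec) <- trajectoryColumns()
    loss <- if (res$lossGen < 0) NA_integer_ else as.integer(res$lossGen)
  } else {
    rows <- list(popMetrics(pop, config))
    loss <- NA_integer_
    f <- freqA2(pop)
    if (f == 0 || f == 1) {
      loss <- 0L
    } else if (config@nGenerations > 0L) {
      for (g in seq_len(config@nGenerations)) {
        pop <- nextGeneration(pop, config)
        f <- freqA2(pop)
        lost <- f == 0 || f == 1
        if (g %% config@recordEvery == 0L || g == config@nGenerations || lost) {
          rows[[length(rows) + 1L]] <- popMetrics(pop, config)
        }
        if (lost) {
          loss <- g
          break
        }
      }
    }
    rec <- as.data.frame(do.call(rbind, rows))
  }
  new("Trajectory", records = rec, config = config,
      lossGeneration = loss, engine = engine)
}

#' @describeIn runSimulation Accessor: the per-generation record table.
#' @param traj A [Trajectory-class].
#' @export
records <- function(traj) traj@records

#' @describeIn runSimulation Accessor: the generation at which the coding
#'   polymorphism was lost (`NA` if retained).
#' @export
lossGeneration <- function(traj) traj@lossGeneration

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory (", object@engine, " engine): ",
      nrow(object@records), " records over ",
      max(object@records$generation), " generations\n", sep = "")
  rt <- retentionTime(object)
  cat("  polymorphism:",
      if (rt$censored) paste0("retained (censored at ", rt$time, ")")
      else paste0("lost at generation ", rt$time), "\n")
})

#' Retention time of the focal polymorphism
#'
#' First generation at which the A2 frequency hit 0 or 1; right-censored at
#' the configured number of generations when the polymorphism survived the
#' whole run.
#'
#' @param traj A [Trajectory-class].
#' @return A list with `time` (generations) and `censored` (logical).
#' @export
retentionTime <- function(traj) {
  if (!is.na(traj@lossGeneration)) {
    list(time = as.integer(traj@lossGeneration), censored = FALSE)
  } else {
    list(time = traj@config@nGenerations, censored = TRUE)
  }
}

#' Paired sign test
#'
#' Exact binomial sign test on per-pair differences, ties dropped.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"greater"` tests whether `x` tends to exceed `y`.
#' @return A list with `nPlus`, `nMinus`, `nTies` and `pValue`.
#' @export
pairedSignTest <- function(x, y, alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  nPlus <- sum(x[ok] > y[ok])
  nMinus <- sum(x[ok] < y[ok])
  p <- if (nPlus + nMinus == 0) {
    1
  } else {
    binom.test(nPlus, nPlus + nMinus, alternative = alternative)$p.value
  }
  list(nPlus = nPlus, nMinus = nMinus, nTies = sum(ok) - nPlus - nMinus,
       pValue = p)
}

#' Run a replicated multi-arm simulation experiment
#'
#' Runs `nReps` paired replicates of each experimental arm (a named list of
#' configuration overrides, e.g. modifier on/off or stimulus equalized),
#' using the same seed for every arm within a replicate so arms are paired.
#' Summaries per run: retention time (with censoring), polymorphism status at
#' the end, final allele-specific expression ratios by sex, final mean phi of
#' heterozygotes by sex together with the generation-0 (additive) baseline,
#' and final mean fitness by sex.
#'
#' @param baseArgs Named list of [simConfig()] arguments shared by all arms.
#' @param arms Named list; each element is a (possibly empty) list of
#'   [simConfig()] overrides defining one arm.
#' @param nReps Number of paired replicates.
#' @param seeds Integer vector of per-replicate seeds (default
#'   `seq_len(nReps)`).
#' @param engine Simulation engine.
#' @return A data frame with one row per replicate x arm.
#' @examples
#' \donttest{
#' ex <- replicateExperiment(list(N = 100, nGenerations = 200),
#'                           arms = list(off = list(modifierEnabled = FALSE),
#'                                       on = list()),
#'                           nReps = 3)
#' }
#' @export
replicateExperiment <- function(baseArgs = list(),
                                arms = list(off = list(modifierEnabled = FALSE),
                                            on = list()),
                                nReps = 50, seeds = NULL,
                                engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (length(arms) < 2L || is.null(names(arms))) {
    stop("at least two named arms are required")
  }
  if (is.null(seeds)) seeds <- seq_len(nReps)
  stopifnot(length(seeds) == nReps)
  out <- vector("list", nReps * length(arms))
  i <- 0L
  for (rep in seq_len(nReps)) {
    for (arm in names(arms)) {
      args <- modifyList(baseArgs, arms[[arm]])
      args$seed <- seeds[rep]
      cfg <- do.call(simConfig, args)
      traj <- runSimulation(cfg, engine = engine)
      rec <- traj@records
      first <- rec[1L, ]
      last <- rec[nrow(rec), ]
      rt <- retentionTime(traj)
      i <- i + 1L
      out[[i]] <- data.frame(
        replicate = rep, arm = arm, seed = seeds[rep],
        retention = rt$time, censored = rt$censored,
        polymorphicAtEnd = is.na(traj@lossGeneration),
        finalFreqA2 = last$freq_A2,
        aseF = last$ase_f, aseM = last$ase_m,
        phiHetF = last$phi_f_A1A2, phiHetM = last$phi_m_A1A2,
        phiHetF0 = first$phi_f_A1A2, phiHetM0 = first$phi_m_A1A2,
        fitnessF = last$fitness_f, fitnessM = last$fitness_m,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
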