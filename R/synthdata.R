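## Synthetic-data generators with ground truth: diallel phenotype tables
## under three dominance architectures, allele-specific count tables with a
## known fraction of reversed genes, and the small preset fixtures used in
## examples and tests.

#' Simulate a full diallel with known dominance architecture
#'
#' Strains are fixed homozygous lines at `nLoci` biallelic loci (allele 1
#' contributes `+e` to the phenotype in context `c1` and `-e` in `c2`;
#' allele 2 the reverse). Cross phenotypes sum locus contributions: a
#' homozygous locus contributes its allele's effect; a heterozygous locus
#' contributes the midpoint (0) displaced by `d * e` according to the mode --
#' toward the context-beneficial allele in both contexts
#' (`dominance_reversed`), toward a globally dominant allele drawn once per
#' locus (`unconditional`), or not at all (`additive`). Gaussian measurement
#' noise is added per record; selfs and both reciprocals are generated (no
#' parent-of-origin effects).
#'
#' @param nStrains Number of inbred strains (>= 4).
#' @param nLoci Number of biallelic loci.
#' @param mode Dominance architecture.
#' @param effectSize Per-locus homozygote effect `e`.
#' @param domDev Dominance displacement `d` as a fraction of `e`, in
#'   `[0, 1]`; ignored in additive mode.
#' @param noiseSd Environmental (measurement) standard deviation.
#' @param replicates Replicate phenotype records per ordered cross.
#' @param seed Optional integer seed.
#' @return A list with `data` (a [DiallelData-class]) and `truth` (strain
#'   genotypes, mode, and -- for unconditional mode -- the per-locus dominant
#'   allele).
#' @examples
#' sim <- simulateDiallel(nStrains = 6, mode = "additive", noiseSd = 0,
#'                        seed = 1)
#' @export
simulateDiallel <- function(nStrains = 16, nLoci = 50,
                            mode = c("dominance_reversed", "unconditional",
                                     "additive"),
                            effectSize = 1, domDev = 0.8, noiseSd = 0.5,
                            replicates = 2, seed = NULL) {
  mode <- match.arg(mode)
  if (nStrains < 4) stop("nStrains must be >= 4")
  if (nLoci < 1) stop("nLoci must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (domDev < 0 || domDev > 1) stop("domDev must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  strains <- sprintf("S%02d", seq_len(nStrains))
  geno <- matrix(rbinom(nStrains * nLoci, 1, 0.5) + 1L, nStrains, nLoci,
                 dimnames = list(strains, NULL))
  dominant <- if (mode == "unconditional") {
    rbinom(nLoci, 1, 0.5) + 1L
  } else {
    rep(NA_integer_, nLoci)
  }
  e <- effectSize
  ## effect of a homozygous allele on the phenotype, by context
  homEff <- function(allele, ctx) {
    s <- ifelse(allele == 1L, 1, -1)          # allele 1: +e in c1, -e in c2
    if (ctx == 1L) s * e else -s * e
  }
  hetEff <- switch(mode,
    additive = function(ctx, loci) rep(0, length(loci)),
    dominance_reversed = function(ctx, loci) rep(domDev * e, length(loci)),
    unconditional = function(ctx, loci) {
      domDev * homEff(dominant[loci], ctx)
    }
  )
  crossValue <- function(r, s, ctx) {
    same <- geno[r, ] == geno[s, ]
    val <- sum(homEff(geno[r, same], ctx))
    hetLoci <- which(!same)
    if (length(hetLoci)) val <- val + sum(hetEff(ctx, hetLoci))
    val
  }
  pairs <- expand.grid(a = seq_len(nStrains), b = seq_len(nStrains))
  rows <- vector("list", 2L * nrow(pairs))
  i <- 0L
  for (ctx in 1:2) {
    vals <- mapply(crossValue, pairs$a, pairs$b, MoreArgs = list(ctx = ctx))
    for (rep in seq_len(replicates)) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        strain_a = strains[pairs$a], strain_b = strains[pairs$b],
        context = paste0("c", ctx), replicate = rep,
        phenotype = vals + if (noiseSd > 0) {
          rnorm(nrow(pairs), sd = noiseSd)
        } else {
          0
        },
        stringsAsFactors = FALSE
      )
    }
  }
  dd <- diallelData(do.call(rbind, rows[seq_len(i)]))
  list(data = dd,
       truth = list(genotypes = geno, mode = mode, dominantAllele = dominant,
                    effectSize = effectSize, domDev = domDev,
                    noiseSd = noiseSd))
}

#' Simulate allele-specific count tables with known reversal labels
#'
#' Reversed genes draw allele-1 counts Binomial(depth, `rho`) in context `c1`
#' and Binomial(depth, `1 - rho`) in context `c2`; balanced (null) genes use
#' 0.5 in both. Depth is fixed or Poisson per gene and context (zero Poisson
#' draws are bumped to 1 so every gene is testable).
#'
#' @param nGenes Number of genes.
#' @param propReversed Proportion of genes with a true reversal.
#' @param rho True allele-1 fraction of reversed genes in context `c1`.
#' @param depth Fixed depth, or the Poisson mean when
#'   `depthDist = "poisson"`.
#' @param depthDist `"fixed"` or `"poisson"`.
#' @param seed Optional integer seed.
#' @return A list with `counts` (long-format data frame: `gene`, `context`,
#'   `allele1_count`, `allele2_count`) and `truth` (`gene`, `reversed`).
#' @examples
#' sim <- simulateAseCounts(nGenes = 20, propReversed = 0.5, seed = 1)
#' @export
simulateAseCounts <- function(nGenes = 2000, propReversed = 0.1, rho = 0.7,
                              depth = 100, depthDist = c("fixed", "poisson"),
                              seed = NULL) {
  depthDist <- match.arg(depthDist)
  if (propReversed < 0 || propReversed > 1) {
    stop("propReversed must be in [0, 1]")
  }
  if (depth <= 0) stop("depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%05d", seq_len(nGenes))
  reversed <- seq_len(nGenes) <= round(propReversed * nGenes)
  drawDepth <- function(n) {
    if (depthDist == "fixed") rep(as.integer(depth), n) else pmax(1L, rpois(n, depth))
  }
  rows <- lapply(1:2, function(ctx) {
    pTrue <- ifelse(reversed, if (ctx == 1L) rho else 1 - rho, 0.5)
    d <- drawDepth(nGenes)
    a1 <- rbinom(nGenes, d, pTrue)
    data.frame(gene = genes, context = paste0("c", ctx),
               allele1_count = a1, allele2_count = d - a1,
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  counts <- counts[order(counts$gene, counts$context), ]
  rownames(counts) <- NULL
  list(counts = counts,
       truth = data.frame(gene = genes, reversed = reversed,
                          stringsAsFactors = FALSE))
}

#' Preset fixtures used in examples and tests
#'
#' Available fixtures:
#' \describe{
#'   \item{`diallel3_additive`}{Noiseless 3-strain purely additive diallel
#'     (cross = midparent); its array covariances are constant, the
#'     degenerate ordination case.}
#'   \item{`box1_default`}{The default [simConfig()] of the regulatory
#'     network simulation.}
#'   \item{`ase10`}{A 10-gene allele-specific count table containing one
#'     clear reversal, one context-dependent gene, one consistent imbalance,
#'     one zero-depth gene and six balanced genes.}
#' }
#'
#' @param name Fixture name.
#' @return The fixture object (type depends on the fixture).
#' @examples
#' presetFixture("ase10")
#' @export
presetFixture <- function(name) {
  fixtures <- c("diallel3_additive", "box1_default", "ase10")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  }
  switch(name,
    diallel3_additive = {
      selfs <- c(S1 = 0, S2 = 1, S3 = 2)
      grid <- expand.grid(a = names(selfs), b = names(selfs),
                          ctx = c("c1", "c2"), stringsAsFactors = FALSE)
      diallelData(data.frame(
        strain_a = grid$a, strain_b = grid$b, context = grid$ctx,
        replicate = 1L,
        phenotype = (selfs[grid$a] + selfs[grid$b]) / 2,
        stringsAsFactors = FALSE
      ))
    },
    box1_default = simConfig(),
    ase10 = {
      a1c1 <- c(90L, 90L, 90L, 0L, 52L, 48L, 50L, 55L, 45L, 50L)
      a1c2 <- c(10L, 55L, 90L, 50L, 50L, 50L, 47L, 53L, 50L, 49L)
      d1 <- rep(100L, 10L); d1[4L] <- 0L
      data.frame(
        gene = rep(sprintf("g%02d", 1:10), each = 2L),
        context = rep(c("c1", "c2"), 10L),
        allele1_count = as.vector(rbind(a1c1, a1c2)),
        allele2_count = as.vector(rbind(d1 - a1c1, 100L - a1c2)),
        stringsAsFactors = FALSE
      )
    }
  )
}
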