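## small diallel constructors used across tests
midparentDiallel <- function(selfs, contexts = c("c1", "c2")) {
  strains <- names(selfs)
  grid <- expand.grid(a = strains, b = strains, ctx = contexts,
                      stringsAsFactors = FALSE)
  diallelData(data.frame(
    strain_a = grid$a, strain_b = grid$b, context = grid$ctx, replicate = 1L,
    phenotype = (selfs[grid$a] + selfs[grid$b]) / 2,
    stringsAsFactors = FALSE
  ))
}

test_that("array covariance matches brute-force covariance conventions", {
  selfs <- c(S1 = 0.3, S2 = 1.1, S3 = 2.0, S4 = 3.7)
  dd <- midparentDiallel(selfs)
  # additive diallel: W_r = var(selfs) / 2, identical for every strain
  for (s in names(selfs)) {
    expect_equal(arrayCovariance(dd, s, "c1"), var(selfs) / 2)
  }
  # adding a constant within a context leaves W unchanged
  shifted <- dd@data
  shifted$phenotype[shifted$context == "c1"] <-
    shifted$phenotype[shifted$context == "c1"] + 100
  expect_equal(arrayCovariance(diallelData(shifted), "S2", "c1"),
               arrayCovariance(dd, "S2", "c1"))
  # reciprocals and replicates are averaged: brute-force check
  set.seed(3)
  d2 <- dd@data
  d2$phenotype <- d2$phenotype + rnorm(nrow(d2), sd = 0.2)
  dd2 <- diallelData(d2)
  m <- sapply(names(selfs), function(a) {
    sapply(names(selfs), function(b) {
      mean(d2$phenotype[d2$context == "c1" &
                          ((d2$strain_a == a & d2$strain_b == b) |
                             (d2$strain_a == b & d2$strain_b == a))])
    })
  })
  expect_equal(arrayCovariance(dd2, "S3", "c1"), cov(m["S3", ], diag(m)))
})

test_that("a fully dominant strain has zero array covariance", {
  selfs <- c(A = 1, B = 2, C = 3)
  d <- expand.grid(a = names(selfs), b = names(selfs),
                   ctx = c("c1", "c2"), stringsAsFactors = FALSE)
  pheno <- mapply(function(a, b) {
    if (a == "A" || b == "A") selfs["A"] else (selfs[a] + selfs[b]) / 2
  }, d$a, d$b)
  dd <- diallelData(data.frame(strain_a = d$a, strain_b = d$b,
                               context = d$ctx, replicate = 1L,
                               phenotype = pheno, stringsAsFactors = FALSE))
  expect_equal(arrayCovariance(dd, "A", "c1"), 0)
  expect_gt(arrayCovariance(dd, "C", "c1"), 0)
})

test_that("diallel validity requires selfs and at least three strains", {
  selfs <- c(S1 = 0, S2 = 1, S3 = 2)
  dd <- midparentDiallel(selfs)
  noSelf <- dd@data[!(dd@data$strain_a == dd@data$strain_b &
                        dd@data$strain_a == "S2"), ]
  expect_error(diallelData(noSelf), "self")
  expect_error(midparentDiallel(c(S1 = 0, S2 = 1)), "3 strains")
  expect_error(arrayCovariance(dd, "S9", "c1"), "unknown strain")
  expect_error(arrayCovariance(dd, "S1", "nope"), "context")
})

test_that("dominance ordination recovers exact correlations and degeneracy", {
  set.seed(14)
  base <- simulateDiallel(nStrains = 8, nLoci = 20,
                          mode = "unconditional", noiseSd = 0.3,
                          replicates = 1, seed = 14)$data@data
  # duplicated context: r = 1 exactly
  dup <- base[base$context == "c1", ]
  dup2 <- dup
  dup2$context <- "c2"
  res <- dominanceOrdination(diallelData(rbind(dup, dup2)), nPerm = 200,
                             seed = 1)
  expect_equal(res@r, 1)
  # complete noiseless reversal orders strains exactly oppositely: r = -1;
  # an unconditionally dominant architecture preserves the order: r = +1
  rev <- simulateDiallel(nStrains = 8, nLoci = 20,
                         mode = "dominance_reversed", domDev = 1,
                         noiseSd = 0, replicates = 1, seed = 2)
  res <- dominanceOrdination(rev$data, nPerm = 500, seed = 2)
  expect_equal(res@r, -1)
  expect_lte(res@pValue, 0.05)
  unc <- simulateDiallel(nStrains = 8, nLoci = 20, mode = "unconditional",
                         domDev = 1, noiseSd = 0, replicates = 1, seed = 2)
  expect_equal(dominanceOrdination(unc$data, nPerm = 200, seed = 2)@r, 1)
  # perfectly additive data are degenerate, flagged rather than an error
  res <- dominanceOrdination(presetFixture("diallel3_additive"), nPerm = 100)
  expect_true(res@degenerate)
  expect_true(is.na(res@r))
})

test_that("ordination is invariant to per-context affine rescaling", {
  sim <- simulateDiallel(nStrains = 10, nLoci = 30, seed = 5)
  r0 <- dominanceOrdination(sim$data, nPerm = 500, seed = 9)
  d <- sim$data@data
  d$phenotype[d$context == "c1"] <- 3.7 * d$phenotype[d$context == "c1"] - 12
  d$phenotype[d$context == "c2"] <- 0.4 * d$phenotype[d$context == "c2"] + 5
  r1 <- dominanceOrdination(diallelData(d), nPerm = 500, seed = 9)
  expect_equal(r1@r, r0@r)
  expect_equal(r1@pValue, r0@pValue)
})

test_that("exact binomial imbalance test matches direct tail summation", {
  res <- aseImbalanceTest(50, 50)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$pValue, 1)
  expect_true(is.na(aseImbalanceTest(0, 0)$pValue))
  res <- aseImbalanceTest(90, 10)
  # oracle: sum of binomial point probabilities no larger than the observed
  pObs <- dbinom(90, 100, 0.5)
  pOracle <- sum(dbinom(0:100, 100, 0.5)[dbinom(0:100, 100, 0.5) <=
                                           pObs * (1 + 1e-7)])
  expect_equal(res$pValue, pOracle)
  expect_lt(res$pValue, 1e-10)
  expect_error(aseImbalanceTest(-1, 5), "non-negative")
})

test_that("the reversal decision rule classifies the canonical cases", {
  tab <- data.frame(
    gene = rep(c("rev", "ctx", "cons"), each = 2),
    context = rep(c("c1", "c2"), 3),
    allele1_count = c(90, 10, 90, 55, 90, 90),
    allele2_count = c(10, 90, 10, 45, 10, 10)
  )
  calls <- classifyAseReversal(tab, alpha = 0.05, mtMethod = "none")
  cls <- setNames(calls$classification, calls$gene)
  expect_identical(unname(cls["rev"]), "reversal")
  expect_identical(unname(cls["ctx"]), "context_dependent")
  expect_identical(unname(cls["cons"]), "consistent_imbalance")
  # 55/100 is far from significant at depth 100
  expect_gt(calls$p_2[calls$gene == "ctx"], 0.3)
})

test_that("zero-depth and missing contexts are skipped with reasons", {
  tab <- presetFixture("ase10")
  calls <- classifyAseReversal(tab)
  expect_match(calls$skipReason[calls$gene == "g04"], "zero depth")
  expect_true(is.na(calls$classification[calls$gene == "g04"]))
  oneCtx <- tab[tab$gene != "g01" | tab$context == "c1", ]
  calls2 <- classifyAseReversal(oneCtx)
  expect_match(calls2$skipReason[calls2$gene == "g01"], "missing context")
})

test_that("reversal is never called for same-direction imbalances (exhaustive)", {
  n <- 24L
  grid <- expand.grid(a = 0:n, b = 0:n)
  tab <- data.frame(
    gene = rep(sprintf("g%03d", seq_len(nrow(grid))), each = 2),
    context = rep(c("c1", "c2"), nrow(grid)),
    allele1_count = as.vector(rbind(grid$a, grid$b)),
    allele2_count = as.vector(rbind(n - grid$a, n - grid$b))
  )
  calls <- classifyAseReversal(tab, alpha = 0.05, mtMethod = "none")
  est1 <- calls$estimate_1
  est2 <- calls$estimate_2
  sameSide <- (est1 - 0.5) * (est2 - 0.5) >= 0
  expect_false(any(calls$classification[sameSide] == "reversal"))
  # and every reversal call that is made has opposite directions
  rev <- calls$classification == "reversal"
  expect_true(all((est1[rev] - 0.5) * (est2[rev] - 0.5) < 0))
})

test_that("count tables round-trip through the TSV dialect", {
  tab <- presetFixture("ase10")
  f <- tempfile(fileext = ".tsv")
  writeAseCountsTSV(tab, f)
  expect_equal(readAseCountsTSV(f), tab)
  sim <- simulateDiallel(nStrains = 5, seed = 2)
  f2 <- tempfile(fileext = ".tsv")
  writeDiallelTSV(sim$data, f2)
  back <- readDiallelTSV(f2)
  expect_equal(back@data$phenotype, sim$data@data$phenotype)
})
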