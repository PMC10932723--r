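test_that("mismatch proportion is a normalized symmetric Hamming distance", {
  expect_identical(mismatchProportion("ACGTACGT", "ACGTACGT"), 0)
  expect_identical(mismatchProportion("AAAAAAAA", "CCCCCCCC"), 1)
  expect_identical(mismatchProportion("AAAAAAAA", "CCAAAAAA"), 0.25)
  expect_identical(mismatchProportion("AACCAAAA", "AAAAAAAA"),
                   mismatchProportion("AAAAAAAA", "AACCAAAA"))
  expect_error(mismatchProportion("AAAA", "AAAAAAAA"), "4.*8")
  expect_error(mismatchProportion("AXAA", "AAAA"), "outside")
})

test_that("fractional occupancy follows the two-copy competition form", {
  expect_identical(fractionalOccupancy(0, 2, 0.3), 0)
  expect_equal(fractionalOccupancy(0.5, 2, 0), 0.25)
  # (1/sqrt(2)) / (1 + 2/sqrt(2)), evaluated by hand
  expect_equal(fractionalOccupancy(1, 2, 0.5), 0.2928932, tolerance = 1e-6)
  expect_error(fractionalOccupancy(1, 1, 0.5), "k")
  expect_error(fractionalOccupancy(1, 2, 1.5), "m")
  expect_error(fractionalOccupancy(-1, 2, 0.5), "Dconc")
})

test_that("occupancy is bounded by 0.5 and monotone in D and -m", {
  # supremum 0.5 approached at enormous stimulus concentration
  expect_lt(abs(fractionalOccupancy(1e9, 2, 0) - 0.5), 1e-6)
  D <- 10^seq(-3, 3, length.out = 25)
  for (m in c(0, 0.5, 1)) {
    occ <- fractionalOccupancy(D, 4, m)
    expect_true(all(diff(occ) > 0))
    expect_true(all(occ >= 0 & occ < 0.5))
  }
  mGrid <- seq(0, 1, by = 0.125)
  for (D in c(0.1, 1, 10)) {
    occ <- fractionalOccupancy(D, 2, mGrid)
    expect_true(all(diff(occ) < 0))
  }
})

test_that("allele concentration responds to the sex-matched stimulus", {
  p <- regNetParams(Dconc = 0.5, Amax = 1)
  expect_equal(alleleConcentration(p@stimM, "male", p), 0.25)
  p0 <- regNetParams(Dconc = 0)
  expect_identical(alleleConcentration(p0@alpha0, "female", p0), 0)
  # lower mismatch to the male stimulus means more product in males
  p <- regNetParams()
  closeSite <- p@stimM
  farSite <- p@stimM
  farSite[1:2] <- farSite[1:2] %% 4L + 1L
  expect_gt(alleleConcentration(closeSite, "male", p),
            alleleConcentration(farSite, "male", p))
})

test_that("competitive site occupancy matches the hand formula", {
  expect_identical(competitiveSiteOccupancy("AAAA", c(0, 0),
                                            list("AAAA", "CCCC"), 2),
                   c(0, 0))
  eq <- competitiveSiteOccupancy("AAAA", c(1, 1), list("GGGG", "GGGG"), 2)
  expect_equal(eq[1], eq[2])
  # two factors, c = 1, k = 2, mismatches 0 and 1: w = (1, 0.5), denom 2.5
  occ <- competitiveSiteOccupancy("AAAA", c(1, 1), list("AAAA", "CCCC"), 2)
  expect_equal(occ, c(0.4, 0.2))
  expect_lt(sum(occ), 1)
  expect_error(competitiveSiteOccupancy("AAAA", c(-1, 1),
                                        list("AAAA", "CCCC"), 2), "negative|>= 0")
})

test_that("single-factor occupancy reduces to the Michaelis-like form", {
  set.seed(11)
  for (i in 1:20) {
    k <- runif(1, 1.5, 300)
    conc <- runif(1, 0, 5)
    site <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    probe <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    m <- mismatchProportion(paste(site, collapse = ""),
                            paste(probe, collapse = ""))
    occ <- competitiveSiteOccupancy(paste(site, collapse = ""), conc,
                                    list(paste(probe, collapse = "")), k)
    expect_equal(occ, conc / (k^m + conc))
  }
})

test_that("expression of B is the bound-fraction share of allele effects", {
  p <- regNetParams()
  # silent network
  pSilent <- regNetParams(Dconc = 0)
  g <- regNetGenotype("female", c("A1", "A2"), params = pSilent)
  expect_identical(expressionB(g, pSilent), 0)
  # homozygote ordering and heterozygote intermediacy
  b11 <- expressionB(regNetGenotype("male", c("A1", "A1"), params = p), p)
  b12 <- expressionB(regNetGenotype("male", c("A1", "A2"), params = p), p)
  b22 <- expressionB(regNetGenotype("male", c("A2", "A2"), params = p), p)
  expect_lt(b11, b22)
  expect_gt(b12, b11)
  expect_lt(b12, b22)
  # default network heterozygote: equal concentrations, A1 binding penalty
  # k^(1/8) = 2 at each site, so the A2 share is 1/(1 + 1/2) = 2/3 per site
  expect_equal(b12, 2 * (2 / 3))
})

test_that("phi standardizes B against the analytic network maximum", {
  p <- regNetParams()
  expect_identical(networkBMax(p), 2)
  expect_identical(phiFromB(0, p), 0)
  expect_identical(phiFromB(networkBMax(p), p), 1)
  expect_identical(phiFromB(networkBMax(p) / 2, p), 0.5)
  expect_error(phiFromB(-0.1, p), "B")
  g22 <- regNetGenotype("female", c("A2", "A2"))
  expect_identical(genotypePhi(g22, p), 1)
})

test_that("lowering a male-stimulus mismatch on the A1 haplotype raises the male A1 share", {
  set.seed(42)
  p <- regNetParams()
  for (i in 1:20) {
    a1 <- sample(4L, p@Lsite, replace = TRUE)
    a2 <- sample(4L, p@Lsite, replace = TRUE)
    bad <- which(a1 != p@stimM)
    if (length(bad) == 0L) next
    a1fix <- a1
    pos <- bad[1L]
    a1fix[pos] <- p@stimM[pos]
    cA1 <- alleleConcentration(a1, "male", p)
    cA1fix <- alleleConcentration(a1fix, "male", p)
    cA2 <- alleleConcentration(a2, "male", p)
    expect_gt(cA1fix / (cA1fix + cA2), cA1 / (cA1 + cA2))
  }
})

test_that("network parameter validity is enforced", {
  expect_error(regNetParams(k = 1), "k")
  expect_error(regNetParams(Dconc = -1), "Dconc")
  expect_error(regNetParams(effectA1 = 0.9, effectA2 = 0.5), "effect")
  expect_error(regNetParams(stimF = "AAAA"), "length")
})
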