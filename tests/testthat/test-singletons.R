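test_that("singleton counts, totals and proportions follow the definition", {
  # chrom x locus: chr1 carries derived at loci 1 and 4, chr2 at 2 and 4
  a <- rbind(c(1, 0, 0, 1), c(0, 1, 0, 1), c(0, 0, 0, 0))
  hm <- HaplotypeMatrix(t(a))
  prof <- countSingletons(hm)
  expect_equal(unname(singletonCounts(prof)), c(1, 1, 0))
  expect_equal(singletonTotal(prof), 2)
  expect_equal(unname(singletonProportions(prof)), c(0.5, 0.5, 0))

  # all-ancestral matrix: no singleton, proportions undefined
  hm0 <- HaplotypeMatrix(matrix(0L, 4, 3))
  prof0 <- countSingletons(hm0)
  expect_equal(singletonTotal(prof0), 0)
  expect_true(all(is.na(singletonProportions(prof0))))
})

test_that("folded mode credits the minor-allele carrier", {
  hmF <- HaplotypeMatrix(matrix(c(0, 1, 1), nrow = 1), polarization = "folded")
  expect_equal(unname(singletonCounts(countSingletons(hmF))), c(1, 0, 0))
  # unfolded reading of the same locus: derived seen twice, no singleton
  hmU <- HaplotypeMatrix(matrix(c(0, 1, 1), nrow = 1))
  expect_equal(singletonTotal(countSingletons(hmU)), 0)
})

test_that("missing calls are handled per locus and all-missing loci skipped", {
  a <- rbind(c(1, NA, 0), # derived seen once among 2 non-missing: singleton
             c(NA, NA, NA),   # skipped
             c(1, NA, NA))    # < 2 non-missing: skipped
  expect_message(prof <- countSingletons(HaplotypeMatrix(a)), "skipped 2")
  expect_equal(unname(singletonCounts(prof)), c(1, 0, 0))
  expect_equal(prof@nSkippedLoci, 2L)
})

test_that("countSingletons matches a brute-force tally on random matrices", {
  set.seed(91)
  for (rep in 1:12) {
    folded <- rep %% 2 == 0
    a <- randomHaplotypeMatrix(20, 10)
    got <- suppressMessages(
      countSingletons(HaplotypeMatrix(a), folded = folded))
    expect_equal(unname(singletonCounts(got)), bruteForceSingletons(a, folded))
  }
})

test_that("matrix validity is enforced", {
  expect_error(HaplotypeMatrix(matrix(0L, 3, 1)), "at least 2 chromosomes")
  expect_error(HaplotypeMatrix(matrix(c(0L, 2L, 1L, 0L), 2, 2)),
               "0, 1 or NA")
  expect_error(HaplotypeMatrix(matrix(0L, 2, 2),
                               chromosomeIds = c("a", "a")), "unique")
})

test_that("site frequency spectrum counts loci by derived-copy class", {
  a <- rbind(c(1, 0, 0, 1), c(0, 1, 0, 1), c(0, 0, 0, 0))
  sfs <- siteFrequencySpectrum(HaplotypeMatrix(t(a)))
  expect_equal(unname(sfs), c(2, 1))   # 2 singletons, 1 doubleton; no class 3
  expect_equal(unname(sfs[1]), singletonTotal(countSingletons(HaplotypeMatrix(t(a)))))
  expect_equal(unname(siteFrequencySpectrum(HaplotypeMatrix(matrix(0L, 5, 4)))),
               rep(0L, 3))
})

test_that("expected heterozygosity uses the unbiased k/(k-1) estimator", {
  # one locus, two chromosomes, alleles 0/1: 2 * .5 * .5 * 2/1 = 1
  hm <- HaplotypeMatrix(matrix(c(0L, 1L), nrow = 1))
  expect_equal(unname(expectedHeterozygosity(hm, c("g", "g"))), 1)
  # monomorphic group: 0
  hm2 <- HaplotypeMatrix(matrix(c(1L, 1L, 0L, 0L), nrow = 2, byrow = TRUE))
  expect_equal(unname(expectedHeterozygosity(hm2, c("g", "g"))), 0)
  # frequency 1/2 at many chromosomes approaches 0.5
  n <- 200
  hm3 <- HaplotypeMatrix(matrix(rep(c(0L, 1L), n / 2), nrow = 1))
  expect_equal(unname(expectedHeterozygosity(hm3, rep("g", n))),
               0.5, tolerance = 0.02)
})

test_that("group summaries report means, SDs and the two-group ratio", {
  prof <- new("SingletonProfile",
              counts = setNames(c(3, 3, 2, 2), letters[1:4]),
              total = 10,
              proportions = setNames(c(0.3, 0.3, 0.2, 0.2), letters[1:4]),
              nSkippedLoci = 0L)
  gs <- groupSummaries(prof, setNames(c("1", "1", "2", "2"), letters[1:4]))
  expect_equal(unname(groupMeans(gs)), c(0.3, 0.2))
  expect_equal(groupRatio(gs), 1.5)
  expect_equal(unname(groupSDs(gs)), c(0, 0))
  # group-size weighted means always reconstruct the total mass
  expect_equal(sum(gs@groupSize * groupMeans(gs)), 1)

  # zero singletons: summary flagged undefined
  prof0 <- new("SingletonProfile",
               counts = setNames(rep(0, 4), letters[1:4]), total = 0,
               proportions = setNames(rep(NA_real_, 4), letters[1:4]),
               nSkippedLoci = 0L)
  gs0 <- groupSummaries(prof0, setNames(c("1", "1", "2", "2"), letters[1:4]))
  expect_false(gs0@defined)
  expect_true(is.na(groupRatio(gs0)))
})

test_that("normalization invariants hold on random profiles", {
  set.seed(17)
  for (i in 1:10) {
    a <- randomHaplotypeMatrix(40, 12, pMissing = 0.05)
    prof <- suppressMessages(countSingletons(HaplotypeMatrix(a)))
    if (singletonTotal(prof) > 0) {
      expect_equal(sum(singletonProportions(prof)), 1, tolerance = 1e-12)
      g <- rep(c("x", "y", "z"), each = 4)
      gs <- groupSummaries(prof, g)
      expect_equal(sum(gs@groupSize * groupMeans(gs)), 1, tolerance = 1e-12)
    }
  }
})
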