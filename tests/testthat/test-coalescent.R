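test_that("neutral coalescent matches closed-form expectations", {
  set.seed(101)
  # n = 2: tree height ~ Exp(1), tau1 = 2 * height
  h <- replicate(3000, {
    tr <- simulateNeutralGenealogy(2)
    sum(tr$edge.length) / 2
  })
  expect_lt(abs(mean(h) - 1), 3 * sd(h) / sqrt(length(h)))

  # E[tau1] = 2 and E[tau_i] = 2/n, checked at n = 60
  tau1 <- replicate(1500, sum(externalBranchLengths(simulateNeutralGenealogy(60))))
  expect_lt(abs(mean(tau1) - 2), 3 * sd(tau1) / sqrt(length(tau1)))
  expect_lt(abs(mean(tau1) / 60 - 2 / 60), 3 * sd(tau1 / 60) / sqrt(length(tau1)))
})

test_that("infinite-sites mutation calibrates to E[xi1] = theta", {
  set.seed(102)
  xi <- replicate(2500, {
    m <- dropMutations(simulateNeutralGenealogy(20), 5)
    sum(colSums(m) == 1)
  })
  expect_lt(abs(mean(xi) - 5), 3 * sd(xi) / sqrt(length(xi)))
  # theta = 0 gives no columns
  expect_equal(ncol(dropMutations(simulateNeutralGenealogy(5), 0)), 0)
})

test_that("mutation counts follow Poisson(theta/2 x branch length) on a fixed tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  theta <- 4
  set.seed(103)
  # brute-force oracle: singleton columns are mutations on external
  # branches, so their count is Poisson with mean theta/2 * tau1
  nRep <- 4000
  nSing <- replicate(nRep, {
    m <- dropMutations(tr, theta)
    if (ncol(m) == 0) 0 else sum(colSums(m) == 1)
  })
  # sums of independent Poisson counts are Poisson: test them exactly
  expected <- theta / 2 * sum(externalBranchLengths(tr))   # 10 per draw
  pv <- stats::poisson.test(sum(nSing), r = nRep * expected)$p.value
  expect_gt(pv, 0.001)
  # total columns: mean theta/2 * total tree length (here 6)
  nTot <- replicate(nRep, ncol(dropMutations(tr, theta)))
  pv2 <- stats::poisson.test(sum(nTot), r = nRep * theta / 2 * 6)$p.value
  expect_gt(pv2, 0.001)
})

test_that("derived alleles land on the clade below the mutated branch", {
  tr <- ape::read.tree(text = "((A:0,B:0):10,C:0);")
  set.seed(104)
  m <- dropMutations(tr, 5)   # only the internal branch has length
  expect_gt(ncol(m), 0)
  expect_true(all(m["A", ] == 1 & m["B", ] == 1 & m["C", ] == 0))
})

test_that("panmictic uniformity: each chromosome carries 1/n of singletons", {
  set.seed(105)
  n <- 50
  nBatch <- 20; perBatch <- 30
  batchP <- matrix(0, nBatch, n)
  for (b in seq_len(nBatch)) {
    counts <- numeric(n)
    for (i in seq_len(perBatch)) {
      m <- dropMutations(simulateNeutralGenealogy(n), 6)
      s <- colSums(m) == 1
      if (any(s)) counts <- counts + rowSums(m[, s, drop = FALSE])
    }
    batchP[b, ] <- counts / sum(counts)
  }
  # empirical Monte-Carlo SE (genealogies overdisperse the counts relative
  # to a multinomial, so binomial SEs would be too small); chromosomes are
  # exchangeable, so the batch variances pool into one stable SE
  pbar <- colMeans(batchP)
  sePooled <- sqrt(mean(apply(batchP, 2, var)) / nBatch)
  expect_lte(sum(abs(pbar - 1 / n) > 3 * sePooled), 2)
  expect_equal(mean(pbar), 1 / n, tolerance = 1e-12)
})

test_that("structured simulator reduces to the neutral coalescent in the limit", {
  set.seed(106)
  p <- splitModelParams(shrinkRate = 1, splitTimeGen = 1e-6, theta = 5,
                        growthRateMs = 0, ancestralPhase = "ms-command")
  p$sampleSizes <- c(10L, 10L)
  stat <- replicate(1200, {
    tr <- simulateStructuredGenealogy(p)
    c(sum(externalBranchLengths(tr)), max(ape::node.depth.edgelength(tr)))
  })
  neu <- replicate(1200, {
    tr <- simulateNeutralGenealogy(20)
    c(sum(externalBranchLengths(tr)), max(ape::node.depth.edgelength(tr)))
  })
  for (k in 1:2) {
    se <- sqrt(var(stat[k, ]) / ncol(stat) + var(neu[k, ]) / ncol(neu))
    expect_lt(abs(mean(stat[k, ]) - mean(neu[k, ])), 3 * se)
  }
})

test_that("chromosomes within a population are exchangeable", {
  set.seed(107)
  p <- splitModelParams(shrinkRate = 0.33, splitTimeGen = 5000, theta = 6)
  p$sampleSizes <- c(15L, 15L)
  counts <- numeric(30)
  for (i in 1:300) {
    m <- dropMutations(simulateStructuredGenealogy(p), 12)
    s <- colSums(m) == 1
    if (any(s)) counts <- counts + rowSums(m[, s, drop = FALSE])
  }
  phat <- counts / sum(counts)
  for (pop in list(1:15, 16:30)) {
    se <- sqrt(mean(phat[pop]) / sum(counts))
    expect_lte(sum(abs(phat[pop] - mean(phat[pop])) > 3 * se), 1)
  }
})

test_that("population 2 carries fewer singletons and the ratio grows as s shrinks", {
  set.seed(108)
  ratios <- vapply(c(0.5, 0.1), function(s) {
    p <- splitModelParams(shrinkRate = s, nLoci = 150L)
    res <- replicateSplitStudy(p, 4)
    mean(res$ratio)
  }, numeric(1))
  expect_gt(ratios[1], 1)        # shrunk population is less diverse
  expect_gt(ratios[2], ratios[1])  # and more so for stronger shrinkage
})

test_that("replicate studies are reproducible under a seed", {
  p <- splitModelParams(nLoci = 30L)
  p$sampleSizes <- c(5L, 5L)
  a <- replicateSplitStudy(p, 2, seed = 99)
  b <- replicateSplitStudy(p, 2, seed = 99)
  expect_identical(a, b)
})
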