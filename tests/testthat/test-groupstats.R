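# Cluster-corrected paired sign-flip permutation tests.

test_that("identical real and surrogate data produce no clusters", {
  set.seed(1)
  x <- matrix(rnorm(8 * 20), 8)
  expect_length(clusterPermutationPaired(x, x,
                                         permutationConfig(nPerm = 100)), 0)
})

test_that("a known 1D effect is detected where it was injected", {
  set.seed(2)
  d <- matrix(rnorm(12 * 20), 12)
  d[, 9:15] <- d[, 9:15] + 1       # 1 SD (of the paired difference) effect
  cl <- clusterPermutationPaired(d, matrix(0, 12, 20),
                                 permutationConfig(nPerm = 500))
  expect_gt(length(cl), 0)
  expect_lt(cl[[1]]@pValue, 0.05)
  mask <- significantMask(cl, 0.05, dim = 20)
  expect_gte(sum(mask[9:15]), 5)
  expect_true(all(vapply(cl, function(x) x@polarity, 1)[
    vapply(cl, function(x) x@pValue, 1) < 0.05] == 1))
})

test_that("a known 2D effect is localized with 4-connectivity", {
  set.seed(3)
  arr <- array(rnorm(10 * 8 * 9), c(10, 8, 9))
  arr[, 3:5, 4:6] <- arr[, 3:5, 4:6] + 1.2
  cl <- clusterPermutationPaired(arr, array(0, c(10, 8, 9)),
                                 permutationConfig(nPerm = 300))
  mask <- significantMask(cl, 0.05, dim = c(8, 9))
  expect_true(is.matrix(mask))
  expect_gte(sum(mask[3:5, 4:6]), 6)
  # diagonal-only neighbors are not connected under 4-connectivity
  flag <- matrix(FALSE, 3, 3); flag[1, 1] <- flag[2, 2] <- TRUE
  lab <- speechPAC:::label2D(flag)
  expect_equal(max(lab), 2L)
})

test_that("p-values are deterministic and subject-order invariant", {
  set.seed(4)
  real <- matrix(rnorm(9 * 15), 9); real[, 5:9] <- real[, 5:9] + 1
  surr <- matrix(rnorm(9 * 15), 9)
  cfg <- permutationConfig(nPerm = 300, seed = 7)
  p1 <- vapply(clusterPermutationPaired(real, surr, cfg),
               function(x) x@pValue, 1)
  p2 <- vapply(clusterPermutationPaired(real, surr, cfg),
               function(x) x@pValue, 1)
  expect_identical(p1, p2)
  perm <- sample(9)
  p3 <- vapply(clusterPermutationPaired(real[perm, ], surr[perm, ], cfg),
               function(x) x@pValue, 1)
  expect_identical(p1, p3)
})

test_that("input contracts are enforced", {
  set.seed(5)
  expect_error(clusterPermutationPaired(matrix(rnorm(80), 4),
                                        matrix(rnorm(80), 4),
                                        permutationConfig(nPerm = 100)),
               "at least 5 subjects")
  expect_error(clusterPermutationPaired(matrix(rnorm(100), 5),
                                        matrix(rnorm(120), 5),
                                        permutationConfig(nPerm = 100)),
               "shapes differ")
  expect_error(permutationConfig(nPerm = 50), "nPerm")
})

test_that("significant masks union positive clusters below alpha", {
  mk <- function(p, pol, bins) {
    m <- rep(FALSE, 10); m[bins] <- TRUE
    new("ClusterResult", mask = m, clusterStat = pol * 10, pValue = p,
        polarity = pol)
  }
  cl <- list(mk(0.01, 1, 1:3), mk(0.20, 1, 5:6), mk(0.001, -1, 8:9))
  mask <- significantMask(cl, 0.05)
  expect_equal(which(mask), 1:3)
  expect_equal(sum(significantMask(list(), 0.05, dim = 10)), 0)
  sm <- clusterSummary(cl, freqs = seq(0.5, 5, 0.5))
  expect_equal(nrow(sm), 3)
  expect_equal(sm$freq_lo[1], 0.5)
  expect_equal(sm$freq_hi[1], 1.5)
})
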