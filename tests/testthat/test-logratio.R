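test_that("pairwiseLogratios produces C(D,2) lexicographic columns", {
  X16 <- randomComposition(10, 16, seed = 2)
  expect_equal(ncol(pairwiseLogratios(X16)@values), 120L)

  X <- matrix(rep(c(1/2, 1/4, 1/4), 2), 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  lrs <- pairwiseLogratios(X)
  expect_identical(lrs@labels, c("A/B", "A/C", "B/C"))
  expect_equal(unname(lrs@values[1, ]), c(log(2), log(2), 0))

  Xeq <- matrix(1/4, 2, 4, dimnames = list(NULL, paste0("P", 1:4)))
  expect_true(all(pairwiseLogratios(Xeq)@values == 0))
  Xz <- X; Xz[1, 1] <- 0
  expect_error(pairwiseLogratios(Xz), "replaceZeros")
})

test_that("total logratio variance matches hand computation and identities", {
  # constant composition
  Xc <- matrix(rep(c(0.2, 0.3, 0.5), 4), 4, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(totalLogratioVariance(Xc), 0)

  # D = 2, logratio values {0, 1}: T = (1/4) * Var = 0.125
  x2 <- exp(1) / (1 + exp(1))
  X2 <- rbind(c(0.5, 0.5), c(x2, 1 - x2))
  colnames(X2) <- c("A", "B")
  expect_equal(totalLogratioVariance(X2), 0.125, tolerance = 1e-12)

  # uniform-weight T equals the weighted-CLR trace identity
  X <- randomComposition(50, 7, seed = 3)
  Y <- log(X) - rowMeans(log(X))
  expect_equal(totalLogratioVariance(X), mean(apply(Y, 2, var)),
               tolerance = 1e-12)

  # invariant to per-subject rescaling of the raw input
  X <- randomComposition(40, 5, seed = 4)
  Xs <- X * runif(40, 0.1, 10)
  expect_equal(totalLogratioVariance(Xs), totalLogratioVariance(X),
               tolerance = 1e-12)
  expect_error(totalLogratioVariance(X[1, , drop = FALSE]), "2 subjects")
})

test_that("greedy selection equals the brute-force projection oracle (D=5, n=40)", {
  X <- randomComposition(40, 5, seed = 42)
  orc <- greedyOracle(X)
  trc <- srdaSelect(pairwiseLogratios(X))
  expect_identical(trc@steps$pair, orc$pairs)
  expect_equal(trc@steps$additional, orc$additional, tolerance = 1e-9)
  expect_equal(trc@steps$cumulative, orc$cumulative, tolerance = 1e-9)
  expect_equal(trc@totalVariance, orc$total, tolerance = 1e-12)
})

test_that("selection runs D-1 steps to exactly 100% on generic data", {
  X3 <- randomComposition(30, 3, seed = 5)
  trc3 <- srdaSelect(pairwiseLogratios(X3))
  expect_equal(nrow(trc3@steps), 2L)
  expect_equal(trc3@steps$cumulative[2], 1, tolerance = 1e-8)

  X6 <- randomComposition(80, 6, seed = 6)
  trc6 <- srdaSelect(pairwiseLogratios(X6))
  expect_equal(nrow(trc6@steps), 5L)
  expect_equal(trc6@steps$cumulative[5], 1, tolerance = 1e-8)
  expect_true(all(diff(trc6@steps$cumulative) > 0))
  expect_true(all(trc6@steps$additional >= 0))
})

test_that("stop rules respect target fraction and maximum step count", {
  X <- randomComposition(60, 6, seed = 7)
  lrs <- pairwiseLogratios(X)
  t1 <- srdaSelect(lrs, targetFraction = 0.6)
  expect_gte(t1@steps$cumulative[nrow(t1@steps)], 0.6)
  expect_lt(t1@steps$cumulative[nrow(t1@steps) - 1], 0.6)
  t2 <- srdaSelect(lrs, maxSteps = 2)
  expect_equal(nrow(t2@steps), 2L)
})

test_that("selection trace is equivariant to part permutation", {
  X <- randomComposition(50, 5, seed = 8)
  perm <- c(3, 1, 5, 2, 4)
  Xp <- X[, perm]
  ta <- srdaSelect(pairwiseLogratios(X))
  tb <- srdaSelect(pairwiseLogratios(Xp))
  expect_equal(tb@steps$additional, ta@steps$additional, tolerance = 1e-9)
  expect_equal(tb@steps$cumulative, ta@steps$cumulative, tolerance = 1e-9)
  expect_equal(tb@totalVariance, ta@totalVariance, tolerance = 1e-12)
  # selected columns span the same subspace (tie resolution may differ in
  # label because span-equivalent candidates exist, but not in geometry)
  spanOf <- function(M, lbls) {
    V <- scale(pairwiseLogratios(M)@values[, lbls, drop = FALSE], scale = FALSE)
    qr.Q(qr(V))
  }
  Qa <- spanOf(X, ta@steps$pair)
  Qb <- spanOf(Xp, tb@steps$pair)
  expect_lt(max(abs(Qa %*% crossprod(Qa, Qb) - Qb)), 1e-8)
})

test_that("part-mean weighting changes the variance but both schemes close at 1", {
  X <- randomComposition(60, 5, seed = 9)
  lrs <- pairwiseLogratios(X)
  tu <- totalLogratioVariance(lrs, "uniform")
  tm <- totalLogratioVariance(lrs, "part_means")
  expect_false(isTRUE(all.equal(tu, tm)))
  trm <- srdaSelect(lrs, weights = "part_means")
  expect_equal(trm@steps$cumulative[nrow(trm@steps)], 1, tolerance = 1e-8)
  expect_equal(trm@totalVariance, tm, tolerance = 1e-12)
})

test_that("pairwiseCorrelations matches the direct formula", {
  X <- randomComposition(40, 4, seed = 10)
  C <- pairwiseCorrelations(X)
  expect_equal(diag(C), setNames(rep(1, 4), colnames(X)))
  manual <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  expect_equal(C["P1", "P3"], manual(X[, 1], X[, 3]), tolerance = 1e-12)
  # closure forces the two parts of a 2-part composition to be antipodal
  X2 <- randomComposition(20, 2, seed = 11)
  expect_equal(pairwiseCorrelations(X2)[1, 2], -1, tolerance = 1e-12)
  # zero-variance part flagged
  Xz <- cbind(X, Z = 0.1)
  Xz <- Xz / rowSums(Xz)
  Xz[, "Z"] <- 0.09                      # exactly constant
  expect_warning(Cz <- pairwiseCorrelations(Xz), "zero-variance")
  expect_true(all(is.na(Cz["Z", -5])))
})
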