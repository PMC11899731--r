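test_that("ground truth is valid, sum-zero and plants exactly three strong edges", {
  tru <- groundTruth()
  expect_true(validObject(tru))
  expect_identical(sum(tru@betaStar), 0)
  expect_equal(sum(tru@betaStar != 0), 5L)
  th <- tru@precision
  pc <- -th / sqrt(outer(diag(th), diag(th)))
  diag(pc) <- 0
  strong <- abs(pc[upper.tri(pc)]) > 0.2
  expect_equal(sum(strong), 3L)
  expect_true(all(abs(pc[upper.tri(pc)][strong]) >= 0.25))
  expect_equal(pc["TCD4CM", "TCD4O"], 0.3)
  expect_equal(pc["TCD4CM", "LYMPO"], -0.3)
  expect_equal(pc["TCD8CM", "TCD8O"], 0.3)
  expect_error(groundTruth(edges = data.frame(a = "X1", b = "TCD4N",
                                              partial = 0.3)),
               "unknown part")
})

test_that("composition generation is deterministic and honours the zero rule", {
  tru <- groundTruth()
  a <- compositions(generateCompositions(200, tru, seed = 9))
  b <- compositions(generateCompositions(200, tru, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, compositions(generateCompositions(200, tru, seed = 10))))

  # zeros appear only in the four detection-limited parts
  zc <- colSums(a == 0)
  expect_true(all(zc[setdiff(colnames(a), tru@zeroParts)] == 0))
  expect_true(all(zc[tru@zeroParts] > 0))

  noz <- generateCompositions(200, groundTruth(zeroRate = 0), seed = 9)
  expect_true(all(compositions(noz) > 0))
})

test_that("about half the subjects carry at least one zero at the default rate", {
  X <- compositions(generateCompositions(6250, groundTruth(), seed = 12))
  frac <- mean(rowSums(X == 0) > 0)
  expect_gt(frac, 0.36)
  expect_lt(frac, 0.56)
})

test_that("generated CLR data reproduce the planted covariance and edge signs", {
  # with no zeros, clr(X) = G %*% latent exactly (G the centring projector),
  # so the sample CLR covariance must converge to G Sigma G
  tru <- groundTruth(zeroRate = 0)
  z <- clrTransform(generateCompositions(10000, tru, seed = 13))
  D <- 16
  G <- diag(D) - matrix(1 / D, D, D)
  theo <- G %*% tru@sigma %*% G
  dimnames(theo) <- list(colnames(z), colnames(z))
  expect_lt(max(abs(cov(z) - theo)), 0.05)
  expect_gt(cov(z)["TCD4CM", "TCD4O"], 0)
  expect_lt(cov(z)["TCD4CM", "LYMPO"], 0)
  expect_gt(cov(z)["TCD8CM", "TCD8O"], 0)
  # the sparse estimator applied to these data recovers the planted signs
  net <- fitGlasso(z, 0.06)
  e <- net@edges
  key <- paste(pmin(e$node_i, e$node_j), pmax(e$node_i, e$node_j))
  expect_identical(e$sign[match("TCD4CM TCD4O", key)], "+")
  expect_identical(e$sign[match("LYMPO TCD4CM", key)], "-")
  expect_identical(e$sign[match("TCD8CM TCD8O", key)], "+")
})

test_that("covariate marginals land within 2 points of their targets at n = 6250", {
  cv <- generateCovariates(6250, seed = 14)
  expect_lt(abs(mean(cv$gender == "women") - 0.574), 0.02)
  expect_lt(max(abs(prop.table(table(cv$race)) -
                    c(0.650, 0.172, 0.146, 0.032))), 0.02)
  expect_lt(max(abs(prop.table(table(cv$education)) -
                    c(0.087, 0.107, 0.301, 0.505))), 0.02)
  expect_lt(abs(mean(cv$cmv == "reactive") - 0.714), 0.02)
  expect_lt(abs(median(cv$age) - 68), 3)
})

test_that("panel decomposition round-trips a zero-free cohort to 1e-9", {
  tree <- lymphocyteTree()
  comp0 <- generateCompositions(1000, groundTruth(zeroRate = 0), seed = 15)
  panel <- decomposeToPanel(comp0, tree)
  back <- compositions(toComposition(panel, tree))
  expect_lt(max(abs(back - compositions(comp0))), 1e-9)
  # hand-checked decomposition of one subject
  X1 <- compositions(comp0)[1, , drop = FALSE]
  tShare <- sum(X1[, c("TCD4N", "TCD4CM", "TCD4EM", "TCD4TDEM", "TCD4O",
                       "TCD8N", "TCD8CM", "TCD8EM", "TCD8TDEM", "TCD8O", "TO")])
  expect_equal(panel$T[1], 100 * tShare, tolerance = 1e-9)
  cd4 <- sum(X1[, c("TCD4N", "TCD4CM", "TCD4EM", "TCD4TDEM", "TCD4O")])
  expect_equal(panel$TCD4[1], 100 * cd4 / tShare, tolerance = 1e-9)
  expect_equal(panel$TCD4N[1], 100 * X1[, "TCD4N"] / cd4, tolerance = 1e-9)
})

test_that("outcomes derive from the planted score with calibrated marginals", {
  tru <- groundTruth()
  comp <- replaceZeros(generateCompositions(4000, tru, seed = 16))
  cv <- generateCovariates(4000, seed = 17)
  oc1 <- generateOutcomes(comp, cv, tru, seed = 18)
  oc2 <- generateOutcomes(comp, cv, tru, seed = 18)
  expect_identical(oc1, oc2)
  expect_true(all(oc1$cdi %in% 0:8))
  expect_true(all(oc1$srh %in% 1:5))
  expect_true(all(oc1$frailty_level %in% 1:4))
  expect_true(all(oc1$frailty_index >= 0 & oc1$frailty_index <= 1))
  expect_identical(oc1$frailty_level, categorizeFrailty(oc1$frailty_index))
  # location calibration: typical subject near CDI 2, SRH 3, frailty level 2
  expect_equal(median(oc1$cdi), 2)
  expect_equal(median(oc1$srh), 3)
  expect_lte(abs(median(oc1$frailty_level) - 2), 1)
  # ordinal outcomes increase with the latent score
  expect_gt(cor(oc1$score, oc1$cdi), 0.3)
  expect_gt(cor(oc1$score, oc1$frailty_index), 0.3)
  expect_error(generateOutcomes(generateCompositions(10, tru, seed = 1),
                                cv[1:10, ], tru),
               "zero-replaced")
})

test_that("a null outcome model yields empty BIC-selected supports", {
  tru0 <- groundTruth(betaStar = setNames(numeric(16), groundTruth()@leaves),
                      gammaStar = c("(Intercept)" = 0))
  empty <- 0L
  for (s in 1:10) {
    comp <- replaceZeros(generateCompositions(500, tru0, seed = 500 + s))
    cv <- generateCovariates(500, seed = 600 + s)
    oc <- generateOutcomes(comp, cv, tru0, seed = 700 + s)
    sel <- bicSelect(comp, oc$score, nlambda = 20)
    empty <- empty + (sum(sel$fits[[sel$index]]@beta != 0) == 0)
  }
  expect_gte(empty, 9L)
})

test_that("simulateCohort is reproducible and serialises its truth", {
  ch1 <- simulateCohort(120, seed = 19)
  ch2 <- simulateCohort(120, seed = 19)
  expect_identical(ch1@panel, ch2@panel)
  expect_identical(ch1@outcomes, ch2@outcomes)
  expect_equal(nrow(ch1@panel), 120)
  expect_identical(names(ch1@panel)[1], "subject_id")
  expect_equal(ncol(ch1@panel), 16)               # id + 15 measured columns
  f <- tempfile(fileext = ".json")
  truthToJSON(ch1@truth, f)
  tr <- jsonlite::fromJSON(f)
  expect_equal(sum(unlist(tr$betaStar)), 0)
  expect_identical(tr$zeroParts, c("TCD4EM", "TCD8EM", "BMIgD-", "BO"))
  unlink(f)
})
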