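tree <- lymphocyteTree()

test_that("canonical lymphocyte tree has 21 nodes, 16 ordered leaves, 4 levels", {
  expect_equal(nrow(tree@nodes), 21L)
  expect_identical(
    leafNames(tree),
    c("TCD4N", "TCD4CM", "TCD4EM", "TCD4TDEM", "TCD4O",
      "TCD8N", "TCD8CM", "TCD8EM", "TCD8TDEM", "TCD8O", "TO",
      "BN", "BMIgD-", "BMIgD+", "BO", "LYMPO"))
  expect_equal(max(tree@nodes$depth), 3L)          # root + 3 = four levels
  internal <- unique(tree@nodes$parent[!is.na(tree@nodes$parent)])
  nDerived <- vapply(internal, function(p)
    sum(tree@nodes$derived[tree@nodes$parent %in% p]), 0)
  expect_true(all(nDerived == 1))
  expect_true(validObject(tree))
})

test_that("buildTree inserts derived children and rejects malformed input", {
  tb <- buildTree(data.frame(name = c("T", "B"),
                             parent = c("lymphocytes", "lymphocytes")))
  expect_setequal(leafNames(tb), c("T", "B", "LYMPO"))
  expect_error(
    buildTree(data.frame(name = c("T", "T"), parent = "lymphocytes")),
    "duplicate")
  # subset nodes whose parent is not itself in the panel: no path to root
  expect_error(
    buildTree(data.frame(name = c("T", "TCD8N"), parent = c("lymphocytes", "TCD8"))),
    "unknown parent")
})

test_that("deriveOther computes the complement on each node's own scale", {
  p <- canonicalPanelRow()
  ext <- deriveOther(p, tree)
  expect_equal(ext$LYMPO, 25)                      # 100 - 60 - 15
  expect_equal(ext$TO, 10)                         # 100 - 60 - 30
  expect_equal(ext$TCD4O, 5)
  expect_equal(ext$BO, 10)
  # exact partition gives an exact zero, not float residue
  p2 <- canonicalPanelRow(cd4 = c(50, 30, 10, 10))
  expect_identical(deriveOther(p2, tree)$TCD4O, 0)
  p3 <- canonicalPanelRow(T = 60.7, B = 39.3, TCD4 = 33.3, TCD8 = 66.7,
                          cd4 = c(50, 30.3, 10.4, 9.3),
                          cd8 = c(25, 25.5, 24.5, 25), b = c(30, 30.7, 39.3))
  ext3 <- deriveOther(p3, tree)
  for (cl in c("LYMPO", "TO", "TCD4O", "TCD8O", "BO"))
    expect_identical(ext3[[cl]], 0)
})

test_that("validateSubjects excludes missing and oversum subjects with reasons", {
  ok <- canonicalPanelRow("keep")
  over <- canonicalPanelRow("over", cd4 = c(50, 33, 10, 10))   # CD4 sums to 103
  mis <- canonicalPanelRow("mis"); mis$BN <- NA
  panel <- rbind(ok, over, mis)
  v <- validateSubjects(panel, tree)
  expect_identical(v$panel$subject_id, "keep")
  expect_identical(v$exclusions$reason[v$exclusions$subject_id == "over"], "oversum")
  expect_identical(v$exclusions$reason[v$exclusions$subject_id == "mis"], "missing")
  # sums of exactly 100 are valid
  exact <- canonicalPanelRow("exact", cd4 = c(50, 30, 10, 10))
  expect_equal(nrow(validateSubjects(exact, tree)$exclusions), 0L)
  expect_error(validateSubjects(over, tree), "no subjects left")
})

test_that("relaxing the oversum tolerance never excludes more subjects", {
  eps <- c(0, 1e-12, 1e-8, 1e-4, 0.5, 2, 5)
  panel <- do.call(rbind, lapply(seq_along(eps), function(i)
    canonicalPanelRow(paste0("s", i), cd4 = c(50, 30, 10, 10 + eps[i]))))
  nExcluded <- vapply(c(1e-9, 1e-6, 1e-3, 1, 10), function(tol)
    nrow(validateSubjects(panel, tree, tol = tol)$exclusions), 0)
  expect_true(all(diff(nExcluded) <= 0))
})

test_that("toComposition multiplies percent-of-parent values down the path", {
  p <- canonicalPanelRow(T = 70, TCD4 = 60, cd4 = c(50, 30, 10, 5))
  comp <- toComposition(p, tree)
  X <- compositions(comp)
  expect_equal(unname(X[1, "TCD4N"]), 0.7 * 0.6 * 0.5, tolerance = 1e-12)
  expect_equal(sum(X), 1, tolerance = 1e-9)
})

test_that("closure and partition consistency hold on 1000 random subjects", {
  truth <- groundTruth(zeroRate = 0)
  comp0 <- generateCompositions(1000, truth, seed = 31)
  panel <- decomposeToPanel(comp0, tree)
  comp <- toComposition(panel, tree)
  X <- compositions(comp)
  expect_lt(max(abs(rowSums(X) - 1)), 1e-9)
  # round trip reproduces the source composition
  expect_lt(max(abs(X - compositions(comp0))), 1e-9)
  # summing leaves back up the tree reproduces each internal node's share
  M <- as.matrix(deriveOther(panel, tree)[, -1]) / 100
  tShare <- M[, "T"]
  cd4Share <- M[, "T"] * M[, "TCD4"]
  cd4Leaves <- c("TCD4N", "TCD4CM", "TCD4EM", "TCD4TDEM", "TCD4O")
  expect_lt(max(abs(cd4Share - rowSums(X[, cd4Leaves]))), 1e-9)
  tLeaves <- c(cd4Leaves, "TCD8N", "TCD8CM", "TCD8EM", "TCD8TDEM", "TCD8O", "TO")
  expect_lt(max(abs(tShare - rowSums(X[, tLeaves]))), 1e-9)
})

test_that("replaceZeros imputes the per-part minimum positive value", {
  X <- cbind(A = c(0, 0.07, 0.38), B = c(0.5, 0.43, 0.12),
             C = c(0.5, 0.5, 0.5))
  out <- replaceZeros(X)
  expect_equal(unname(out[1, "A"]), 0.07)
  expect_true(attr(out, "zeroReplaced")[1, 1])
  # two zeros in one column get the same minimum
  X2 <- cbind(A = c(0, 0, 0.38, 0.07), B = rep(0.3, 4), C = rep(0.3, 4))
  out2 <- replaceZeros(X2)
  expect_equal(unname(out2[1:2, "A"]), c(0.07, 0.07))
  # idempotent, and identity on zero-free input
  expect_equal(replaceZeros(out2), out2, ignore_attr = TRUE)
  X3 <- randomComposition(5, 4, seed = 1)
  expect_equal(replaceZeros(X3), X3, ignore_attr = TRUE)
  # a part that is zero everywhere is degenerate
  X4 <- cbind(A = c(0, 0), B = c(1, 1), C = c(0.5, 0.2))
  expect_error(replaceZeros(X4), "degenerate")
})

test_that("replaceZeros on a CompositionSet records flags and provenance", {
  truth <- groundTruth()
  comp <- generateCompositions(300, truth, seed = 5)
  nz <- sum(compositions(comp) == 0)
  expect_gt(nz, 0)
  rz <- replaceZeros(comp)
  expect_true(all(compositions(rz) > 0))
  expect_equal(sum(SummarizedExperiment::assay(rz, "zeroReplaced")), nz)
  expect_equal(S4Vectors::metadata(rz)$zeroReplacement$nCells, nz)
})

test_that("tree JSON serialisation round-trips the node table", {
  f <- tempfile(fileext = ".json")
  treeToJSON(tree, f)
  nd <- jsonlite::fromJSON(f)
  expect_equal(nrow(nd), 21)
  expect_setequal(nd$name[nd$derived], c("LYMPO", "TO", "BO", "TCD4O", "TCD8O"))
  unlink(f)
})
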