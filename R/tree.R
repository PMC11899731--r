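## Gating-hierarchy construction and percentage -> composition conversion.

.defaultOtherNames <- c(lymphocytes = "LYMPO", T = "TO", B = "BO",
                        TCD4 = "TCD4O", TCD8 = "TCD8O")

#' Build a composition tree from a measured-panel description
#'
#' Takes the measured populations of an immunophenotyping panel (each with
#' its parent) and inserts, under every internal node, a derived "other"
#' child that carries the percentage the measured children do not account
#' for. Leaves are ordered depth-first, measured children in input order
#' and the derived child last, which fixes the canonical part order of all
#' downstream output.
#'
#' @param measured data.frame with columns `name` and `parent` listing the
#'   measured populations. Parents must be the root or other measured
#'   nodes.
#' @param root name of the root population (default `"lymphocytes"`).
#' @param otherNames optional named character vector mapping an internal
#'   node to the name of its derived child; unnamed internal nodes get
#'   `<node>O`. The conventional lymphocyte names (LYMPO, TO, BO, TCD4O,
#'   TCD8O) are built in.
#' @return a [CompositionTree-class].
#' @examples
#' buildTree(data.frame(name = c("T", "B"),
#'                      parent = c("lymphocytes", "lymphocytes")))
#' @export
buildTree <- function(measured, root = "lymphocytes", otherNames = NULL) {
  stopifnot(is.data.frame(measured), all(c("name", "parent") %in% names(measured)))
  measured$name <- as.character(measured$name)
  measured$parent <- as.character(measured$parent)
  if (anyDuplicated(c(root, measured$name)))
    stop("duplicate node names in tree description")
  known <- c(root, measured$name)
  bad <- setdiff(measured$parent, known)
  if (length(bad))
    stop("measured node(s) with unknown parent (no path to root): ",
         paste(unique(measured$parent[measured$parent %in% bad]), collapse = ", "))

  oth <- .defaultOtherNames
  if (!is.null(otherNames)) oth[names(otherNames)] <- otherNames

  internal <- unique(measured$parent)           # every parent gets an "other" child
  derivedName <- function(p) if (!is.na(oth[p])) unname(oth[p]) else paste0(p, "O")
  derived <- data.frame(name = vapply(internal, derivedName, ""),
                        parent = internal, stringsAsFactors = FALSE)
  if (any(derived$name %in% known))
    stop("derived 'other' name collides with a measured node: ",
         paste(intersect(derived$name, known), collapse = ", "))

  nodes <- rbind(
    data.frame(name = root, parent = NA_character_, derived = FALSE),
    data.frame(name = measured$name, parent = measured$parent, derived = FALSE),
    data.frame(name = derived$name, parent = derived$parent, derived = TRUE))

  depth <- setNames(integer(nrow(nodes)), nodes$name)
  for (i in seq_len(nrow(nodes))) {
    d <- 0L; p <- nodes$parent[i]
    while (!is.na(p)) {
      d <- d + 1L
      if (d > nrow(nodes)) stop("cycle in tree description")
      p <- nodes$parent[match(p, nodes$name)]
    }
    depth[i] <- d
  }
  nodes$depth <- unname(depth)

  # depth-first leaf order: measured children in input order, derived last
  childrenOf <- function(p) {
    kids <- nodes$name[!is.na(nodes$parent) & nodes$parent == p]
    kids[order(nodes$derived[match(kids, nodes$name)])]
  }
  leaves <- character()
  dfs <- function(nm) {
    kids <- childrenOf(nm)
    if (!length(kids)) leaves <<- c(leaves, nm)
    else for (k in kids) dfs(k)
  }
  dfs(root)

  new("CompositionTree", nodes = nodes, leaves = leaves, root = root)
}

#' The canonical 21-node lymphocyte tree
#'
#' Four levels deep: lymphocytes split into T, B and other lymphocytes;
#' T into CD4, CD8 and other T; CD4 and CD8 each into naive, central
#' memory, effector memory, terminally differentiated effector memory and
#' an "other" remainder; B into naive, IgD- memory, IgD+ memory and other
#' B. The 16 leaves are the parts analysed everywhere else.
#'
#' @return a [CompositionTree-class] with 21 nodes and 16 leaves.
#' @export
lymphocyteTree <- function() {
  m <- data.frame(
    name = c("T", "TCD4", "TCD4N", "TCD4CM", "TCD4EM", "TCD4TDEM",
             "TCD8", "TCD8N", "TCD8CM", "TCD8EM", "TCD8TDEM",
             "B", "BN", "BMIgD-", "BMIgD+"),
    parent = c("lymphocytes", "T", "TCD4", "TCD4", "TCD4", "TCD4",
               "T", "TCD8", "TCD8", "TCD8", "TCD8",
               "lymphocytes", "B", "B", "B"),
    stringsAsFactors = FALSE)
  buildTree(m, root = "lymphocytes")
}

.measuredNodes <- function(tree) {
  nd <- tree@nodes
  nd$name[!nd$derived & !is.na(nd$parent)]
}

.childrenTable <- function(tree) {
  nd <- tree@nodes
  internal <- unique(nd$parent[!is.na(nd$parent)])
  lapply(setNames(internal, internal), function(p) {
    kids <- nd[!is.na(nd$parent) & nd$parent == p, ]
    list(measured = kids$name[!kids$derived], derived = kids$name[kids$derived])
  })
}

#' Fill in the derived "other" columns of a percentage panel
#'
#' For every internal node, `other = 100 - sum(measured children)` on that
#' node's percent-of-parent scale. Remainders within `tol` of zero (the
#' floating-point residue of an exact partition) become exact zeros;
#' genuine over-sums should be removed first with [validateSubjects()].
#'
#' @param panel data.frame of measured percent-of-parent columns.
#' @param tree a [CompositionTree-class].
#' @param tol numerical slack on the 0-100 scale.
#' @return `panel` extended with one column per derived node.
#' @export
deriveOther <- function(panel, tree, tol = 1e-9) {
  miss <- setdiff(.measuredNodes(tree), names(panel))
  if (length(miss))
    stop("panel is missing measured column(s): ", paste(miss, collapse = ", "))
  for (ct in .childrenTable(tree)) {
    s <- rowSums(panel[, ct$measured, drop = FALSE])
    o <- 100 - s
    o[abs(o) <= tol] <- 0      # exact partitions must give an exact zero
    panel[[ct$derived]] <- o
  }
  panel
}

#' Validate subjects of a raw percentage panel
#'
#' Applies the two exclusion rules of the composition pipeline: subjects
#' with any missing measured percentage are dropped (reason `"missing"`),
#' and subjects whose measured children sum to more than 100 at any node
#' beyond `tol` are dropped (reason `"oversum"`). Sums of exactly 100 are
#' valid and simply yield a zero "other" part.
#'
#' @param panel data.frame with a `subject_id` column and the measured
#'   percentage columns of `tree`.
#' @param tree a [CompositionTree-class].
#' @param tol oversum tolerance on the 0-100 scale.
#' @return list with `panel` (kept rows) and `exclusions`
#'   (data.frame of `subject_id`, `reason`).
#' @export
validateSubjects <- function(panel, tree, tol = 1e-9) {
  meas <- .measuredNodes(tree)
  miss <- setdiff(meas, names(panel))
  if (length(miss))
    stop("panel is missing measured column(s): ", paste(miss, collapse = ", "))
  ids <- if ("subject_id" %in% names(panel)) panel$subject_id else seq_len(nrow(panel))

  M <- as.matrix(panel[, meas, drop = FALSE])
  isMissing <- rowSums(is.na(M)) > 0
  rangeBad <- !isMissing & (rowSums(M < 0 | M > 100) > 0)

  over <- rep(FALSE, nrow(panel))
  for (ct in .childrenTable(tree)) {
    s <- rowSums(panel[, ct$measured, drop = FALSE])
    over <- over | (!is.na(s) & s > 100 + tol)
  }
  reason <- rep(NA_character_, nrow(panel))
  reason[over] <- "oversum"
  reason[rangeBad] <- "range"
  reason[isMissing] <- "missing"            # missing takes precedence

  keep <- is.na(reason)
  exclusions <- data.frame(subject_id = ids[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
  if (!any(keep)) stop("no subjects left after exclusions; unusable input")
  list(panel = panel[keep, , drop = FALSE], exclusions = exclusions)
}

#' Convert a percent-of-parent panel into a closed composition
#'
#' Each leaf proportion is the product of the percent-of-parent values
#' (divided by 100) along the root-to-leaf path, i.e. the share of that
#' subset in total lymphocytes. Rows close to 1 by construction; a row-sum
#' deviation beyond `tol` aborts.
#'
#' @param panel validated data.frame; derived "other" columns are computed
#'   with [deriveOther()] if absent.
#' @param tree a [CompositionTree-class].
#' @param colData optional data.frame/DataFrame of per-subject covariates.
#' @param tol closure tolerance on the unit scale.
#' @return a [CompositionSet-class] (leaves x subjects).
#' @export
toComposition <- function(panel, tree, colData = NULL, tol = 1e-9) {
  nd <- tree@nodes
  derivedCols <- nd$name[nd$derived]
  if (!all(derivedCols %in% names(panel))) panel <- deriveOther(panel, tree)

  allCols <- nd$name[!is.na(nd$parent)]
  M <- as.matrix(panel[, allCols, drop = FALSE]) / 100
  if (any(is.na(M))) stop("panel contains missing values; run validateSubjects() first")
  if (any(M < 0)) stop("negative intermediate proportion; input not validated")

  leaves <- tree@leaves
  X <- matrix(1, nrow(M), length(leaves), dimnames = list(NULL, leaves))
  for (k in seq_along(leaves)) {
    nm <- leaves[k]
    while (!is.na(nm) && nm != tree@root) {
      X[, k] <- X[, k] * M[, nm]
      nm <- nd$parent[match(nm, nd$name)]
    }
  }
  rs <- rowSums(X)
  if (any(abs(rs - 1) > tol))
    stop("composition rows do not close to 1 within tolerance (max |dev| = ",
         format(max(abs(rs - 1))), ")")

  ids <- if ("subject_id" %in% names(panel)) as.character(panel$subject_id)
         else as.character(seq_len(nrow(panel)))
  cd <- if (is.null(colData)) S4Vectors::DataFrame(row.names = ids)
        else S4Vectors::DataFrame(colData, row.names = ids)
  se <- SummarizedExperiment(
    assays = list(proportions = t(X)),
    colData = cd,
    metadata = list(tree = tree, zeroReplacement = NULL))
  colnames(se) <- ids
  new("CompositionSet", se)
}

#' Construct a CompositionSet directly from a proportion matrix
#'
#' @param proportions numeric matrix, subjects in rows, parts in columns
#'   (unit scale, rows summing to ~1).
#' @param tree optional [CompositionTree-class] stored in the metadata.
#' @param colData optional covariates.
#' @return a [CompositionSet-class].
#' @export
CompositionSet <- function(proportions, tree = NULL, colData = NULL) {
  proportions <- as.matrix(proportions)
  if (is.null(colnames(proportions)))
    colnames(proportions) <- paste0("P", seq_len(ncol(proportions)))
  ids <- rownames(proportions)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(proportions)))
  cd <- if (is.null(colData)) S4Vectors::DataFrame(row.names = ids)
        else S4Vectors::DataFrame(colData, row.names = ids)
  se <- SummarizedExperiment(assays = list(proportions = t(proportions)),
                             colData = cd,
                             metadata = list(tree = tree, zeroReplacement = NULL))
  colnames(se) <- ids
  new("CompositionSet", se)
}

#' Replace exact zeros by the smallest positive value of their part
#'
#' Each exact-zero cell becomes the minimum positive value observed for
#' that same part across the dataset (a per-part detection-limit
#' imputation). No renormalisation is applied by default: the perturbation
#' is tiny relative to the parts involved, and the subsequent logratio
#' machinery is invariant to closure anyway. Idempotent.
#'
#' @param x a [CompositionSet-class] or subjects-by-parts matrix.
#' @param renormalize re-close rows to sum 1 after replacement.
#' @return object of the same class, with a logical `"zeroReplaced"` assay
#'   (or attribute for matrices) flagging imputed cells.
#' @export
replaceZeros <- function(x, renormalize = FALSE) {
  X <- compositions(x)
  if (nrow(X) < 2) stop("zero replacement needs at least 2 subjects")
  flags <- X == 0
  if (any(flags)) {
    for (k in which(colSums(flags) > 0)) {
      pos <- X[X[, k] > 0, k]
      if (!length(pos))
        stop("part '", colnames(X)[k], "' is zero for every subject; degenerate input")
      X[flags[, k], k] <- min(pos)
    }
    if (renormalize) X <- X / rowSums(X)
  }
  if (is.matrix(x)) {
    attr(X, "zeroReplaced") <- flags
    return(X)
  }
  assay(x, "proportions") <- t(X)
  assays(x)[["zeroReplaced"]] <- t(flags)
  metadata(x)$zeroReplacement <- list(nCells = sum(flags),
                                      nSubjects = sum(rowSums(flags) > 0),
                                      renormalized = renormalize)
  validObject(x)
  x
}

#' Read a raw percentage panel from CSV
#'
#' Column names are taken verbatim (they contain `+`/`-`), empty fields
#' become `NA`.
#'
#' @param file path to a CSV with `subject_id` plus the measured columns.
#' @return data.frame.
#' @export
readPanelCSV <- function(file) {
  read.csv(file, check.names = FALSE, na.strings = c("", "NA"))
}

#' Serialize a tree to JSON
#'
#' @param tree a [CompositionTree-class].
#' @param file optional path; if NULL the JSON string is returned.
#' @export
treeToJSON <- function(tree, file = NULL) {
  js <- jsonlite::toJSON(tree@nodes[, c("name", "parent", "derived")],
                         dataframe = "rows", na = "null", pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
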