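#' Extract the subject-by-part proportion matrix
#'
#' @param x a [CompositionSet-class] (or a plain numeric matrix, returned
#'   as is).
#' @return numeric matrix, subjects in rows, parts in columns.
#' @export
setGeneric("compositions", function(x) standardGeneric("compositions"))

#' Part (leaf) names of an object
#'
#' @param x a tree, composition, logratio set or network object.
#' @return character vector of part names in canonical order.
#' @export
setGeneric("leafNames", function(x) standardGeneric("leafNames"))

#' @describeIn compositions subjects x parts matrix from the
#'   `"proportions"` assay.
#' @export
setMethod("compositions", "CompositionSet", function(x) t(assay(x, "proportions")))

#' @describeIn compositions identity for a plain matrix.
#' @export
setMethod("compositions", "matrix", function(x) x)

#' @describeIn leafNames leaves of a tree.
#' @export
setMethod("leafNames", "CompositionTree", function(x) x@leaves)

#' @describeIn leafNames row (part) names of a composition.
#' @export
setMethod("leafNames", "CompositionSet", function(x) rownames(x))

#' @describeIn leafNames parts of a logratio set.
#' @export
setMethod("leafNames", "LogratioSet", function(x) x@leaves)

#' @describeIn leafNames nodes of a network.
#' @export
setMethod("leafNames", "ConditionalNetwork", function(x) x@nodes)

setMethod("show", "CompositionTree", function(object) {
  nd <- object@nodes
  cat("CompositionTree:", nrow(nd), "nodes,", length(object@leaves),
      "leaves, depth", max(nd$depth), "\n")
  cat("  root:", object@root, "\n")
  cat("  derived:", paste(nd$name[nd$derived], collapse = ", "), "\n")
  cat("  leaves:", paste(object@leaves, collapse = ", "), "\n")
})

setMethod("show", "LogratioSet", function(object) {
  cat("LogratioSet:", nrow(object@values), "subjects,",
      ncol(object@values), "pairwise logratios over",
      length(object@leaves), "parts\n")
})

setMethod("show", "SelectionTrace", function(object) {
  cat("SelectionTrace (", object@weights, " weights): ",
      nrow(object@steps), " steps, cumulative ",
      sprintf("%.2f%%", 100 * max(0, object@steps$cumulative[nrow(object@steps)])),
      " of total variance ", sprintf("%.4f", object@totalVariance), "\n", sep = "")
  print(head(object@steps, 10))
  if (nrow(object@steps) > 10) cat("  ...\n")
})

setMethod("show", "ConditionalNetwork", function(object) {
  cat("ConditionalNetwork [", object@method, "], penalty ",
      signif(object@penalty, 4), ": ", nrow(object@edges), " edges over ",
      length(object@nodes), " nodes\n", sep = "")
  if (nrow(object@edges))
    print(object@edges[, c("node_i", "node_j", "sign", "weight")])
})

setMethod("show", "LogContrastFit", function(object) {
  nz <- sum(abs(object@beta) > 0)
  cat("LogContrastFit (tier ", object@tier, "): lambda ",
      signif(object@lambda, 4), ", ", nz, "/", length(object@beta),
      " non-zero part coefficients (sum ",
      format(sum(object@beta), digits = 3), ")\n", sep = "")
  b <- object@beta[abs(object@beta) > 0]
  if (length(b)) print(round(b, 4))
})

setMethod("show", "GroundTruth", function(object) {
  th <- object@precision
  pc <- -th / sqrt(outer(diag(th), diag(th)))
  diag(pc) <- 0
  ne <- sum(abs(pc[upper.tri(pc)]) > 1e-8)
  cat("GroundTruth:", length(object@leaves), "parts,", ne,
      "planted conditional-dependence edges,",
      sum(abs(object@betaStar) > 0), "active outcome coefficients\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@panel), "subjects,",
      ncol(object@panel) - 1L, "measured panel columns,",
      ncol(object@outcomes), "outcome columns\n")
})

setMethod("show", "LogratioRegressionFit", function(object) {
  cat("LogratioRegressionFit (tier ", object@tier, "): adjusted R2 ",
      sprintf("%.4f", object@adjustedR2), "\n", sep = "")
  print(object@table)
})
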