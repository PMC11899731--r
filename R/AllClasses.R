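#' Gating hierarchy of lymphocyte subsets
#'
#' A rooted tree over named cell populations. Measured nodes come straight
#' from the immunophenotyping panel; every internal node additionally owns
#' exactly one *derived* "other" child that absorbs whatever fraction of the
#' parent the measured children leave unexplained. The leaves, in a fixed
#' canonical order, are the parts of the composition.
#'
#' @slot nodes data.frame with columns `name`, `parent`, `derived`, `depth`
#'   (root has `parent == NA` and depth 0).
#' @slot leaves character, canonical depth-first leaf order.
#' @slot root character scalar, the root node name.
#'
#' @seealso [buildTree()], [lymphocyteTree()]
#' @export
setClass("CompositionTree",
  slots = c(nodes = "data.frame", leaves = "character", root = "character"))

setValidity("CompositionTree", function(object) {
  nd <- object@nodes
  msg <- character()
  if (anyDuplicated(nd$name)) msg <- c(msg, "duplicate node names")
  if (sum(is.na(nd$parent)) != 1L) msg <- c(msg, "tree must have exactly one root")
  known <- c(nd$name, NA)
  if (!all(nd$parent %in% known)) msg <- c(msg, "parent of some node is not in the tree")
  internal <- unique(nd$parent[!is.na(nd$parent)])
  for (p in internal) {
    kids <- nd[!is.na(nd$parent) & nd$parent == p, ]
    if (sum(kids$derived) != 1L)
      msg <- c(msg, sprintf("internal node '%s' must have exactly one derived child", p))
  }
  leaves <- nd$name[!(nd$name %in% internal)]
  if (!setequal(leaves, object@leaves))
    msg <- c(msg, "leaf slot does not match the childless nodes")
  if (length(msg)) msg else TRUE
})

#' Subject-by-part composition container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the leaf parts
#' as rows (assay `"proportions"`, unit scale) and subjects as columns, so
#' covariates and outcomes travel in `colData`. After [replaceZeros()] a
#' logical assay `"zeroReplaced"` marks imputed cells.
#'
#' @export
setClass("CompositionSet", contains = "SummarizedExperiment")

setValidity("CompositionSet", function(object) {
  if (!"proportions" %in% names(assays(object)))
    return("assay 'proportions' is required")
  p <- assay(object, "proportions")
  if (!is.numeric(p)) return("proportions must be numeric")
  if (any(!is.finite(p))) return("proportions must be finite")
  if (any(p < 0)) return("proportions must be non-negative")
  TRUE
})

#' All pairwise logratios of a composition
#'
#' Holds the \eqn{D(D-1)/2} columns \eqn{\ln(x_i/x_j)}, \eqn{i<j} in the
#' canonical leaf order, together with the part means needed for the
#' part-mean weighting variant of the total logratio variance.
#'
#' @slot leaves character, part names.
#' @slot pairs integer matrix (m x 2) of part indices, i < j.
#' @slot labels character, `"A/B"` labels matching `pairs`.
#' @slot values numeric matrix (n x m) of natural-log ratios.
#' @slot partMeans numeric, mean proportion per part.
#' @export
setClass("LogratioSet",
  slots = c(leaves = "character", pairs = "matrix", labels = "character",
            values = "matrix", partMeans = "numeric"))

#' Trace of a stepwise logratio selection
#'
#' @slot steps data.frame with columns `step`, `pair`, `i`, `j`,
#'   `additional`, `cumulative` (variance fractions of the total).
#' @slot totalVariance numeric scalar, the total logratio variance being
#'   explained.
#' @slot weights character, the part-weighting scheme used.
#' @export
setClass("SelectionTrace",
  slots = c(steps = "data.frame", totalVariance = "numeric",
            weights = "character"))

#' Conditional-dependence network over composition parts
#'
#' @slot nodes character, part names.
#' @slot edges data.frame with columns `i`, `j`, `node_i`, `node_j`,
#'   `sign`, `weight`.
#' @slot method `"glasso"` or `"mb"`.
#' @slot penalty numeric, the L1 penalty the edges were estimated at.
#' @slot precision numeric matrix (glasso) or NULL-like empty matrix (mb).
#' @slot stabilityPath data.frame of per-penalty StARS instabilities
#'   (empty if sparsity was not stability-selected).
#' @export
setClass("ConditionalNetwork",
  slots = c(nodes = "character", edges = "data.frame", method = "character",
            penalty = "numeric", precision = "matrix",
            stabilityPath = "data.frame"))

setValidity("ConditionalNetwork", function(object) {
  e <- object@edges
  if (nrow(e) && any(e$i == e$j)) return("self edges are not allowed")
  if (nrow(e) && any(!is.finite(e$weight))) return("edge weights must be finite")
  TRUE
})

#' Penalised log-contrast regression fit
#'
#' @slot beta named numeric, part coefficients on the standardised
#'   log-part scale; sums to zero.
#' @slot gamma named numeric, unpenalised covariate coefficients
#'   (including the intercept).
#' @slot lambda numeric, the L1 penalty of the reported fit.
#' @slot bicPath data.frame with columns `lambda`, `df`, `bic`, `rss`.
#' @slot ci data.frame of bootstrap percentile intervals (may be empty).
#' @slot tier integer, covariate adjustment tier (1, 2 or 3).
#' @slot objective numeric, attained value of the penalised objective.
#' @slot details list of solver diagnostics.
#' @export
setClass("LogContrastFit",
  slots = c(beta = "numeric", gamma = "numeric", lambda = "numeric",
            bicPath = "data.frame", ci = "data.frame", tier = "integer",
            objective = "numeric", details = "list"))

setValidity("LogContrastFit", function(object) {
  if (abs(sum(object@beta)) > 1e-8)
    return("part coefficients must sum to zero (within 1e-8)")
  TRUE
})

#' OLS fit of an outcome on selected logratios
#'
#' @slot table data.frame with columns `term`, `estimate`, `lower`, `upper`.
#' @slot adjustedR2 numeric scalar.
#' @slot tier integer covariate tier.
#' @slot aliased character, names of columns dropped for collinearity.
#' @export
setClass("LogratioRegressionFit",
  slots = c(table = "data.frame", adjustedR2 = "numeric", tier = "integer",
            aliased = "character"))

#' Ground truth of a synthetic cohort
#'
#' Everything needed to regenerate a cohort and to score recovery: the
#' planted latent precision matrix (conditional-dependence edges and their
#' signs), the sparse sum-to-zero outcome coefficients, covariate effects,
#' the noise level and the zero-inflation rule.
#'
#' @export
setClass("GroundTruth",
  slots = c(leaves = "character", precision = "matrix", mu = "numeric",
            sigma = "matrix", betaStar = "numeric", gammaStar = "numeric",
            noiseSd = "numeric", zeroRate = "numeric", zeroParts = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!isSymmetric(unname(object@precision), tol = 1e-10))
    msg <- c(msg, "precision must be symmetric")
  ev <- tryCatch(min(eigen(object@precision, symmetric = TRUE,
                           only.values = TRUE)$values),
                 error = function(e) -Inf)
  if (ev <= 0) msg <- c(msg, "precision must be positive definite")
  if (abs(sum(object@betaStar)) > 1e-12)
    msg <- c(msg, "betaStar must sum to zero exactly")
  if (length(msg)) msg else TRUE
})

#' A generated cohort with its ground truth
#'
#' @slot panel data.frame of percent-of-parent measured columns (the raw
#'   "front door" format), including any exact zeros.
#' @slot covariates data.frame of subject covariates.
#' @slot outcomes data.frame of generated outcomes.
#' @slot truth the [GroundTruth-class] the cohort was drawn from.
#' @export
setClass("SyntheticCohort",
  slots = c(panel = "data.frame", covariates = "data.frame",
            outcomes = "data.frame", truth = "GroundTruth"))
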