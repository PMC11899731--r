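## Conditional-dependence network inference on CLR-transformed
## compositions: graphical lasso or MB neighbourhood selection, with StARS
## stability selection of the penalty.

#' Centred-logratio transform
#'
#' \eqn{z_{ik} = \ln x_{ik} - \frac{1}{D}\sum_k \ln x_{ik}}; every row
#' sums to zero, which makes the transform invariant to per-subject
#' scaling of the raw parts.
#'
#' @param x composition set or subjects-by-parts matrix, strictly
#'   positive.
#' @return numeric matrix, subjects x parts.
#' @export
clrTransform <- function(x) {
  X <- compositions(x)
  if (any(X <= 0))
    stop("composition has non-positive entries; apply replaceZeros() first")
  L <- log(X)
  L - rowMeans(L)
}

.emptyPath <- function() data.frame(penalty = numeric(), instability = numeric(),
                                    monotonized = numeric())

.networkFromPrecision <- function(Theta, nodes, penalty, path = .emptyPath(),
                                  edgeTol = 1e-8) {
  D <- ncol(Theta)
  pc <- -Theta / sqrt(outer(diag(Theta), diag(Theta)))
  idx <- which(upper.tri(Theta) & abs(Theta) > edgeTol, arr.ind = TRUE)
  edges <- data.frame(
    i = idx[, 1], j = idx[, 2],
    node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
    sign = ifelse(pc[idx] > 0, "+", "-"),
    weight = pc[idx], stringsAsFactors = FALSE)
  new("ConditionalNetwork", nodes = nodes, edges = edges, method = "glasso",
      penalty = penalty, precision = Theta, stabilityPath = path)
}

#' Graphical-lasso network on CLR data
#'
#' Estimates an L1-penalised precision matrix of the CLR covariance; an
#' edge is present where the precision entry is non-zero, signed and
#' weighted by the partial correlation
#' \eqn{-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}. Because the CLR
#' covariance is singular (rank at most D-1), a small diagonal ridge
#' (`1e-6` times the mean variance) is added when `penalty = 0`; positive
#' penalties regularise on their own.
#'
#' @param z CLR matrix from [clrTransform()].
#' @param penalty non-negative L1 penalty.
#' @param stabilityPath optional per-penalty instability record to attach.
#' @return a [ConditionalNetwork-class] with method `"glasso"`.
#' @export
fitGlasso <- function(z, penalty, stabilityPath = .emptyPath()) {
  stopifnot(penalty >= 0)
  S <- cov(z)
  if (penalty == 0) S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
  fit <- glasso_cpp(S, penalty)
  Theta <- fit$theta
  ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
  if (!all(is.finite(Theta)) || ev <= 0)
    stop("graphical lasso did not converge to a positive-definite precision",
         " at penalty ", penalty, " (min eigenvalue ", format(ev), ")")
  dimnames(Theta) <- list(colnames(z), colnames(z))
  .networkFromPrecision(Theta, colnames(z), penalty, stabilityPath)
}

# node-wise lasso coefficient array over a (descending) penalty grid;
# returns list over penalties of p x p coefficient matrices B[j, k] =
# coefficient of part k in the regression of part j.
.mbCoefPath <- function(z, grid) {
  p <- ncol(z)
  ord <- order(grid, decreasing = TRUE)
  gridSorted <- grid[ord]
  out <- lapply(seq_along(grid), function(i) matrix(0, p, p))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(z[, -j, drop = FALSE], z[, j], family = "gaussian",
                          lambda = gridSorted, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-10)
    cf <- as.matrix(coef(fit))[-1, , drop = FALSE]   # drop intercept
    for (s in seq_along(gridSorted)) {
      col <- if (s <= ncol(cf)) cf[, s] else cf[, ncol(cf)]
      out[[ord[s]]][j, -j] <- col
    }
  }
  out
}

#' Neighbourhood-selection (MB) network on CLR data
#'
#' Each part is lasso-regressed on all the others; parts i and j are
#' joined if either regression selects the other (OR rule; `rule = "and"`
#' requires both). The edge weight is the mean of the two directed
#' coefficients and carries the sign.
#'
#' @param z CLR matrix.
#' @param penalty non-negative L1 penalty (glmnet scale, objective
#'   `(1/2n)RSS + penalty * ||beta||_1`).
#' @param rule `"or"` (default) or `"and"` symmetrisation.
#' @param stabilityPath optional instability record to attach.
#' @return a [ConditionalNetwork-class] with method `"mb"` (empty
#'   precision slot).
#' @export
fitMB <- function(z, penalty, rule = c("or", "and"),
                  stabilityPath = .emptyPath()) {
  rule <- match.arg(rule)
  stopifnot(penalty >= 0)
  B <- .mbCoefPath(z, penalty)[[1]]
  sel <- B != 0
  adj <- if (rule == "or") sel | t(sel) else sel & t(sel)
  wgt <- (B + t(B)) / 2
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  nodes <- colnames(z)
  edges <- data.frame(
    i = idx[, 1], j = idx[, 2],
    node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
    sign = ifelse(wgt[idx] > 0, "+", "-"),
    weight = wgt[idx], stringsAsFactors = FALSE)
  new("ConditionalNetwork", nodes = nodes, edges = edges, method = "mb",
      penalty = penalty, precision = matrix(numeric(0), 0, 0),
      stabilityPath = stabilityPath)
}

# adjacency matrices over a penalty grid for one data matrix
.adjPath <- function(z, grid, method, rule = "or", edgeTol = 1e-8) {
  if (method == "mb") {
    lapply(.mbCoefPath(z, grid), function(B) {
      sel <- B != 0
      if (rule == "or") sel | t(sel) else sel & t(sel)
    })
  } else {
    S <- cov(z)
    lapply(grid, function(lam) {
      Theta <- glasso_cpp(S, lam)$theta
      A <- abs(Theta) > edgeTol
      diag(A) <- FALSE
      A
    })
  }
}

#' Default penalty grid for network estimation
#'
#' Log-spaced from the smallest penalty that empties the graph
#' (max |off-diagonal covariance|) down to 1% of it.
#'
#' @param z CLR matrix.
#' @param nPenalties grid size.
#' @param ratio smallest/largest penalty ratio.
#' @return decreasing numeric vector.
#' @export
penaltyGrid <- function(z, nPenalties = 30, ratio = 0.01) {
  S <- cov(z)
  lmax <- max(abs(S[upper.tri(S)]))
  exp(seq(log(lmax), log(ratio * lmax), length.out = nPenalties))
}

#' StARS stability selection of the network penalty
#'
#' Refits the network on `B` subsamples (without replacement, size
#' `min(floor(10*sqrt(n)), floor(0.8*n))`) at every penalty of the grid,
#' computes the mean edge instability \eqn{2\xi(1-\xi)} over part pairs,
#' monotonises it from the sparse end down (running maximum as the
#' penalty decreases), and returns the smallest penalty -- the densest
#' stable graph -- whose monotonised instability stays at or below the
#' threshold.
#'
#' @param z CLR matrix (needs at least 50 subjects).
#' @param method `"glasso"` or `"mb"`.
#' @param grid decreasing penalty grid (default [penaltyGrid()], at least
#'   10 values).
#' @param B number of subsamples.
#' @param threshold instability threshold (default 0.05).
#' @param rule MB symmetrisation rule.
#' @param subSize optional subsample size override.
#' @param seed optional RNG seed for the subsampling.
#' @return list with `penalty` (selected value), `path` (data.frame of
#'   penalty, instability, monotonized), `B`, `subSize`. If every penalty
#'   is unstable the largest penalty is returned with a warning.
#' @export
selectSparsityStars <- function(z, method = c("glasso", "mb"), grid = NULL,
                                B = 50, threshold = 0.05, rule = "or",
                                subSize = NULL, seed = NULL) {
  method <- match.arg(method)
  n <- nrow(z)
  if (n < 50) stop("StARS needs at least 50 subjects")
  if (is.null(grid)) grid <- penaltyGrid(z)
  if (length(grid) < 10) stop("penalty grid must have at least 10 values")
  grid <- sort(grid, decreasing = TRUE)
  b <- if (is.null(subSize)) min(floor(10 * sqrt(n)), floor(0.8 * n)) else subSize
  if (!is.null(seed)) set.seed(seed)

  p <- ncol(z)
  freq <- lapply(seq_along(grid), function(i) matrix(0, p, p))
  for (s in seq_len(B)) {
    rows <- sample.int(n, b)
    adj <- .adjPath(z[rows, , drop = FALSE], grid, method, rule)
    for (i in seq_along(grid)) freq[[i]] <- freq[[i]] + adj[[i]]
  }
  ut <- upper.tri(matrix(0, p, p))
  instability <- vapply(freq, function(f) {
    xi <- f[ut] / B
    mean(2 * xi * (1 - xi))
  }, 0)
  monotonized <- cummax(instability)      # nondecreasing as penalty decreases

  ok <- which(monotonized <= threshold)
  if (!length(ok)) {
    warning("no penalty meets the instability threshold; ",
            "falling back to the largest penalty")
    sel <- grid[1]
  } else {
    sel <- grid[max(ok)]                  # smallest stable penalty
  }
  list(penalty = sel,
       path = data.frame(penalty = grid, instability = instability,
                         monotonized = monotonized),
       B = B, subSize = b)
}

#' Infer a conditional-dependence network with stability-selected sparsity
#'
#' Convenience wrapper: [selectSparsityStars()] followed by [fitGlasso()]
#' or [fitMB()] at the selected penalty, with the stability path attached
#' to the returned network.
#'
#' @inheritParams selectSparsityStars
#' @param x composition set/matrix (CLR-transformed internally) or an
#'   already-CLR matrix via `isCLR = TRUE`.
#' @param isCLR set TRUE if `x` is already a CLR matrix.
#' @return a [ConditionalNetwork-class].
#' @export
inferNetwork <- function(x, method = c("glasso", "mb"), grid = NULL, B = 50,
                         threshold = 0.05, rule = "or", subSize = NULL,
                         seed = NULL, isCLR = FALSE) {
  method <- match.arg(method)
  z <- if (isCLR) x else clrTransform(x)
  sel <- selectSparsityStars(z, method, grid = grid, B = B,
                             threshold = threshold, rule = rule,
                             subSize = subSize, seed = seed)
  if (method == "glasso") fitGlasso(z, sel$penalty, stabilityPath = sel$path)
  else fitMB(z, sel$penalty, rule = rule, stabilityPath = sel$path)
}

#' Edge list of a network as a data.frame
#'
#' @param net a [ConditionalNetwork-class].
#' @return data.frame with node pair, sign, weight, method and penalty.
#' @export
edgeTable <- function(net) {
  e <- net@edges
  if (!nrow(e))
    return(data.frame(node_i = character(), node_j = character(),
                      sign = character(), weight = numeric(),
                      method = character(), penalty = numeric()))
  data.frame(e[, c("node_i", "node_j", "sign", "weight")],
             method = net@method, penalty = net@penalty)
}

#' Export a network as GraphML (requires igraph)
#'
#' @param net a [ConditionalNetwork-class].
#' @param file output path.
#' @export
writeGraphML <- function(net, file) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export needs the igraph package")
  g <- igraph::graph_from_data_frame(
    net@edges[, c("node_i", "node_j", "sign", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net@nodes))
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
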