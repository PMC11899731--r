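## Pairwise logratios, total logratio variance and stepwise redundancy
## analysis (greedy forward selection of logratios by explained variance).

.partWeights <- function(weights, partMeans) {
  D <- length(partMeans)
  w <- switch(weights,
    uniform = rep(1 / D, D),
    part_means = partMeans / sum(partMeans),
    stop("unknown weighting scheme: ", weights))
  w
}

#' All pairwise logratios of a composition
#'
#' One column per unordered pair of parts, \eqn{\ln(x_i/x_j)} with
#' \eqn{i<j} in the canonical leaf order (for 16 parts: 120 columns).
#'
#' @param x a [CompositionSet-class] or subjects-by-parts matrix with
#'   strictly positive entries (run [replaceZeros()] first if needed).
#' @return a [LogratioSet-class].
#' @export
pairwiseLogratios <- function(x) {
  X <- compositions(x)
  if (any(X <= 0))
    stop("composition has non-positive entries; apply replaceZeros() first")
  D <- ncol(X)
  leaves <- colnames(X)
  L <- log(X)
  pairs <- t(combn(D, 2L))
  vals <- L[, pairs[, 1], drop = FALSE] - L[, pairs[, 2], drop = FALSE]
  labels <- paste(leaves[pairs[, 1]], leaves[pairs[, 2]], sep = "/")
  colnames(vals) <- labels
  new("LogratioSet", leaves = leaves, pairs = pairs, labels = labels,
      values = vals, partMeans = colMeans(X))
}

#' Total pairwise-logratio variance
#'
#' \deqn{T = \sum_{i<j} w_i w_j \,\mathrm{Var}\,\ln(x_i/x_j)}
#' with sample variances (denominator n-1). With uniform weights
#' \eqn{w_i = 1/D} this is \eqn{(1/D^2)\sum_{i<j}\mathrm{Var}\,L_{ij}},
#' identically equal to the weighted variance of the centred-logratio
#' matrix. The part-mean weighting used by some compositional software is
#' available via `weights = "part_means"`.
#'
#' @param x composition (set or matrix) or a [LogratioSet-class].
#' @param weights `"uniform"` (default) or `"part_means"`.
#' @return numeric scalar (squared nats).
#' @export
totalLogratioVariance <- function(x, weights = c("uniform", "part_means")) {
  weights <- match.arg(weights)
  lrs <- if (is(x, "LogratioSet")) x else pairwiseLogratios(x)
  if (nrow(lrs@values) < 2) stop("variance undefined for fewer than 2 subjects")
  w <- .partWeights(weights, lrs@partMeans)
  v <- apply(lrs@values, 2, var)
  sum(w[lrs@pairs[, 1]] * w[lrs@pairs[, 2]] * v)
}

# weighted clr matrix reconstructed from the logratio columns:
# clr_k = sum_j w_j ln(x_k/x_j)
.clrFromLogratios <- function(lrs, w) {
  n <- nrow(lrs@values); D <- length(lrs@leaves)
  Y <- matrix(0, n, D, dimnames = list(NULL, lrs@leaves))
  for (m in seq_len(nrow(lrs@pairs))) {
    i <- lrs@pairs[m, 1]; j <- lrs@pairs[m, 2]
    Y[, i] <- Y[, i] + w[j] * lrs@values[, m]
    Y[, j] <- Y[, j] - w[i] * lrs@values[, m]
  }
  Y
}

#' Stepwise redundancy analysis over pairwise logratios
#'
#' Greedy forward selection: at every step the candidate logratio that
#' most increases the fraction of the total logratio variance explained is
#' added, where explained variance is the weighted variance of the
#' least-squares projection of the (weighted) centred-logratio matrix onto
#' the span of the selected logratio columns. On generic data the
#' cumulative fraction reaches 1 after D-1 steps, each selected logratio
#' being linearly independent of its predecessors. Ties are broken by
#' lexicographic pair order, so the trace is deterministic.
#'
#' @param lrs a [LogratioSet-class] (or composition coerced via
#'   [pairwiseLogratios()]).
#' @param targetFraction stop once the cumulative explained fraction
#'   reaches this value (e.g. 0.90).
#' @param maxSteps stop after this many steps.
#' @param weights part weighting, as in [totalLogratioVariance()].
#' @param tol a candidate adding less than this fraction is considered to
#'   add nothing; selection stops when no candidate exceeds it.
#' @return a [SelectionTrace-class].
#' @details With neither `targetFraction` nor `maxSteps` the selection
#'   runs to exhaustion (until the span of selected columns covers the
#'   full logratio geometry).
#' @export
srdaSelect <- function(lrs, targetFraction = NULL, maxSteps = NULL,
                       weights = c("uniform", "part_means"), tol = 1e-10) {
  weights <- match.arg(weights)
  if (!is(lrs, "LogratioSet")) lrs <- pairwiseLogratios(lrs)
  n <- nrow(lrs@values)
  w <- .partWeights(weights, lrs@partMeans)

  Y <- .clrFromLogratios(lrs, w)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  totalVar <- sum(w * apply(Y, 2, var))
  if (totalVar <= 0) stop("total logratio variance is zero; constant composition")

  V <- scale(lrs@values, center = TRUE, scale = FALSE)   # candidate columns
  m <- ncol(V)
  Q <- matrix(0, n, 0)                                   # orthonormal basis so far
  remaining <- seq_len(m)
  steps <- list()
  cumulative <- 0

  repeat {
    gains <- rep(NA_real_, length(remaining))
    qs <- vector("list", length(remaining))
    for (ci in seq_along(remaining)) {
      v <- V[, remaining[ci]]
      r <- if (ncol(Q)) v - Q %*% crossprod(Q, v) else v
      nr <- sqrt(sum(r^2))
      if (nr < 1e-9 * max(1, sqrt(sum(v^2)))) next      # in current span
      q <- r / nr
      gains[ci] <- sum(w * as.vector(crossprod(Y, q))^2) / (n - 1) / totalVar
      qs[[ci]] <- q
    }
    if (all(is.na(gains))) break
    best <- max(gains, na.rm = TRUE)
    if (best <= tol) break
    # ties (span-equivalent candidates) go to the lexicographically first pair
    ci <- which(!is.na(gains) & gains >= best * (1 - 1e-9))[1]
    bestIdx <- remaining[ci]; bestQ <- qs[[ci]]; best <- gains[ci]
    Q <- cbind(Q, bestQ)
    cumulative <- cumulative + best
    remaining <- setdiff(remaining, bestIdx)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L,
      pair = lrs@labels[bestIdx],
      i = lrs@pairs[bestIdx, 1], j = lrs@pairs[bestIdx, 2],
      additional = best, cumulative = cumulative,
      stringsAsFactors = FALSE)
    if (!is.null(targetFraction) && cumulative >= targetFraction) break
    if (!is.null(maxSteps) && length(steps) >= maxSteps) break
    if (cumulative >= 1 - 1e-12) break
  }
  if (!length(steps)) stop("no logratio explains any variance")
  new("SelectionTrace", steps = do.call(rbind, steps),
      totalVariance = totalVar, weights = weights)
}

#' Pairwise correlations among composition parts
#'
#' Plain correlation matrix of the part proportions (for descriptive
#' heatmaps; note this ignores the compositional geometry).
#'
#' @param x composition set or matrix.
#' @param method passed to [stats::cor()] (default `"pearson"`).
#' @return symmetric D x D correlation matrix with unit diagonal;
#'   zero-variance parts give `NA` rows/columns with a warning.
#' @export
pairwiseCorrelations <- function(x, method = "pearson") {
  X <- compositions(x)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    warning("zero-variance part(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  suppressWarnings(cor(X, method = method))
}

#' Write a selection trace as CSV
#'
#' @param trace a [SelectionTrace-class].
#' @param file output path.
#' @export
writeTraceCSV <- function(trace, file) {
  df <- trace@steps
  parts <- strsplit(df$pair, "/", fixed = TRUE)
  df$numerator <- vapply(parts, `[`, "", 1)
  df$denominator <- vapply(parts, `[`, "", 2)
  df$additional_pct <- 100 * df$additional
  df$cumulative_pct <- 100 * df$cumulative
  write.csv(df[, c("step", "pair", "numerator", "denominator",
                   "additional_pct", "cumulative_pct")],
            file, row.names = FALSE)
  invisible(file)
}

#' Scree-style plot of a selection trace
#'
#' @param x a [SelectionTrace-class].
#' @param y ignored.
#' @param ... passed to [graphics::barplot()].
#' @export
setMethod("plot", signature(x = "SelectionTrace", y = "missing"),
  function(x, y, ...) {
    st <- x@steps
    bp <- graphics::barplot(100 * st$additional, names.arg = st$pair,
                            las = 2, ylab = "% of total variance",
                            ylim = c(0, 105), ...)
    graphics::lines(bp, 100 * st$cumulative, type = "b", pch = 19)
    invisible(bp)
  })
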