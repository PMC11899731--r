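## Synthetic cohort generator with known ground truth: logistic-normal
## compositions on the lymphocyte tree with planted conditional-dependence
## edges, detection-limit zero inflation, survey-like covariates, and
## outcomes from a sparse sum-to-zero log-contrast model.

# typical median percentages (of total lymphocytes) for an older-adult
# T/B panel; used to centre the latent log-scale means
.defaultMedians <- c(
  TCD4N = 19.8, TCD4CM = 17.3, TCD4EM = 0.07, TCD4TDEM = 0.53, TCD4O = 6.46,
  TCD8N = 2.79, TCD8CM = 1.09, TCD8EM = 0.11, TCD8TDEM = 6.28, TCD8O = 2.69,
  TO = 4.06, BN = 3.8, `BMIgD-` = 0.53, `BMIgD+` = 0.58, BO = 0.52,
  LYMPO = 21.1)

.defaultEdges <- function() data.frame(
  a = c("TCD4CM", "TCD4CM", "TCD8CM"),
  b = c("TCD4O", "LYMPO", "TCD8O"),
  partial = c(0.3, -0.3, 0.3),
  stringsAsFactors = FALSE)

.defaultBetaStar <- function(leaves) {
  b <- setNames(numeric(length(leaves)), leaves)
  b["TCD4N"] <- -0.15
  b["TCD4O"] <- 0.10
  b["TCD8CM"] <- 0.10
  b["TCD8O"] <- -0.14
  b["LYMPO"] <- 0.09     # balances the others exactly to zero
  stopifnot(sum(b) == 0)
  b
}

.defaultGammaStar <- c(
  "(Intercept)" = 0, age = 0.025, genderwomen = 0.15,
  raceblack = 0.20, racehispanic = 0.05, raceother = 0.05,
  educationlower_secondary = -0.05, educationupper_secondary = -0.20,
  educationabove_upper_secondary = -0.40, cmvreactive = 0.10)

#' Ground truth for a synthetic lymphocyte cohort
#'
#' Defaults plant exactly three conditional-dependence edges (partial
#' correlations +/-0.3: TCD4CM--TCD4O positive, TCD4CM--LYMPO negative,
#' TCD8CM--TCD8O positive) in an otherwise diagonal unit precision, centre
#' the latent log-scale means at typical older-adult subset medians, scale
#' the latent covariance to a mean variance of 0.6 (giving a realistic
#' total logratio variance around 0.55), and use a 5-part sum-to-zero
#' outcome coefficient vector (negative on naive CD4 and other CD8,
#' positive on other CD4, central-memory CD8 and other lymphocytes).
#'
#' @param medians named part medians (percent scale) for the latent means.
#' @param edges data.frame with columns `a`, `b`, `partial` planting
#'   conditional-dependence edges.
#' @param latentVarMean target mean latent log-scale variance.
#' @param betaStar named sum-to-zero outcome coefficients per log-part.
#' @param gammaStar named covariate effects (names must match
#'   [covariateDesign()] tier-3 columns).
#' @param noiseSd outcome noise standard deviation.
#' @param zeroRate detection-limit zero-inflation rate per affected part.
#' @param zeroParts parts subject to zero inflation (default: the four
#'   smallest-median parts).
#' @return a [GroundTruth-class].
#' @export
groundTruth <- function(medians = .defaultMedians, edges = .defaultEdges(),
                        latentVarMean = 0.6, betaStar = NULL,
                        gammaStar = .defaultGammaStar, noiseSd = 1,
                        zeroRate = 0.143,
                        zeroParts = c("TCD4EM", "TCD8EM", "BMIgD-", "BO")) {
  leaves <- names(medians)
  D <- length(leaves)
  Theta <- diag(D)
  dimnames(Theta) <- list(leaves, leaves)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- match(edges$a[r], leaves); j <- match(edges$b[r], leaves)
      if (is.na(i) || is.na(j)) stop("edge references unknown part")
      Theta[i, j] <- Theta[j, i] <- -edges$partial[r]
    }
  }
  Sigma <- solve(Theta)
  Sigma <- Sigma * (latentVarMean / mean(diag(Sigma)))
  if (is.null(betaStar)) betaStar <- .defaultBetaStar(leaves)
  stopifnot(setdiff(zeroParts, leaves) == character(0))
  new("GroundTruth", leaves = leaves, precision = Theta,
      mu = log(medians / 100), sigma = Sigma, betaStar = betaStar,
      gammaStar = gammaStar, noiseSd = noiseSd, zeroRate = zeroRate,
      zeroParts = zeroParts)
}

#' Generate logistic-normal compositions with planted dependence
#'
#' Draws latent log-abundances from a multivariate normal with the
#' planted precision structure, maps them onto the simplex by
#' exponentiate-and-close, then applies detection-limit zero inflation:
#' within each affected part, the lowest `zeroRate` fraction of values is
#' set to exact 0 and rows are re-closed.
#'
#' @param n number of subjects.
#' @param truth a [GroundTruth-class].
#' @param seed RNG seed.
#' @return a [CompositionSet-class] (tree metadata attached).
#' @export
generateCompositions <- function(n, truth = groundTruth(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  D <- length(truth@leaves)
  R <- chol(truth@sigma)
  latent <- matrix(rnorm(n * D), n, D) %*% R
  latent <- sweep(latent, 2, truth@mu, "+")
  X <- exp(latent)
  X <- X / rowSums(X)
  colnames(X) <- truth@leaves

  if (truth@zeroRate > 0) {
    for (p in truth@zeroParts) {
      thr <- quantile(X[, p], truth@zeroRate, names = FALSE)
      X[X[, p] < thr, p] <- 0
    }
    X <- X / rowSums(X)
  }
  rownames(X) <- paste0("S", seq_len(n))
  tree <- if (identical(truth@leaves, lymphocyteTree()@leaves)) lymphocyteTree() else NULL
  CompositionSet(X, tree = tree)
}

#' Generate survey-like covariates
#'
#' Age from a shifted gamma (median ~68, IQR ~62-77), and categorical
#' covariates drawn at fixed marginal probabilities typical of an
#' older-adult US cohort: 57.4% women; race 65.0/17.2/14.6/3.2%
#' white/black/hispanic/other; education 8.7/10.7/30.1/50.5% from below
#' secondary to above upper secondary; 71.4% CMV reactive.
#'
#' @param n subjects.
#' @param seed RNG seed.
#' @return data.frame with columns `age`, `gender`, `race`, `education`,
#'   `cmv` (factors with fixed level order).
#' @export
generateCovariates <- function(n, seed = 1L) {
  set.seed(seed)
  age <- pmin(round(50 + rgamma(n, shape = 4, scale = 5)), 100)
  draw <- function(levels, probs)
    factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
  data.frame(
    age = age,
    gender = draw(c("men", "women"), c(0.426, 0.574)),
    race = draw(c("white", "black", "hispanic", "other"),
                c(0.650, 0.172, 0.146, 0.032)),
    education = draw(c("below_secondary", "lower_secondary",
                       "upper_secondary", "above_upper_secondary"),
                     c(0.087, 0.107, 0.301, 0.505)),
    cmv = draw(c("nonreactive", "reactive"), c(0.286, 0.714)))
}

#' Generate outcomes from the planted log-contrast model
#'
#' A latent score \eqn{s = \ln(x)\beta^* + W\gamma^* + \epsilon}
#' (\eqn{\epsilon \sim N(0, \sigma^2)}) drives all outcomes. The noisy
#' score itself is returned as `score`; the chronic disease index is a
#' binomial(8) draw with a logistic link on the standardised score; the
#' self-reported health grade cuts the standardised score into five bins;
#' the frailty index averages 44 Bernoulli deficit items whose
#' probabilities increase with the score, then is categorised with
#' [categorizeFrailty()].
#'
#' @param x zero-replaced composition (strictly positive).
#' @param covariates data.frame from [generateCovariates()].
#' @param truth a [GroundTruth-class].
#' @param seed RNG seed.
#' @return data.frame with `score`, `cdi`, `srh`, `frailty_index`,
#'   `frailty_level`.
#' @export
generateOutcomes <- function(x, covariates, truth = groundTruth(), seed = 1L) {
  X <- compositions(x)
  if (any(X <= 0)) stop("zero-replaced (strictly positive) compositions required")
  if (nrow(X) != nrow(covariates)) stop("composition/covariate row mismatch")
  set.seed(seed)
  W <- covariateDesign(covariates, 3)
  g <- setNames(numeric(ncol(W)), colnames(W))
  common <- intersect(names(truth@gammaStar), names(g))
  g[common] <- truth@gammaStar[common]

  n <- nrow(X)
  sLin <- as.numeric(log(X) %*% truth@betaStar[colnames(X)] + W %*% g)
  score <- sLin + rnorm(n, 0, truth@noiseSd)
  sStd <- as.numeric(scale(score))

  cdi <- rbinom(n, 8, plogis(-1.1 + 0.9 * sStd))
  srh <- findInterval(sStd, qnorm(c(0.10, 0.35, 0.70, 0.92))) + 1L

  a <- qlogis(seq(0.03, 0.35, length.out = 44))
  P <- plogis(outer(0.9 * sStd, a, "+"))
  deficits <- matrix(rbinom(length(P), 1, P), n, 44)
  fi <- rowMeans(deficits)

  data.frame(score = score, cdi = cdi, srh = srh,
             frailty_index = fi, frailty_level = categorizeFrailty(fi))
}

#' Decompose a composition back into a percent-of-parent panel
#'
#' Inverse of [toComposition()]: internal-node totals are leaf sums, and
#' each measured node's panel value is 100 times its total divided by its
#' parent's total. Derived "other" columns are withheld, emulating a raw
#' panel. A zero parent makes the child's relative percentage undefined;
#' it is emitted as 0 and flagged in the `"zeroParent"` attribute.
#'
#' @param x composition set or matrix on the tree's leaves.
#' @param tree a [CompositionTree-class].
#' @return data.frame with `subject_id` and the measured columns.
#' @export
decomposeToPanel <- function(x, tree) {
  X <- compositions(x)
  if (!setequal(colnames(X), tree@leaves))
    stop("composition parts do not match the tree leaves")
  X <- X[, tree@leaves, drop = FALSE]
  nd <- tree@nodes

  descendantsOf <- function(nm) {
    kids <- nd$name[!is.na(nd$parent) & nd$parent == nm]
    if (!length(kids)) return(nm)
    unlist(lapply(kids, descendantsOf))
  }
  totals <- vapply(setNames(nd$name, nd$name), function(nm)
    rowSums(X[, descendantsOf(nm), drop = FALSE]), numeric(nrow(X)))
  if (nrow(X) == 1) totals <- matrix(totals, 1, dimnames = list(NULL, nd$name))

  meas <- .measuredNodes(tree)
  zeroParent <- matrix(FALSE, nrow(X), length(meas),
                       dimnames = list(NULL, meas))
  panel <- matrix(0, nrow(X), length(meas), dimnames = list(NULL, meas))
  for (m in meas) {
    p <- nd$parent[match(m, nd$name)]
    den <- totals[, p]
    bad <- den == 0
    panel[, m] <- ifelse(bad, 0, 100 * totals[, m] / den)
    zeroParent[, m] <- bad
  }
  out <- data.frame(subject_id = rownames(X) %||% seq_len(nrow(X)),
                    panel, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "zeroParent") <- zeroParent
  out
}

#' Simulate a full cohort: panel, covariates and outcomes
#'
#' Generates compositions (with zero inflation), covariates and outcomes,
#' and decomposes the compositions into the raw percent-of-parent panel so
#' the result can enter the analysis pipeline through the same front door
#' as real data. Bit-identical under the same `(truth, seed)`.
#'
#' @param n subjects (default 6250).
#' @param truth a [GroundTruth-class].
#' @param seed master seed; stage seeds are derived from it.
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(n = 6250, truth = groundTruth(), seed = 1L) {
  seed <- as.integer(seed)
  comp0 <- generateCompositions(n, truth, seed = seed)
  covariates <- generateCovariates(n, seed = seed + 1L)
  compPos <- replaceZeros(comp0)
  outcomes <- generateOutcomes(compPos, covariates, truth, seed = seed + 2L)
  tree <- metadata(comp0)$tree
  if (is.null(tree)) stop("cohort simulation needs the canonical tree")
  panel <- decomposeToPanel(comp0, tree)
  new("SyntheticCohort", panel = panel, covariates = covariates,
      outcomes = outcomes, truth = truth)
}

#' Serialize a ground truth to JSON
#'
#' @param truth a [GroundTruth-class].
#' @param file optional output path.
#' @export
truthToJSON <- function(truth, file = NULL) {
  js <- jsonlite::toJSON(list(
    leaves = truth@leaves,
    precision = truth@precision,
    mu = truth@mu,
    betaStar = truth@betaStar,
    gammaStar = truth@gammaStar,
    noiseSd = truth@noiseSd,
    zeroRate = truth@zeroRate,
    zeroParts = truth@zeroParts), digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
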