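## Penalised log-contrast regression of health outcomes on log-parts with
## a sum-to-zero coefficient constraint, BIC penalty tuning and bootstrap
## percentile confidence intervals.

.tierVars <- list(
  `1` = character(),
  `2` = c("age", "gender"),
  `3` = c("age", "gender", "race", "education", "cmv"))

#' Covariate design matrix for an adjustment tier
#'
#' Tier 1 is intercept-only, tier 2 adds age and gender, tier 3 further
#' adds race, educational attainment and CMV serostatus. Factors are
#' dummy-coded against their first level.
#'
#' @param covariates data.frame with (up to) columns `age`, `gender`,
#'   `race`, `education`, `cmv`.
#' @param tier 1, 2 or 3.
#' @return numeric model matrix including the intercept column.
#' @export
covariateDesign <- function(covariates = NULL, tier = 1) {
  tier <- as.integer(tier)
  stopifnot(tier %in% 1:3)
  vars <- .tierVars[[as.character(tier)]]
  if (!length(vars)) {
    n <- if (is.null(covariates)) stop("tier 1 needs the number of subjects; pass covariates or use nInterceptOnly()")
         else nrow(covariates)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  miss <- setdiff(vars, names(covariates))
  if (length(miss))
    stop("covariates missing for tier ", tier, ": ", paste(miss, collapse = ", "))
  f <- as.formula(paste("~", paste(vars, collapse = " + ")))
  W <- model.matrix(f, data = covariates)
  empty <- colSums(W != 0) == 0            # dummy columns of unused levels
  W <- W[, !empty, drop = FALSE]
  if (qr(W)$rank < ncol(W)) stop("rank-deficient covariate design")
  W
}

.interceptOnly <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

# standardized log-part design; keeps scaling so coefficients can be
# reported consistently
.logPartDesign <- function(x, standardize = TRUE) {
  X <- compositions(x)
  if (any(X <= 0))
    stop("composition has non-positive entries; apply replaceZeros() first")
  Z0 <- log(X)
  ctr <- colMeans(Z0)
  scl <- if (standardize) apply(Z0, 2, sd) else rep(1, ncol(Z0))
  if (any(scl == 0)) stop("constant log-part column; cannot standardize")
  Z <- sweep(sweep(Z0, 2, ctr), 2, scl, "/")
  list(Z = Z, center = ctr, scale = scl)
}

.resolveW <- function(covariates, tier, n) {
  if (tier == 1L || is.null(covariates)) .interceptOnly(n)
  else covariateDesign(covariates, tier)
}

#' Fit the sum-to-zero penalised log-contrast model at a fixed penalty
#'
#' Solves
#' \deqn{\min_{\beta,\gamma} \frac{1}{2n}\|y - Z\beta - W\gamma\|^2
#'       + \lambda\|\beta\|_1 \quad \mathrm{s.t.}\ \textstyle\sum_k \beta_k = 0}
#' where Z holds the column-standardised log-parts (penalised) and W the
#' tier covariates plus intercept (unpenalised). Solved by ADMM; the
#' reported coefficients are the sparse iterate re-projected exactly onto
#' the sum-to-zero constraint over its support, and the covariate
#' coefficients are refit by least squares given the parts.
#'
#' @param x composition set or strictly positive subjects-by-parts matrix.
#' @param outcome numeric vector (ordinal outcomes are treated as
#'   numeric).
#' @param covariates data.frame of covariates (may be NULL for tier 1).
#' @param tier adjustment tier 1-3 (see [covariateDesign()]).
#' @param lambda non-negative penalty.
#' @param standardize standardize log-part columns (default TRUE;
#'   coefficients are reported on the standardized scale).
#' @param rho,tol,maxit ADMM controls.
#' @param warm optional warm start (list with `alpha`, `u`).
#' @return a [LogContrastFit-class].
#' @export
fitPenalizedLogContrast <- function(x, outcome, covariates = NULL, tier = 1,
                                    lambda, standardize = TRUE, rho = 1,
                                    tol = 1e-10, maxit = 50000, warm = NULL) {
  if (lambda < 0) stop("negative lambda")
  tier <- as.integer(tier)
  d <- .logPartDesign(x, standardize)
  Z <- d$Z
  n <- nrow(Z); p <- ncol(Z)
  y <- as.numeric(outcome)
  if (length(y) != n) stop("outcome length does not match the composition")
  W <- .resolveW(covariates, tier, n)

  alpha0 <- if (!is.null(warm)) warm$alpha else numeric(p)
  u0 <- if (!is.null(warm)) warm$u else numeric(p)
  fit <- admm_logcontrast(Z, W, y, lambda, rho, tol, maxit, alpha0, u0)

  beta <- as.numeric(fit$alpha)
  beta[abs(beta) < 1e-8] <- 0
  act <- beta != 0
  if (any(act)) beta[act] <- beta[act] - sum(beta) / sum(act)  # exact re-projection
  names(beta) <- colnames(Z)

  # covariate coefficients consistent with the reported (projected) beta
  gamma <- as.numeric(qr.solve(W, y - Z %*% beta))
  names(gamma) <- colnames(W)

  res <- y - Z %*% beta - W %*% gamma
  obj <- sum(res^2) / (2 * n) + lambda * sum(abs(beta))

  new("LogContrastFit", beta = beta, gamma = gamma, lambda = lambda,
      bicPath = data.frame(), ci = data.frame(), tier = tier,
      objective = obj,
      details = list(iterations = fit$iterations, rss = sum(res^2),
                     center = d$center, scale = d$scale,
                     warm = list(alpha = as.numeric(fit$alpha),
                                 u = as.numeric(fit$u))))
}

.lambdaMax <- function(Z, W, y) {
  g0 <- qr.solve(W, y)
  r <- y - W %*% g0
  max(abs(crossprod(Z, r))) / length(y)
}

# RSS of the sum-to-zero-constrained least-squares refit on a support
.refitRSS <- function(Z, W, y, support) {
  if (!any(support)) {
    r <- y - W %*% qr.solve(W, y)
    return(sum(r^2))
  }
  Za <- Z[, support, drop = FALSE]
  p <- ncol(Za); q <- ncol(W)
  K <- rbind(cbind(crossprod(Za), crossprod(Za, W), 1),
             cbind(crossprod(W, Za), crossprod(W), 0),
             c(rep(1, p), rep(0, q), 0))
  sol <- tryCatch(solve(K, c(crossprod(Za, y), crossprod(W, y), 0)),
                  error = function(e) NULL)
  if (is.null(sol)) return(sum((y - W %*% qr.solve(W, y))^2))
  r <- y - Za %*% sol[seq_len(p)] - W %*% sol[p + seq_len(q)]
  sum(r^2)
}

#' BIC selection of the log-contrast penalty
#'
#' Fits the constrained lasso along a descending penalty grid (warm
#' starts) and returns the penalty minimising
#' \deqn{\mathrm{BIC}(\lambda) = n\ln(\mathrm{RSS}_\lambda/n) + \mathrm{df}(\lambda)\ln n,}
#' with df counting the non-zero part coefficients plus the covariate
#' dimension. \eqn{\mathrm{RSS}_\lambda} is taken from the sum-to-zero
#' constrained least-squares refit on the support selected at
#' \eqn{\lambda} (the usual relaxed/debiased convention, so that lasso
#' shrinkage biases the penalty choice, not the model-size comparison).
#' At the null end of the grid this reduces exactly to the
#' covariate-only model's BIC. Ties go to the larger (sparser) penalty.
#'
#' @inheritParams fitPenalizedLogContrast
#' @param grid optional penalty grid (at least 20 values); by default 30
#'   log-spaced values from the null-model penalty down to 0.1% of it.
#' @param nlambda grid size when `grid` is NULL.
#' @return list with `lambda` (selected), `path` (data.frame of lambda,
#'   df, rss, bic) and `fits` (the per-lambda [LogContrastFit-class]s).
#' @export
bicSelect <- function(x, outcome, covariates = NULL, tier = 1, grid = NULL,
                      nlambda = 30, standardize = TRUE) {
  tier <- as.integer(tier)
  d <- .logPartDesign(x, standardize)
  n <- nrow(d$Z)
  y <- as.numeric(outcome)
  W <- .resolveW(covariates, tier, n)
  if (is.null(grid)) {
    lmax <- .lambdaMax(d$Z, W, y)
    grid <- exp(seq(log(lmax), log(1e-3 * lmax), length.out = nlambda))
  }
  if (length(grid) < 1) stop("empty penalty grid")
  grid <- sort(grid, decreasing = TRUE)

  fits <- vector("list", length(grid))
  warm <- NULL
  path <- data.frame(lambda = grid, df = NA_real_, rss = NA_real_,
                     bic = NA_real_)
  for (i in seq_along(grid)) {
    f <- fitPenalizedLogContrast(x, y, covariates, tier, grid[i],
                                 standardize = standardize, warm = warm)
    warm <- f@details$warm
    df <- sum(f@beta != 0) + ncol(W)
    rss <- .refitRSS(d$Z, W, y, f@beta != 0)
    path$df[i] <- df
    path$rss[i] <- rss
    path$bic[i] <- n * log(rss / n) + df * log(n)
    fits[[i]] <- f
  }
  best <- which(path$bic <= min(path$bic) + 1e-12)[1]  # grid descending: first = largest lambda
  list(lambda = grid[best], path = path, fits = fits, index = best)
}

#' Case-resampling bootstrap intervals for a log-contrast fit
#'
#' Resamples subjects with replacement `B` times, refits at the fixed
#' selected penalty (or re-tunes per replicate with `retune = TRUE`), and
#' reports percentile 2.5/97.5% intervals for every part and covariate
#' coefficient. Degenerate resamples (constant outcome) are skipped and
#' counted.
#'
#' @inheritParams fitPenalizedLogContrast
#' @param lambda the penalty of the original fit.
#' @param B bootstrap repetitions (default 200).
#' @param seed RNG seed, required for reproducibility.
#' @param retune re-run [bicSelect()] inside each replicate.
#' @return data.frame `term`, `estimate`, `lower`, `upper` with
#'   attributes `B` (replicates used) and `skipped`.
#' @export
bootstrapCI <- function(x, outcome, covariates = NULL, tier = 1, lambda,
                        B = 200, seed = 1L, retune = FALSE,
                        standardize = TRUE) {
  if (B < 2) stop("B must be at least 2")
  tier <- as.integer(tier)
  X <- compositions(x)
  y <- as.numeric(outcome)
  n <- nrow(X)
  fit0 <- fitPenalizedLogContrast(X, y, covariates, tier, lambda,
                                  standardize = standardize)
  est <- c(fit0@beta, fit0@gamma)

  set.seed(seed)
  draws <- matrix(NA_real_, B, length(est),
                  dimnames = list(NULL, names(est)))
  skipped <- 0L
  for (bId in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (sd(yb) == 0) { skipped <- skipped + 1L; next }
    cvb <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    lamB <- if (retune) bicSelect(X[idx, , drop = FALSE], yb, cvb, tier,
                                  standardize = standardize)$lambda else lambda
    fb <- tryCatch(
      fitPenalizedLogContrast(X[idx, , drop = FALSE], yb, cvb, tier, lamB,
                              standardize = standardize),
      error = function(e) NULL)
    if (is.null(fb)) { skipped <- skipped + 1L; next }
    v <- c(fb@beta, fb@gamma)
    # a resample can lose a rare factor level; align coefficients by name
    common <- intersect(names(v), colnames(draws))
    draws[bId, common] <- v[common]
  }
  qs <- apply(draws, 2, quantile, c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(term = names(est), estimate = unname(est),
                    lower = qs[1, ], upper = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "B") <- B - skipped
  attr(out, "skipped") <- skipped
  out
}

#' Full log-contrast analysis of one outcome
#'
#' BIC-tunes the penalty, fits at the selected value and attaches
#' bootstrap percentile intervals.
#'
#' @inheritParams bootstrapCI
#' @param nlambda,grid passed to [bicSelect()].
#' @return a [LogContrastFit-class] with `bicPath` and `ci` filled in.
#' @export
logContrastRegression <- function(x, outcome, covariates = NULL, tier = 1,
                                  B = 200, seed = 1L, grid = NULL,
                                  nlambda = 30, standardize = TRUE) {
  sel <- bicSelect(x, outcome, covariates, tier, grid = grid,
                   nlambda = nlambda, standardize = standardize)
  fit <- sel$fits[[sel$index]]
  fit@bicPath <- sel$path
  if (B >= 2) {
    fit@ci <- bootstrapCI(x, outcome, covariates, tier, sel$lambda, B = B,
                          seed = seed, standardize = standardize)
  }
  fit
}
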