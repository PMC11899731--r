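## OLS of outcomes on selected logratios, adjusted-R2 comparison against
## the full pairwise-logratio set, and the outcome constructions (chronic
## disease index, deficit-accumulation frailty categories).

.selectedColumns <- function(lrs, selection) {
  labels <- if (is(selection, "SelectionTrace")) selection@steps$pair
            else as.character(selection)
  idx <- match(labels, lrs@labels)
  if (anyNA(idx)) stop("selected pair(s) not present in the logratio set: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  lrs@values[, idx, drop = FALSE]
}

#' OLS of an outcome on selected logratios
#'
#' Classical least squares of the outcome on the selected logratio
#' columns plus tier covariates, with 95% confidence intervals and
#' adjusted R-squared. Columns aliased by collinearity are dropped and
#' recorded.
#'
#' @param lrs a [LogratioSet-class].
#' @param selection a [SelectionTrace-class] or character vector of pair
#'   labels ("A/B").
#' @param outcome numeric vector.
#' @param covariates data.frame (see [covariateDesign()]).
#' @param tier adjustment tier 1-3.
#' @return a [LogratioRegressionFit-class].
#' @export
fitLogratioOLS <- function(lrs, selection, outcome, covariates = NULL,
                           tier = 1) {
  tier <- as.integer(tier)
  V <- .selectedColumns(lrs, selection)
  y <- as.numeric(outcome)
  W <- .resolveW(covariates, tier, nrow(V))
  df <- data.frame(y = y, V, W[, -1, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  ci <- confint(fit)
  keep <- !is.na(cf)
  tab <- data.frame(term = names(cf)[keep], estimate = unname(cf[keep]),
                    lower = ci[keep, 1], upper = ci[keep, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  new("LogratioRegressionFit", table = tab,
      adjustedR2 = summary(fit)$adj.r.squared, tier = tier,
      aliased = aliased)
}

# minimum-norm least squares via SVD; returns fitted values and the
# effective rank used
.minNormFit <- function(X, y, tol = 1e-8) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  r <- sum(sv$d > tol * max(sv$d))
  U <- sv$u[, seq_len(r), drop = FALSE]
  fitted <- mean(y) + U %*% crossprod(U, y - mean(y))
  list(fitted = as.numeric(fitted), rank = r)
}

#' Compare explanatory power of the selected vs the full logratio set
#'
#' The selected-set model is an ordinary OLS fit; the full-set model
#' regresses on all pairwise logratios (plus covariates) by minimum-norm
#' least squares, since the 120-column logratio matrix has rank at most
#' D-1. Adjusted R-squared of the full model uses the effective rank as
#' its degrees of freedom.
#'
#' @param lrs the full [LogratioSet-class].
#' @param selection selected pairs (trace or labels).
#' @param outcome numeric vector.
#' @param covariates,tier as in [fitLogratioOLS()].
#' @return list with `r2_full`, `r2_selected` (both adjusted) and
#'   `delta = r2_full - r2_selected`.
#' @export
compareR2 <- function(lrs, selection, outcome, covariates = NULL, tier = 1) {
  tier <- as.integer(tier)
  y <- as.numeric(outcome)
  n <- length(y)
  W <- .resolveW(covariates, tier, n)

  selFit <- fitLogratioOLS(lrs, selection, y, covariates, tier)

  Xfull <- cbind(lrs@values, W[, -1, drop = FALSE])
  mn <- .minNormFit(Xfull, y)
  rss <- sum((y - mn$fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  dfModel <- mn$rank + 1                     # + intercept
  r2full <- 1 - (1 - r2) * (n - 1) / (n - dfModel)

  list(r2_full = r2full, r2_selected = selFit@adjustedR2,
       delta = r2full - selFit@adjustedR2)
}

#' Categorise a deficit-accumulation frailty index
#'
#' Cut points: robust below 0.15, prefrail `[0.15, 0.25)`, mildly frail
#' `[0.25, 0.35)`, moderate-to-severely frail at or above 0.35 -- coded
#' 1 to 4.
#'
#' @param index numeric in `[0, 1]`.
#' @return integer vector of levels 1-4.
#' @export
categorizeFrailty <- function(index) {
  if (any(is.na(index)) || any(index < 0 | index > 1))
    stop("frailty index must lie in [0, 1]")
  findInterval(index, c(0.15, 0.25, 0.35)) + 1L
}

#' Chronic disease index from eight condition flags
#'
#' Simple sum of affirmative responses over the eight self-reported
#' chronic conditions; ranges 0-8.
#'
#' @param conditions matrix/data.frame with exactly 8 binary (0/1)
#'   columns, no missing values.
#' @return integer vector.
#' @export
chronicDiseaseIndex <- function(conditions) {
  M <- as.matrix(conditions)
  if (ncol(M) != 8) stop("exactly 8 condition flags are required")
  if (any(is.na(M))) stop("missing condition flag")
  if (!all(M %in% c(0, 1))) stop("condition flags must be 0/1")
  as.integer(rowSums(M))
}
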