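# shared fixtures: random compositions, a hand-built canonical panel row,
# and the brute-force greedy SRDA oracle used by unit and acceptance tests

randomComposition <- function(n, D, seed = NULL, sd = 0.8) {
  if (!is.null(seed)) set.seed(seed)
  X <- exp(matrix(rnorm(n * D, sd = sd), n, D))
  X <- X / rowSums(X)
  colnames(X) <- paste0("P", seq_len(D))
  X
}

# one fully valid subject on the canonical 15-column panel (percent of parent)
canonicalPanelRow <- function(subject_id = "s1",
                              T = 60, B = 15,
                              TCD4 = 60, TCD8 = 30,
                              cd4 = c(50, 30, 10, 5),
                              cd8 = c(25, 25, 25, 20),
                              b = c(30, 30, 30)) {
  df <- data.frame(subject_id = subject_id,
                   T = T, TCD4 = TCD4,
                   TCD4N = cd4[1], TCD4CM = cd4[2], TCD4EM = cd4[3],
                   TCD4TDEM = cd4[4],
                   TCD8 = TCD8,
                   TCD8N = cd8[1], TCD8CM = cd8[2], TCD8EM = cd8[3],
                   TCD8TDEM = cd8[4],
                   B = B, BN = b[1], check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[["BMIgD-"]] <- b[2]
  df[["BMIgD+"]] <- b[3]
  df
}

# independent brute-force greedy selection: every remaining pair is scored
# by an explicit lm() projection of the centred CLR matrix at every step
greedyOracle <- function(X, nSteps = ncol(X) - 1) {
  lrs <- pairwiseLogratios(X)
  D <- ncol(X)
  w <- rep(1 / D, D)
  Y <- scale(log(X) - rowMeans(log(X)), scale = FALSE)
  total <- sum(w * apply(Y, 2, var))
  V <- lrs@values
  sel <- integer(0)
  cums <- numeric(0)
  for (s in seq_len(nSteps)) {
    gains <- rep(NA_real_, ncol(V))
    for (c in setdiff(seq_len(ncol(V)), sel)) {
      Xd <- V[, c(sel, c), drop = FALSE]
      if (qr(cbind(1, Xd))$rank < ncol(Xd) + 1) next   # candidate in span
      gains[c] <- sum(w * apply(fitted(lm(Y ~ Xd)), 2, var)) / total
    }
    if (all(is.na(gains))) break
    prev <- if (length(cums)) cums[length(cums)] else 0
    add <- gains - prev
    best <- max(add, na.rm = TRUE)
    if (best <= 1e-10) break
    bi <- which(!is.na(add) & add >= best * (1 - 1e-9))[1]
    sel <- c(sel, bi)
    cums <- c(cums, gains[bi])
  }
  list(pairs = lrs@labels[sel],
       additional = diff(c(0, cums)),
       cumulative = cums,
       total = total)
}

# closed-form equality-constrained least squares (Lagrange system),
# the lambda = 0 oracle for the constrained lasso
constrainedLSOracle <- function(Z, W, y) {
  p <- ncol(Z); q <- ncol(W)
  K <- rbind(cbind(crossprod(Z), crossprod(Z, W), 1),
             cbind(crossprod(W, Z), crossprod(W), 0),
             c(rep(1, p), rep(0, q), 0))
  sol <- solve(K, c(crossprod(Z, y), crossprod(W, y), 0))
  list(beta = sol[seq_len(p)], gamma = sol[p + seq_len(q)])
}
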