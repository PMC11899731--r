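## End-to-end orchestration: simulate (or ingest) -> compose -> network ->
## stepwise logratio selection -> log-contrast regressions -> logratio OLS
## -> markdown report, with config + seed provenance in the run directory.

#' Default pipeline configuration
#'
#' @param ... replacements for any top-level or nested entry; unknown keys
#'   are rejected.
#' @return nested list of settings.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    n = 6250,
    seed = 1L,
    input = NULL,                 # list(panel=, covariates=, outcomes=) CSV paths
    tiers = 1:3,
    outcomes = c("cdi", "srh", "frailty_level"),
    zero = list(renormalize = FALSE),
    srda = list(target_fraction = 0.90, weights = "uniform"),
    network = list(methods = c("glasso", "mb"), B = 50, nPenalties = 30,
                   threshold = 0.05, rule = "or"),
    logcontrast = list(B = 200, nlambda = 30))
  dots <- list(...)
  if (!length(dots)) return(cfg)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      bad2 <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad2))
        stop("unknown config key(s) under '", nm, "': ",
             paste(bad2, collapse = ", "))
      cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

.writeCoefCSV <- function(fits, file) {
  rows <- lapply(fits, function(f) {
    ci <- f$fit@ci
    if (!nrow(ci)) {
      est <- c(f$fit@beta, f$fit@gamma)
      ci <- data.frame(term = names(est), estimate = unname(est),
                       lower = NA_real_, upper = NA_real_)
    }
    data.frame(outcome = f$outcome, tier = f$tier, term = ci$term,
               estimate = ci$estimate, ci_lo = ci$lower, ci_hi = ci$upper)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either a simulated cohort or user-supplied
#' CSVs, writing all stage outputs, a markdown report and full provenance
#' (config as YAML, seed, package version, exclusion log) into `outdir`.
#' Re-running with the same config and seed reproduces every output.
#'
#' @param config list from [pipelineConfig()] (or a path to a YAML file
#'   with the same structure).
#' @param outdir run directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the main stage objects and file paths.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, seed = NULL) {
  if (is.character(config)) config <- do.call(pipelineConfig, yaml::read_yaml(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- as.integer(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) message("[lymphCODA] ", sprintf(...))

  tree <- lymphocyteTree()

  ## stage: simulate or ingest -------------------------------------------
  if (is.null(config$input)) {
    logf("simulate: n = %d, seed = %d", config$n, seed)
    cohort <- simulateCohort(config$n, seed = seed)
    panel <- cohort@panel
    covariates <- cohort@covariates
    outcomes <- cohort@outcomes
    truthToJSON(cohort@truth, file.path(outdir, "truth.json"))
  } else {
    logf("ingest: %s", config$input$panel)
    panel <- readPanelCSV(config$input$panel)
    covariates <- read.csv(config$input$covariates, stringsAsFactors = TRUE)
    outcomes <- read.csv(config$input$outcomes)
  }
  write.csv(panel, file.path(outdir, "panel.csv"), row.names = FALSE)
  write.csv(covariates, file.path(outdir, "covariates.csv"), row.names = FALSE)
  write.csv(outcomes, file.path(outdir, "outcomes.csv"), row.names = FALSE)

  ## stage: compose -------------------------------------------------------
  val <- validateSubjects(panel, tree)
  keptIdx <- match(val$panel$subject_id, panel$subject_id)
  covariates <- covariates[keptIdx, , drop = FALSE]
  outcomes <- outcomes[keptIdx, , drop = FALSE]
  logf("compose: kept %d subjects, excluded %d (%s)",
       nrow(val$panel), nrow(val$exclusions),
       paste(names(table(val$exclusions$reason)), table(val$exclusions$reason),
             sep = "=", collapse = ", "))
  comp <- toComposition(val$panel, tree, colData = covariates)
  comp <- replaceZeros(comp, renormalize = isTRUE(config$zero$renormalize))
  write.csv(data.frame(subject_id = colnames(comp), compositions(comp),
                       check.names = FALSE),
            file.path(outdir, "composition.csv"), row.names = FALSE)
  jsonlite::write_json(val$exclusions, file.path(outdir, "exclusions.json"),
                       dataframe = "rows")
  treeToJSON(tree, file.path(outdir, "tree.json"))

  ## stage: network -------------------------------------------------------
  z <- clrTransform(comp)
  nets <- list()
  for (i in seq_along(config$network$methods)) {
    m <- config$network$methods[i]
    logf("network: %s with StARS (B = %d)", m, config$network$B)
    nets[[m]] <- inferNetwork(
      z, method = m, B = config$network$B,
      grid = penaltyGrid(z, config$network$nPenalties),
      threshold = config$network$threshold, rule = config$network$rule,
      seed = seed + 10L + i, isCLR = TRUE)
    write.csv(edgeTable(nets[[m]]),
              file.path(outdir, paste0("network_", m, ".csv")),
              row.names = FALSE)
  }

  ## stage: stepwise logratio selection -----------------------------------
  lrs <- pairwiseLogratios(comp)
  trace <- srdaSelect(lrs, weights = config$srda$weights)   # to exhaustion
  nSel <- which(trace@steps$cumulative >= config$srda$target_fraction)[1]
  if (is.na(nSel)) nSel <- nrow(trace@steps)
  selPairs <- trace@steps$pair[seq_len(nSel)]
  logf("srda: %d steps total, %d reach the %.0f%% target",
       nrow(trace@steps), nSel, 100 * config$srda$target_fraction)
  writeTraceCSV(trace, file.path(outdir, "srda_trace.csv"))

  ## stage: log-contrast regressions --------------------------------------
  lcFits <- list()
  k <- 0L
  for (oc in config$outcomes) for (tier in config$tiers) {
    k <- k + 1L
    logf("logcontrast: outcome %s, tier %d", oc, tier)
    fit <- logContrastRegression(comp, outcomes[[oc]], covariates, tier,
                                 B = config$logcontrast$B,
                                 seed = seed + 20L + k,
                                 nlambda = config$logcontrast$nlambda)
    lcFits[[k]] <- list(outcome = oc, tier = tier, fit = fit)
  }
  .writeCoefCSV(lcFits, file.path(outdir, "logcontrast_coefficients.csv"))

  ## stage: OLS on selected logratios --------------------------------------
  lrRows <- list(); r2Rows <- list()
  for (oc in config$outcomes) for (tier in config$tiers) {
    f <- fitLogratioOLS(lrs, selPairs, outcomes[[oc]], covariates, tier)
    cmp <- compareR2(lrs, selPairs, outcomes[[oc]], covariates, tier)
    lrRows[[length(lrRows) + 1L]] <- data.frame(
      outcome = oc, tier = tier, f@table, adj_r2 = f@adjustedR2)
    r2Rows[[length(r2Rows) + 1L]] <- data.frame(
      outcome = oc, tier = tier, r2_selected = cmp$r2_selected,
      r2_full = cmp$r2_full, delta = cmp$delta)
  }
  write.csv(do.call(rbind, lrRows),
            file.path(outdir, "logratio_ols.csv"), row.names = FALSE)
  write.csv(do.call(rbind, r2Rows),
            file.path(outdir, "r2_comparison.csv"), row.names = FALSE)

  ## provenance + report ---------------------------------------------------
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  jsonlite::write_json(
    list(seed = seed, package = "lymphCODA",
         version = as.character(packageVersion("lymphCODA")),
         r_version = R.version.string,
         n_input = nrow(panel), n_kept = ncol(comp),
         exclusions = as.list(table(val$exclusions$reason))),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE)
  .writeReport(outdir, config, val, comp, nets, trace, nSel,
               do.call(rbind, r2Rows))

  invisible(list(composition = comp, networks = nets, trace = trace,
                 selected = selPairs, logcontrast = lcFits,
                 outdir = outdir))
}

.writeReport <- function(outdir, config, val, comp, nets, trace, nSel, r2) {
  st <- trace@steps
  lines <- c(
    "# Lymphocyte composition analysis report", "",
    sprintf("- subjects in: %d; kept: %d; excluded: %d",
            nrow(val$panel) + nrow(val$exclusions), ncol(comp),
            nrow(val$exclusions)),
    sprintf("- zero-replaced cells: %s",
            format(metadata(comp)$zeroReplacement$nCells)),
    sprintf("- total logratio variance: %.4f", trace@totalVariance), "",
    "## Stepwise logratio selection", "",
    "| step | logratio | additional % | cumulative % |",
    "|-----:|----------|-------------:|-------------:|",
    sprintf("| %d | %s | %.1f | %.1f |", st$step, st$pair,
            100 * st$additional, 100 * st$cumulative),
    "",
    sprintf("First %d logratios reach the %.0f%% target.", nSel,
            100 * config$srda$target_fraction), "",
    "## Conditional-dependence networks", "")
  for (m in names(nets)) {
    e <- nets[[m]]@edges
    lines <- c(lines, sprintf("### %s (penalty %.4f, %d edges)", m,
                              nets[[m]]@penalty, nrow(e)))
    if (nrow(e))
      lines <- c(lines, "",
                 sprintf("- %s %s %s (weight %.3f)", e$node_i, e$sign,
                         e$node_j, e$weight))
    lines <- c(lines, "")
  }
  lines <- c(lines,
    "## Adjusted R2: selected vs all pairwise logratios", "",
    "| outcome | tier | selected | full | delta |",
    "|---------|-----:|---------:|-----:|------:|",
    sprintf("| %s | %d | %.4f | %.4f | %.4f |", r2$outcome, r2$tier,
            r2$r2_selected, r2$r2_full, r2$delta),
    "",
    "Coefficient tables: `logcontrast_coefficients.csv`, `logratio_ols.csv`.")
  writeLines(lines, file.path(outdir, "report.md"))
}
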