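#' Default end-to-end run configuration
#'
#' A nested list (serializable as YAML) with one block per pipeline stage.
#' Every stage can be disabled; paths under \code{inputs} replace the
#' synthetic generator with user data where given.
#'
#' @param seed master seed governing all synthetic stages.
#' @return a list of class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    timestamps = FALSE,
    stages = list(synth = TRUE, lfq = TRUE, consensus = TRUE,
                  differential = TRUE, ora = TRUE, concordance = TRUE,
                  cytometry = TRUE, dose_response = TRUE,
                  correlation = TRUE),
    inputs = list(matrix = NULL, groups = NULL, catalog = NULL,
                  contaminants = NULL, active = NULL, inactive = NULL,
                  rna = NULL, beads = NULL, flow = NULL, plates = NULL),
    synth = list(n_proteins = 600L, n_samples_per_group = 3L,
                 frac_surface = 0.3, frac_contaminant = 0.05,
                 prc2_frac_up = 0.05, prc2_log2fc_mean = 3,
                 prc2_log2fc_sd = 0.5, replicate_cv = 0.1,
                 rna_coupling_rho = 0.12),
    consensus = list(median_mode = "per-protein"),
    differential = list(lfc_min = 1, fdr_max = 0.05, test = "welch"),
    concordance = list(min_tpm = NULL),
    screen = list(n_lines = 12L, n_doses = 8L, dose_decades = 4,
                  n_reps = 4L, n_media_wells = 8L, n_zero_wells = 8L,
                  noise_sd = 0.05, bead_slope = 0.98,
                  bead_intercept = 0.2, density_noise_cv = 0.1)),
    class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys are kept
#' for \code{\link{validateRunConfig}} to flag.
#'
#' @param path YAML file.
#' @return a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  merge2 <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(over[[k]]) && is.list(base[[k]]))
        merge2(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  out <- merge2(unclass(cfg), user)
  structure(out, class = "RunConfig")
}

#' Validate a run configuration
#'
#' Schema and cross-field checks: thresholds must be positive, the median
#' mode legal, stage flags logical. Unknown keys are reported with the
#' nearest valid key suggested (edit distance). Problems are reported, not
#' raised, so configurations can be linted in batch.
#'
#' @param config a \code{"RunConfig"} list.
#' @return data.frame of issues (\code{field}, \code{severity},
#'   \code{problem}); attribute \code{"valid"} is TRUE when no errors (only
#'   warnings) were found.
#' @export
validateRunConfig <- function(config) {
  issues <- data.frame(field = character(), severity = character(),
                       problem = character(), stringsAsFactors = FALSE)
  note <- function(field, severity, problem)
    issues <<- rbind(issues, data.frame(field = field, severity = severity,
                                        problem = problem))
  known <- names(unclass(defaultRunConfig()))
  for (k in setdiff(names(config), known)) {
    nearest <- known[which.min(adist(k, known))]
    note(k, "warning", sprintf("unknown key; did you mean '%s'?", nearest))
  }
  dd <- config$differential
  if (!is.null(dd$lfc_min) && (!is.numeric(dd$lfc_min) || dd$lfc_min <= 0))
    note("differential.lfc_min", "error", "must be > 0")
  if (!is.null(dd$fdr_max) &&
      (!is.numeric(dd$fdr_max) || dd$fdr_max <= 0 || dd$fdr_max > 1))
    note("differential.fdr_max", "error", "must be in (0, 1]")
  if (!is.null(dd$test) && !dd$test %in% c("welch", "pooled"))
    note("differential.test", "error", "must be 'welch' or 'pooled'")
  cm <- config$consensus$median_mode
  if (!is.null(cm) && !cm %in% c("per-protein", "pooled"))
    note("consensus.median_mode", "error",
         "must be 'per-protein' or 'pooled'")
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    note("seed", "error", "must be an integer")
  for (s in names(config$stages))
    if (!is.logical(config$stages[[s]]))
      note(paste0("stages.", s), "error", "must be TRUE/FALSE")
  sc <- config$screen
  if (!is.null(sc$noise_sd) && sc$noise_sd < 0)
    note("screen.noise_sd", "error", "must be >= 0")
  attr(issues, "valid") <- !any(issues$severity == "error")
  issues
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

#' Run the full surfaceome pipeline
#'
#' Executes the enabled stages in dependency order — synthetic data (or
#' user inputs), contaminant filter + median normalization, consensus
#' surfaceome, differential abundance with over-representation analysis,
#' RNA-protein concordance, bead-calibrated antigen density, dose-response
#' fitting, and the density-potency correlation — writing each stage's
#' outputs under \code{outDir} plus a provenance manifest
#' (\code{manifest.json}) with per-file checksums and row counts.
#' Re-running an identical configuration reproduces identical checksums.
#'
#' @param config a \code{"RunConfig"} (see \code{\link{defaultRunConfig}},
#'   \code{\link{readRunConfig}}).
#' @param outDir output directory, created if needed.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  issues <- validateRunConfig(config)
  if (!attr(issues, "valid"))
    .stopParam("config", paste(issues$field[issues$severity == "error"],
                               collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  seed <- config$seed

  cfgPath <- file.path(outDir, "config.json")
  .writeJSON(unclass(config), cfgPath)
  manifest <- list(tool = "surfkit",
                   version = as.character(utils::packageVersion("surfkit")),
                   config_hash = unname(tools::md5sum(cfgPath)),
                   stages = list())
  if (isTRUE(config$timestamps))
    manifest$started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  addStage <- function(name, files, counts = list()) {
    manifest$stages[[name]] <<- list(
      outputs = lapply(setNames(files, basename(files)), function(f)
        list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))),
      counts = counts)
  }
  fail <- function(stage, e)
    .stopData(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))

  # ---- synthetic / input data -------------------------------------------
  synthCfg <- do.call(syntheticConfig, c(config$synth, list(seed = seed)))
  lfqx <- truth <- NULL
  if (!is.null(config$inputs$matrix)) {
    groups <- read.delim(config$inputs$groups)
    m <- readIntensityMatrix(config$inputs$matrix)
    lfqx <- LFQExperiment(m, group = groups$group[match(colnames(m),
                                                        groups$sample)])
  } else if (isTRUE(st$synth)) {
    sim <- tryCatch(simulateLFQ(synthCfg), error = function(e)
      fail("synth", e))
    lfqx <- sim$experiment; truth <- sim$truth
    f1 <- file.path(outDir, "lfq_matrix.tsv")
    writeIntensityMatrix(lfqx, f1)
    f2 <- .writeJSON(list(surface_set = truth$surface_set,
                          contaminant_set = truth$contaminant_set,
                          true_sample_scales =
                            as.list(truth$true_sample_scales)),
                     file.path(outDir, "ground_truth.json"))
    addStage("synth", c(f1, f2), list(proteins = nrow(lfqx),
                                      samples = ncol(lfqx)))
  }
  contam <- if (!is.null(config$inputs$contaminants))
    readContaminantList(config$inputs$contaminants)
  else truth$contaminant_set
  catalog <- if (!is.null(config$inputs$catalog))
    readSurfaceCatalog(config$inputs$catalog)
  else truth$surface_set

  # ---- lfq core ----------------------------------------------------------
  norm <- NULL
  if (isTRUE(st$lfq) && !is.null(lfqx)) {
    fc <- filterContaminants(lfqx, contam)
    nn <- medianNormalize(fc$experiment)
    norm <- nn$experiment
    f1 <- file.path(outDir, "lfq_normalized.tsv")
    writeIntensityMatrix(norm, f1)
    f2 <- file.path(outDir, "normalization_report.tsv")
    write.table(nn$report, f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addStage("lfq", c(f1, f2),
             list(removed_contaminants = length(fc$removed),
                  proteins = nrow(norm)))
  }

  # ---- consensus ---------------------------------------------------------
  if (isTRUE(st$consensus) && !is.null(lfqx)) {
    cons <- buildConsensus(lfqx, catalog = catalog,
                           contaminants = contam,
                           medianMode = config$consensus$median_mode)
    f1 <- .writeJSON(list(groups = cons@groups,
                          perGroup = cons@perGroup,
                          consensus = consensusSet(cons),
                          provenance = provenance(cons)),
                     file.path(outDir, "consensus.json"))
    f2 <- file.path(outDir, "consensus_proteins.tsv")
    write.table(data.frame(protein = consensusSet(cons)), f2, sep = "\t",
                quote = FALSE, row.names = FALSE)
    addStage("consensus", c(f1, f2),
             list(consensus = length(consensusSet(cons))))
  }

  # ---- differential + ORA ------------------------------------------------
  upset <- NULL; diffTab <- NULL
  if (isTRUE(st$differential)) {
    if (!is.null(config$inputs$active)) {
      act <- readIntensityMatrix(config$inputs$active,
                                 group = "cell_line",
                                 condition = "PRC2_active")
      ina <- readIntensityMatrix(config$inputs$inactive,
                                 group = "cell_line",
                                 condition = "PRC2_inactive")
      pairTruth <- NULL
    } else {
      pair <- simulatePRC2Pair(synthCfg)
      act <- pair$active; ina <- pair$inactive
      pairTruth <- pair$truth
    }
    diffTab <- differentialAbundance(act, ina,
                                     test = config$differential$test)
    upset <- significantUpSet(diffTab,
                              lfcMin = config$differential$lfc_min,
                              fdrMax = config$differential$fdr_max)
    f1 <- file.path(outDir, "differential.tsv")
    write.table(diffTab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(outDir, "up_set.txt")
    writeLines(upset, f2)
    files <- c(f1, f2)
    if (isTRUE(st$ora) && length(upset) > 0) {
      sets <- list()
      if (!is.null(pairTruth) && length(pairTruth$planted_up_set) > 0)
        sets$PLANTED_UP <- names(pairTruth$planted_up_set)
      set.seed(.subSeed(seed, "orasets"))
      for (k in 1:5)
        sets[[sprintf("RANDOM_%02d", k)]] <-
          sample(diffTab$protein, min(50L, nrow(diffTab)))
      ora <- oraEnrichment(upset, diffTab$protein, sets)
      f3 <- file.path(outDir, "ora.tsv")
      write.table(ora, f3, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f3)
    }
    addStage("differential", files,
             list(tested = sum(!is.na(diffTab$p_value)),
                  up = length(upset)))
  }

  # ---- concordance -------------------------------------------------------
  if (isTRUE(st$concordance) && !is.null(lfqx)) {
    rna <- if (!is.null(config$inputs$rna))
      readIntensityMatrix(config$inputs$rna)
    else simulateRNAMatched(lfqx, synthCfg$rna_coupling_rho,
                            seed = .subSeed(seed, "pipe-rna"))
    pairs <- matchGenes(lfqx, rna)
    corAll <- correlateAbundance(pairs,
                                 minTPM = config$concordance$min_tpm)
    dec <- decileBinning(pairs)
    scm <- sampleCorrelationMatrix(lfqx)
    f1 <- .writeJSON(list(n = corAll$n, pearson_r = corAll$r,
                          pearson_p = corAll$p),
                     file.path(outDir, "concordance.json"))
    f2 <- file.path(outDir, "deciles.tsv")
    write.table(dec$summary, f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f3 <- file.path(outDir, "sample_correlation.tsv")
    write.table(round(scm, 6), f3, sep = "\t", quote = FALSE)
    addStage("concordance", c(f1, f2, f3), list(matched = corAll$n))
  }

  # ---- cytometry + dose response + correlation ---------------------------
  dens <- NULL; fits <- list()
  needScreen <- isTRUE(st$cytometry) || isTRUE(st$dose_response) ||
    isTRUE(st$correlation)
  if (needScreen) {
    scr <- config$screen
    panel <- simulateDensityPotencyPanel(
      n_lines = scr$n_lines, noise_cv = scr$density_noise_cv,
      seed = .subSeed(seed, "pipe-screen"))
    if (isTRUE(st$cytometry)) {
      beads <- if (!is.null(config$inputs$beads))
        readBeadLot(config$inputs$beads)
      else simulateBeadPanel(slope = scr$bead_slope,
                             intercept = scr$bead_intercept,
                             seed = .subSeed(seed, "pipe-beads"))
      cal <- fitBeadCurve(beads$mfi, beads$pe_per_bead)
      flow <- if (!is.null(config$inputs$flow))
        read.csv(config$inputs$flow)
      else simulateFlowSummaries(panel, slope = scr$bead_slope,
                                 intercept = scr$bead_intercept,
                                 seed = .subSeed(seed, "pipe-flow"))
      dens <- antigenDensity(cal, flow)
      f1 <- file.path(outDir, "antigen_density.csv")
      write.csv(dens, f1, row.names = FALSE, quote = FALSE)
      addStage("cytometry", f1,
               list(samples = nrow(dens),
                    calibration_r2 = cal@rSquared))
    }
    if (isTRUE(st$dose_response)) {
      doses0 <- 10^seq(0, -scr$dose_decades,
                       length.out = scr$n_doses)
      viabAll <- NULL
      for (i in seq_len(nrow(panel))) {
        trueFit <- doseResponseFit(b = 1.5, c = 0, d = 1,
                                   e = panel$true_ic50[i],
                                   drug = "ADC", sample = panel$sample[i])
        plate <- simulateViabilityPlate(
          trueFit, doses = panel$true_ic50[i] * 10^2 * doses0,
          n_reps = scr$n_reps, n_media_wells = scr$n_media_wells,
          n_zero_wells = scr$n_zero_wells, noise_sd = scr$noise_sd,
          seed = .subSeed(seed, paste0("pipe-plate", i)),
          drug = "ADC", plate = panel$sample[i])
        v <- normalizeViability(plate)
        fit <- fit4PL(v, drug = "ADC")
        fit@sample <- panel$sample[i]
        fits[[panel$sample[i]]] <- fit
        viabAll <- rbind(viabAll, v)
      }
      fitTab <- data.frame(
        sample = vapply(fits, slot, "", "sample"),
        drug = vapply(fits, slot, "", "drug"),
        b = vapply(fits, slot, 0, "b"), c = vapply(fits, slot, 0, "c"),
        d = vapply(fits, slot, 0, "d"),
        ic50 = vapply(fits, ic50, 0),
        converged = vapply(fits, slot, TRUE, "converged"),
        rss = vapply(fits, slot, 0, "rss"))
      f1 <- file.path(outDir, "dose_response_fits.tsv")
      write.table(fitTab, f1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f2 <- file.path(outDir, "viability.tsv")
      write.table(viabAll, f2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      addStage("dose_response", c(f1, f2),
               list(fits = length(fits),
                    converged = sum(fitTab$converged)))
    }
    if (isTRUE(st$correlation) && !is.null(dens) && length(fits) > 0) {
      pc <- densityPotencyCorrelation(dens, fits)
      f1 <- .writeJSON(list(spearman_rho = pc$rho, p = pc$p, n = pc$n),
                       file.path(outDir, "density_potency.json"))
      addStage("correlation", f1, list(pairs = pc$n))
    }
  }

  if (isTRUE(config$timestamps))
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  .writeJSON(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}

#' @importFrom utils adist
NULL
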