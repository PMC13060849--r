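#' Configuration for the synthetic surfaceome data generator
#'
#' Bundles every knob of the synthetic LFQ / RNA / PRC2-pair generators with
#' validation. Intensities are generated on the linear scale; all log-scale
#' parameters below are base-2 (LFQ intensities are conventionally examined
#' as log2). Missing values are explicit \code{NA}, never 0.
#'
#' @param n_proteins number of proteins in the simulated universe.
#' @param n_samples_per_group samples per group (and replicates per condition
#'   for the PRC2 pair generator).
#' @param groups character vector of group labels.
#' @param frac_surface fraction of proteins annotated as true surface
#'   proteins.
#' @param frac_contaminant fraction of extra rows spiked in as mass-spec
#'   contaminants (drawn high-abundance, from the upper quartile of the
#'   intensity distribution, so they would pass abundance filters if not
#'   removed).
#' @param log_intensity_mean,log_intensity_sd mean and sd of true protein
#'   log2 intensities.
#' @param sample_scale_sd sd (log2 scale) of per-sample multiplicative
#'   distortions; 0 means all sample scale factors are exactly 1.
#' @param dropout_midpoint,dropout_steepness logistic intensity-dependent
#'   missingness: a cell with true log2 intensity \eqn{z} is dropped with
#'   probability \eqn{1 / (1 + \exp(s (z - m)))}, which decreases in
#'   \eqn{z}. \code{dropout_steepness = Inf} with a midpoint below the
#'   intensity range disables dropout.
#' @param prc2_frac_up fraction of proteins planted as PRC2-derepressed
#'   (more abundant when PRC2 is inactive).
#' @param prc2_log2fc_mean,prc2_log2fc_sd distribution of planted log2 fold
#'   changes.
#' @param rna_coupling_rho target population correlation between log RNA and
#'   log protein abundance, in [-1, 1].
#' @param replicate_cv multiplicative coefficient of variation for technical
#'   replicates.
#' @param seed integer master seed; every generator derives a per-operation
#'   sub-seed from it, so individual generators are reproducible on their
#'   own.
#' @return a validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_proteins = 1000L,
                            n_samples_per_group = 3L,
                            groups = c("PDX", "cell_line"),
                            frac_surface = 0.3,
                            frac_contaminant = 0.05,
                            log_intensity_mean = 23,
                            log_intensity_sd = 2,
                            sample_scale_sd = 0.25,
                            dropout_midpoint = 19,
                            dropout_steepness = 1.5,
                            prc2_frac_up = 0.05,
                            prc2_log2fc_mean = 3,
                            prc2_log2fc_sd = 0.5,
                            rna_coupling_rho = 0.12,
                            replicate_cv = 0.1,
                            seed = 1L) {
  .checkCount(n_proteins, "n_proteins")
  .checkCount(n_samples_per_group, "n_samples_per_group")
  if (!is.character(groups) || length(groups) < 1L || anyDuplicated(groups))
    .stopParam("groups", "must be distinct group labels")
  .checkFraction(frac_surface, "frac_surface")
  .checkFraction(frac_contaminant, "frac_contaminant")
  .checkPositive(log_intensity_sd, "log_intensity_sd")
  .checkPositive(sample_scale_sd, "sample_scale_sd", strict = FALSE)
  .checkFraction(prc2_frac_up, "prc2_frac_up")
  .checkPositive(prc2_log2fc_sd, "prc2_log2fc_sd")
  if (!is.numeric(rna_coupling_rho) || abs(rna_coupling_rho) > 1)
    .stopParam("rna_coupling_rho", "must be in [-1, 1]")
  .checkPositive(replicate_cv, "replicate_cv", strict = FALSE)
  .checkCount(seed, "seed", min = 0L)
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = groups, frac_surface = frac_surface,
    frac_contaminant = frac_contaminant,
    log_intensity_mean = log_intensity_mean,
    log_intensity_sd = log_intensity_sd,
    sample_scale_sd = sample_scale_sd,
    dropout_midpoint = dropout_midpoint,
    dropout_steepness = dropout_steepness,
    prc2_frac_up = prc2_frac_up,
    prc2_log2fc_mean = prc2_log2fc_mean,
    prc2_log2fc_sd = prc2_log2fc_sd,
    rna_coupling_rho = rna_coupling_rho,
    replicate_cv = replicate_cv,
    seed = as.integer(seed)), class = "SyntheticConfig")
}

# logistic dropout probability, monotone non-increasing in log2 intensity
.dropoutProb <- function(log2x, midpoint, steepness) {
  p <- 1 / (1 + exp(steepness * (log2x - midpoint)))
  p[is.nan(p)] <- ifelse(log2x[is.nan(p)] > midpoint, 0, 1) # Inf steepness
  p
}

# lognormal multiplicative noise with a given coefficient of variation
.cvNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a multi-group LFQ surfaceome dataset with known ground truth
#'
#' Generates linear-scale LFQ intensities for \code{n_proteins} proteins
#' across the configured sample groups: per-protein true log2 abundances are
#' Gaussian, each sample applies a multiplicative scale distortion,
#' contaminant rows are spiked in at high abundance, and cells go missing
#' with a probability that decreases logistically in true log2 intensity.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{LFQExperiment}) and \code{truth}, a list recording
#'   \code{surface_set}, \code{contaminant_set}, \code{true_sample_scales}
#'   (linear factors), \code{true_log2_abundance} and the dropout
#'   probability matrix \code{dropout_prob}.
#' @export
simulateLFQ <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(.subSeed(config$seed, "lfq"))
  np <- config$n_proteins
  ns <- config$n_samples_per_group * length(config$groups)

  prot <- sprintf("P%04d", seq_len(np))
  nContam <- round(np * config$frac_contaminant)
  contam <- if (nContam > 0) sprintf("CONTAM%03d", seq_len(nContam))
            else character()
  nSurf <- round(np * config$frac_surface)
  surface <- if (nSurf > 0) sample(prot, nSurf) else character()

  # true per-protein log2 abundance; contaminants from the upper quartile
  mu <- rnorm(np, config$log_intensity_mean, config$log_intensity_sd)
  q75 <- config$log_intensity_mean + 0.6745 * config$log_intensity_sd
  muC <- q75 + abs(rnorm(nContam, 0, config$log_intensity_sd / 2))
  mu <- c(mu, muC)
  ids <- c(prot, contam)

  samples <- paste(rep(config$groups, each = config$n_samples_per_group),
                   rep(seq_len(config$n_samples_per_group),
                       length(config$groups)), sep = "_")
  scales <- if (config$sample_scale_sd == 0) rep(1, ns) else
    2^rnorm(ns, 0, config$sample_scale_sd)

  noise <- matrix(rnorm(length(ids) * ns, 0, 0.25), length(ids), ns)
  log2true <- mu + noise   # per-cell true log2 intensity, pre-scaling
  values <- 2^log2true * rep(scales, each = length(ids))

  pDrop <- .dropoutProb(log2true, config$dropout_midpoint,
                        config$dropout_steepness)
  drop <- matrix(runif(length(pDrop)) < pDrop, nrow(values), ns)
  values[drop] <- NA_real_
  dimnames(values) <- list(ids, samples)
  dimnames(pDrop) <- dimnames(values)

  expt <- LFQExperiment(values,
                        group = rep(config$groups,
                                    each = config$n_samples_per_group))
  list(experiment = expt,
       truth = list(surface_set = sort(surface),
                    contaminant_set = contam,
                    true_sample_scales = setNames(scales, samples),
                    true_log2_abundance = setNames(mu, ids),
                    dropout_prob = pDrop))
}

#' Simulate a PRC2 active/inactive surfaceome pair
#'
#' Two condition matrices over an identical protein universe: a planted
#' subset of proteins ("derepressed" when PRC2 is lost) is multiplied by
#' \code{2^log2FC} in the PRC2-inactive condition, with per-protein log2
#' fold changes drawn from
#' N(\code{prc2_log2fc_mean}, \code{prc2_log2fc_sd}). Technical-replicate
#' noise (multiplicative, CV \code{replicate_cv}) is applied independently
#' to every cell. No intensity-dependent dropout is applied here: the pair
#' emulates deep technical-replicate runs of the same line under two PRC2
#' states.
#'
#' @param config a \code{\link{syntheticConfig}};
#'   \code{n_samples_per_group} (>= 2) is the replicate count per condition.
#' @return list with \linkS4class{LFQExperiment}s \code{active} and
#'   \code{inactive} and a \code{truth} list whose \code{planted_up_set} is
#'   a named numeric vector of true log2 fold changes.
#' @export
simulatePRC2Pair <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$n_samples_per_group < 2L)
    .stopParam("n_samples_per_group",
               "PRC2 pair needs >= 2 replicates per condition")
  set.seed(.subSeed(config$seed, "prc2"))
  np <- config$n_proteins
  nr <- config$n_samples_per_group
  prot <- sprintf("P%04d", seq_len(np))

  mu <- rnorm(np, config$log_intensity_mean, config$log_intensity_sd)
  base <- 2^mu

  nUp <- round(np * config$prc2_frac_up)
  upIdx <- if (nUp > 0) sample.int(np, nUp) else integer()
  lfc <- rnorm(nUp, config$prc2_log2fc_mean, config$prc2_log2fc_sd)
  fcMult <- rep(1, np)
  fcMult[upIdx] <- 2^lfc

  mk <- function(baseline, label) {
    v <- matrix(baseline, np, nr) *
      matrix(.cvNoise(np * nr, config$replicate_cv), np, nr)
    dimnames(v) <- list(prot, paste0(label, "_rep", seq_len(nr)))
    LFQExperiment(v, group = "cell_line", condition = label)
  }
  active <- mk(base, "PRC2_active")
  inactive <- mk(base * fcMult, "PRC2_inactive")
  list(active = active, inactive = inactive,
       truth = list(planted_up_set = setNames(lfc, prot[upIdx]),
                    base_log2_abundance = setNames(mu, prot)))
}

#' Simulate an RNA (TPM) matrix matched to an LFQ experiment
#'
#' Gaussian-copula construction: for each gene the latent log2 RNA
#' abundance is \code{rho * z + sqrt(1 - rho^2) * noise}, where \code{z} is
#' the standardized per-gene median log2 protein intensity, so the
#' population correlation between log RNA and log protein equals
#' \code{rho}. TPM values are strictly positive.
#'
#' @param lfq an \linkS4class{LFQExperiment} (genes with no detected value
#'   get an uncoupled RNA draw).
#' @param rho target correlation in [-1, 1].
#' @param seed integer seed.
#' @param n_samples number of RNA samples to emit (small independent
#'   sample-level jitter around the gene latent value).
#' @return numeric matrix of TPM values, genes x samples.
#' @export
simulateRNAMatched <- function(lfq, rho, seed, n_samples = 3L) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) > 1)
    .stopParam("rho", "must be a single value in [-1, 1]")
  set.seed(.subSeed(seed, "rna"))
  v <- intensities(lfq)
  med <- apply(v, 1L, .presentMedian)
  z <- rep(0, length(med))
  ok <- !is.na(med)
  if (sum(ok) >= 2L) z[ok] <- as.numeric(scale(log2(med[ok])))
  z[!ok] <- rnorm(sum(!ok))

  latent <- rho * z + sqrt(1 - rho^2) * rnorm(length(z))
  # map the unit-variance latent onto a realistic log2 TPM scale
  log2tpm <- 4 + 2 * latent
  jitter <- matrix(rnorm(length(z) * n_samples, 0, 0.05), length(z),
                   n_samples)
  tpm <- 2^(log2tpm + jitter)
  dimnames(tpm) <- list(rownames(v), paste0("rna_", seq_len(n_samples)))
  tpm
}

#' Simulate a 4-peak PE calibration bead panel
#'
#' Peak median fluorescences follow
#' \code{log10(MFI) = intercept + slope * log10(PE)} with optional
#' multiplicative lognormal noise.
#'
#' @param slope,intercept true calibration line (log10-log10 scale).
#' @param pe_per_bead strictly increasing positive PE molecules per bead;
#'   the default is a typical 4-level QuantiBrite-style lot.
#' @param noise_cv multiplicative noise CV on the peak MFIs (0 = exact).
#' @param seed integer seed.
#' @return data.frame with columns \code{peak}, \code{pe_per_bead},
#'   \code{mfi}.
#' @export
simulateBeadPanel <- function(slope = 1, intercept = 0,
                              pe_per_bead = c(474, 5359, 23843, 62336),
                              noise_cv = 0, seed = 1L) {
  if (any(pe_per_bead <= 0) || any(diff(pe_per_bead) <= 0))
    .stopParam("pe_per_bead", "must be strictly increasing and > 0")
  .checkPositive(noise_cv, "noise_cv", strict = FALSE)
  set.seed(.subSeed(seed, "beads"))
  mfi <- 10^(intercept + slope * log10(pe_per_bead)) *
    .cvNoise(length(pe_per_bead), noise_cv)
  data.frame(peak = seq_along(pe_per_bead), pe_per_bead = pe_per_bead,
             mfi = mfi)
}

#' Simulate a viability plate for one drug/cell line
#'
#' Raw well intensities are \code{background + signal * f(dose)} for drug
#' wells, \code{background} for media-only wells, and
#' \code{background + signal * d} (the full upper-asymptote signal) for
#' zero-drug wells, where \code{f} is the 4PL curve of \code{true_fit}.
#' Noise is multiplicative Gaussian with sd \code{noise_sd}.
#'
#' @param true_fit a \linkS4class{DoseResponseFit} holding the true 4PL
#'   parameters (use \code{\link{doseResponseFit}} to build one).
#' @param doses positive drug concentrations (molar); each tested in
#'   \code{n_reps} replicate wells.
#' @param n_reps replicate wells per dose (the screen design default is
#'   quadruplicate).
#' @param n_media_wells,n_zero_wells media-only and zero-drug well counts
#'   (design default 8 of each).
#' @param noise_sd multiplicative noise sd (0.05 = 5\% noise).
#' @param background,signal plate optics: additive background intensity and
#'   full-viability signal amplitude.
#' @param seed integer seed.
#' @param drug,plate identifiers written into the plate table.
#' @return data.frame with columns \code{plate}, \code{well}, \code{row},
#'   \code{col}, \code{role} (drug/zero_drug/media_only), \code{drug},
#'   \code{dose}, \code{intensity}.
#' @export
simulateViabilityPlate <- function(true_fit, doses, n_reps = 4L,
                                   n_media_wells = 8L, n_zero_wells = 8L,
                                   noise_sd = 0.05, background = 200,
                                   signal = 2000, seed = 1L,
                                   drug = "drug1", plate = "plate1") {
  if (any(doses <= 0)) .stopParam("doses", "must all be > 0")
  .checkCount(n_reps, "n_reps")
  .checkCount(n_media_wells, "n_media_wells")
  .checkCount(n_zero_wells, "n_zero_wells")
  .checkPositive(noise_sd, "noise_sd", strict = FALSE)
  set.seed(.subSeed(seed, "plate"))

  f <- .ll4(doses, true_fit@b, true_fit@c, true_fit@d, true_fit@e)
  mean_int <- c(rep(background + signal * f, each = n_reps),
                rep(background + signal * true_fit@d, n_zero_wells),
                rep(background, n_media_wells))
  role <- c(rep("drug", length(doses) * n_reps),
            rep("zero_drug", n_zero_wells),
            rep("media_only", n_media_wells))
  dose <- c(rep(doses, each = n_reps), rep(NA_real_,
            n_zero_wells + n_media_wells))
  n <- length(mean_int)
  intensity <- mean_int * (1 + rnorm(n, 0, noise_sd))
  row <- LETTERS[(seq_len(n) - 1L) %/% 24L + 1L]
  col <- (seq_len(n) - 1L) %% 24L + 1L
  data.frame(plate = plate, well = paste0(row, col), row = row, col = col,
             role = role,
             drug = ifelse(role == "drug", drug, NA_character_),
             dose = dose, intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Simulate an antigen-density / ADC-potency screen panel
#'
#' Emulates the coupled structure in which a denser surface antigen makes
#' the targeting antibody-drug conjugate more potent: per cell line,
#' antigens per cell are drawn log-uniformly and the true IC50 is
#' proportional to 1/density with multiplicative lognormal noise.
#'
#' @param n_lines number of cell line / antigen pairs.
#' @param kappa proportionality constant (molar x antigens/cell); the
#'   default puts IC50s in the low-nanomolar range at typical densities.
#' @param density_range log10 range of antigens per cell to draw from.
#' @param noise_cv multiplicative CV of the IC50 around kappa/density.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{antigen},
#'   \code{antigens_per_cell}, \code{true_ic50}.
#' @export
simulateDensityPotencyPanel <- function(n_lines = 12L, kappa = 3e-4,
                                        density_range = c(3.5, 5.5),
                                        noise_cv = 0.1, seed = 1L) {
  .checkCount(n_lines, "n_lines")
  set.seed(.subSeed(seed, "screen"))
  dens <- 10^runif(n_lines, density_range[1], density_range[2])
  ic50 <- kappa / dens * .cvNoise(n_lines, noise_cv)
  data.frame(sample = sprintf("line%02d", seq_len(n_lines)),
             antigen = "PTK7",
             antigens_per_cell = dens, true_ic50 = ic50,
             stringsAsFactors = FALSE)
}

#' Simulate flow-cytometry median-fluorescence summaries
#'
#' Inverts a calibration line to produce stained and isotype MFIs from true
#' antigen densities: stained PE molecules per cell =
#' \code{density * pe_per_antibody + isotype_pe} (specific plus nonspecific
#' signal), isotype PE = \code{isotype_pe}.
#'
#' @param densities data.frame with \code{sample}, \code{antigen},
#'   \code{antigens_per_cell} (e.g. from
#'   \code{\link{simulateDensityPotencyPanel}}).
#' @param slope,intercept the true calibration line.
#' @param isotype_pe nonspecific PE molecules per cell.
#' @param pe_per_antibody PE molecules per antibody (1:1 conjugation
#'   default).
#' @param noise_cv multiplicative MFI noise.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{antigen},
#'   \code{stained_mfi}, \code{isotype_mfi}, \code{pe_per_antibody}.
#' @export
simulateFlowSummaries <- function(densities, slope = 1, intercept = 0,
                                  isotype_pe = 300, pe_per_antibody = 1,
                                  noise_cv = 0, seed = 1L) {
  set.seed(.subSeed(seed, "flow"))
  pe <- densities$antigens_per_cell * pe_per_antibody + isotype_pe
  n <- nrow(densities)
  stained <- 10^(intercept + slope * log10(pe)) * .cvNoise(n, noise_cv)
  iso <- 10^(intercept + slope * log10(isotype_pe)) * .cvNoise(n, noise_cv)
  data.frame(sample = densities$sample, antigen = densities$antigen,
             stained_mfi = stained, isotype_mfi = iso,
             pe_per_antibody = pe_per_antibody, stringsAsFactors = FALSE)
}
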