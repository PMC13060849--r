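# the LL.4 four-parameter log-logistic: viability at dose x
.ll4 <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))

#' Construct a DoseResponseFit by hand
#'
#' Mainly for specifying true curves for the plate simulator; fitted
#' objects come from \code{\link{fit4PL}}.
#'
#' @param b,c,d,e LL.4 parameters (slope, lower asymptote, upper asymptote,
#'   midpoint = IC50 on the dose scale).
#' @param drug,sample identifiers.
#' @param converged logical flag (default TRUE).
#' @param rss residual sum of squares (0 for a specified true curve).
#' @param doseRange covered dose range.
#' @param nObs number of observations.
#' @return a \linkS4class{DoseResponseFit}.
#' @export
doseResponseFit <- function(b, c, d, e, drug = "", sample = "",
                            converged = TRUE, rss = 0,
                            doseRange = c(NA_real_, NA_real_),
                            nObs = 0L) {
  new("DoseResponseFit", drug = drug, sample = sample, b = b, c = c,
      d = d, e = e, rss = rss, converged = converged,
      doseRange = as.numeric(doseRange), nObs = as.integer(nObs))
}

#' @rdname ic50
#' @export
setMethod("ic50", "DoseResponseFit", function(x)
  if (isTRUE(x@converged)) x@e else NA_real_)

setMethod("show", "DoseResponseFit", function(object) {
  if (isTRUE(object@converged))
    cat(sprintf(
      "DoseResponseFit [%s%s]: IC50 = %.3g, b = %.3g, c = %.3g, d = %.3g (rss %.3g, n %d)\n",
      object@drug, if (nzchar(object@sample)) paste0("/", object@sample)
      else "", object@e, object@b, object@c, object@d, object@rss,
      object@nObs))
  else
    cat(sprintf("DoseResponseFit [%s]: not converged (no IC50)\n",
                object@drug))
})

#' Subtract the plate background from well intensities
#'
#' Every well's raw intensity is shifted by the mean intensity of that
#' plate's media-only wells (the standard design carries 8 media wells per
#' plate). Shifting is per plate id.
#'
#' @param plate data.frame in the plate layout of
#'   \code{\link{simulateViabilityPlate}} (columns \code{plate},
#'   \code{role}, \code{intensity}, ...).
#' @return the plate table with an added \code{shifted} column.
#' @export
backgroundShift <- function(plate) {
  stopifnot(all(c("plate", "role", "intensity") %in% colnames(plate)))
  out <- plate
  out$shifted <- NA_real_
  for (p in unique(plate$plate)) {
    sel <- plate$plate == p
    media <- plate$intensity[sel & plate$role == "media_only"]
    if (length(media) == 0L)
      .stopData(sprintf("plate '%s' has no media_only wells", p))
    out$shifted[sel] <- plate$intensity[sel] - mean(media)
  }
  out
}

#' Normalize shifted intensities to viability fractions
#'
#' Viability of a drug well is its background-shifted intensity divided by
#' the mean shifted intensity of the plate's zero-drug wells (design
#' default: 8 wells with zero drug). Replicate wells are kept as individual
#' observations. Runs \code{\link{backgroundShift}} first if the
#' \code{shifted} column is absent.
#'
#' @param plate plate table (see \code{\link{backgroundShift}}).
#' @return data.frame per drug well: \code{plate}, \code{well},
#'   \code{drug}, \code{dose}, \code{viability}.
#' @export
normalizeViability <- function(plate) {
  if (!("shifted" %in% colnames(plate))) plate <- backgroundShift(plate)
  out <- NULL
  for (p in unique(plate$plate)) {
    sel <- plate$plate == p
    z <- plate$shifted[sel & plate$role == "zero_drug"]
    if (length(z) == 0L)
      .stopData(sprintf("plate '%s' has no zero_drug wells", p))
    z0 <- mean(z)
    if (z0 <= 0)
      .stopData(sprintf("plate '%s': zero-drug signal below background", p))
    dw <- plate[sel & plate$role == "drug", , drop = FALSE]
    out <- rbind(out, data.frame(
      plate = dw$plate, well = dw$well, drug = dw$drug, dose = dw$dose,
      viability = dw$shifted / z0, stringsAsFactors = FALSE))
  }
  out
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{f(x) = c + (d - c)/(1 + \exp(b(\ln x - \ln e)))} to per-well
#' viability observations for one drug (Levenberg-Marquardt). Starting
#' values come from the data: \code{d} from the top, \code{c} from the
#' bottom of the observed viabilities, \code{e} from the dose whose mean
#' response is nearest the half-range crossing, and the sign of \code{b}
#' from the dose-response trend. Viabilities are not clipped to [0, 1]
#' (clipping biases the asymptotes). A flat response, a failed optimizer or
#' a midpoint escaping far outside the tested dose range yields
#' \code{converged = FALSE} and no IC50 rather than an error, so screens
#' containing inactive drugs complete.
#'
#' @param viability data.frame from \code{\link{normalizeViability}}.
#' @param drug drug id to fit (default: the single drug present).
#' @return a \linkS4class{DoseResponseFit}.
#' @export
fit4PL <- function(viability, drug = NULL) {
  stopifnot(all(c("drug", "dose", "viability") %in% colnames(viability)))
  if (is.null(drug)) {
    drugs <- unique(viability$drug)
    if (length(drugs) != 1L)
      .stopParam("drug", "several drugs present; name one")
    drug <- drugs
  }
  v <- viability[viability$drug == drug & !is.na(viability$dose), ,
                 drop = FALSE]
  doses <- sort(unique(v$dose))
  if (length(doses) < 4L)
    .stopData("a 4-parameter fit needs >= 4 distinct doses")
  x <- v$dose; y <- v$viability
  meanByDose <- tapply(y, x, mean)
  dosesOrd <- as.numeric(names(meanByDose))

  d0 <- max(meanByDose); c0 <- min(meanByDose)
  half <- (d0 + c0) / 2
  e0 <- dosesOrd[which.min(abs(meanByDose - half))]
  trend <- suppressWarnings(cor(log(dosesOrd), as.numeric(meanByDose)))
  b0 <- if (!is.na(trend) && trend > 0) -1 else 1   # b > 0: decreasing

  flatRSS <- sum((y - mean(y))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c + (d - c) / (1 + exp(b * (log(x) - log(e)))),
      start = list(b = b0, c = c0, d = d0, e = e0),
      lower = c(-50, -Inf, -Inf, min(doses) / 1e6),
      upper = c(50, Inf, Inf, max(doses) * 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  bad <- function() doseResponseFit(
    b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_, drug = drug,
    converged = FALSE, rss = flatRSS, doseRange = range(doses),
    nObs = length(y))

  if (is.null(fit)) return(bad())
  co <- coef(fit)
  rss <- sum(resid(fit)^2)
  # a real dose response must beat the flat model clearly and keep its
  # midpoint near the tested doses; otherwise report non-convergence
  explained <- if (flatRSS > 0) 1 - rss / flatRSS else 0
  inRange <- co[["e"]] > min(doses) / 1e3 && co[["e"]] < max(doses) * 1e3
  amplitude <- abs(co[["d"]] - co[["c"]])
  if (explained < 0.5 || !inRange || amplitude < 0.1) return(bad())

  doseResponseFit(b = co[["b"]], c = co[["c"]], d = co[["d"]],
                  e = co[["e"]], drug = drug, converged = TRUE, rss = rss,
                  doseRange = range(doses), nObs = length(y))
}

#' Antigen density vs ADC potency correlation
#'
#' Spearman correlation between antigens per cell and IC50 over matched
#' (sample, antigen/drug) pairs with converged fits. A negative rho means
#' denser antigens need less drug for half-maximal killing. The p-value is
#' the exact permutation p for n < 10 (no ties) and the asymptotic
#' approximation otherwise.
#'
#' @param densities data.frame from \code{\link{antigenDensity}}.
#' @param fits list of \linkS4class{DoseResponseFit}s.
#' @param pairing data.frame mapping \code{sample} + \code{antigen} to
#'   \code{drug}. Defaults to pairing fit \code{sample}/\code{drug} slots
#'   directly against the density table's \code{sample} rows.
#' @return list with \code{rho}, \code{p}, \code{n} and the paired
#'   \code{data} (sample, antigens_per_cell, ic50).
#' @export
densityPotencyCorrelation <- function(densities, fits, pairing = NULL) {
  ics <- data.frame(
    sample = vapply(fits, slot, "", "sample"),
    drug = vapply(fits, slot, "", "drug"),
    ic50 = vapply(fits, ic50, 0),
    stringsAsFactors = FALSE)
  ics <- ics[!is.na(ics$ic50), , drop = FALSE]
  if (!is.null(pairing)) {
    m <- merge(densities, pairing, by = c("sample", "antigen"))
    m <- merge(m, ics, by = c("sample", "drug"))
  } else {
    m <- merge(densities, ics, by = "sample")
  }
  if (nrow(m) < 3L)
    .stopData("need >= 3 matched density/IC50 pairs with converged fits")
  ct <- suppressWarnings(
    cor.test(m$antigens_per_cell, m$ic50, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       data = m[, c("sample", "antigens_per_cell", "ic50")])
}
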