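#' Effective radical dose from adenine dosimetry
#'
#' The adenine internal-standard dosimeter loses 260 nm absorbance in
#' proportion to the hydroxyl radical available after scavenging, so
#' the effective dose delivered in an exposure is the drop in A260.
#'
#' @param a260_before,a260_after Absorbance readings (>= 0) before and
#'   after laser exposure.
#' @return Effective dose (delta A260, dimensionless, >= 0).
#' @export
effective_dose <- function(a260_before, a260_after) {
  stopifnot(all(a260_before >= 0), all(a260_after >= 0))
  dose <- a260_before - a260_after
  if (any(dose < 0)) {
    stop("negative effective dose: dosimeter absorbance must decrease ",
         "(are the before/after readings swapped?)")
  }
  dose
}

#' Fit a per-residue linear dose-response regression
#'
#' Ordinary least squares of oxidation fraction on effective radical
#' dose; the slope is the residue's radical response rate (its HRPF
#' reactivity). Replicates enter as individual points.
#'
#' @param points Data frame with columns `dose` and `oxidation` (and
#'   optionally `replicate`).
#' @param force_origin If `TRUE`, fit without intercept.
#' @return A one-row data frame: slope, intercept, slope_se, r2, n.
#' @export
fit_dose_response <- function(points, force_origin = FALSE) {
  stopifnot(all(points$dose >= 0), all(points$oxidation >= 0),
            all(points$oxidation <= 1))
  if (length(unique(points$dose)) < 3L) {
    stop("dose-response fit needs >= 3 distinct dose values")
  }
  fml <- if (force_origin) oxidation ~ dose - 1 else oxidation ~ dose
  fit <- stats::lm(fml, data = points)
  # noise-free fixtures trigger the "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  data.frame(
    slope = co["dose", "Estimate"],
    intercept = if (force_origin) 0 else co["(Intercept)", "Estimate"],
    slope_se = co["dose", "Std. Error"],
    r2 = sm$r.squared,
    n = nrow(points)
  )
}

#' Filter slopes to residues with detectable oxidation
#'
#' Keeps residues whose dose-response slope is positive and exceeds
#' `min_t` standard errors — the analogue of a residue being observed
#' as oxidized in an experiment. Residues below the detection floor
#' carry no usable reactivity signal and would otherwise contaminate
#' ratio or calibration analyses with pure noise.
#'
#' @param slopes Slope table from [fit_slopes()].
#' @param min_t Minimum slope / slope_se (default 3).
#' @return Filtered slope table; dropped keys in
#'   `attr(, "undetected")`.
#' @export
detected_residues <- function(slopes, min_t = 3) {
  keep <- slopes$slope > 0 & slopes$slope / slopes$slope_se > min_t
  out <- slopes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "undetected") <- paste0(slopes$resname[!keep], slopes$resseq[!keep])
  out
}

#' Fit dose-response slopes for a residue table
#'
#' Applies [fit_dose_response()] per residue key. Residues with fewer
#' than 3 distinct doses are excluded and logged in the
#' `"excluded"` attribute.
#'
#' @param measurements Data frame with columns `chain`, `resseq`,
#'   `resname`, `dose`, `oxidation` (and optionally `replicate`).
#' @inheritParams fit_dose_response
#' @return Data frame of per-residue fits: chain, resseq, resname,
#'   slope, intercept, slope_se, r2, n; excluded residues recorded in
#'   `attr(, "excluded")`.
#' @export
fit_slopes <- function(measurements, force_origin = FALSE) {
  key <- paste(measurements$chain, measurements$resseq,
               measurements$resname, sep = "|")
  res <- list()
  excluded <- character()
  for (k in unique(key)) {
    pts <- measurements[key == k, , drop = FALSE]
    if (length(unique(pts$dose)) < 3L) {
      excluded <- c(excluded, paste0(k, ": <3 distinct doses"))
      next
    }
    f <- fit_dose_response(pts, force_origin = force_origin)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    res[[k]] <- cbind(data.frame(chain = parts[1],
                                 resseq = as.integer(parts[2]),
                                 resname = parts[3],
                                 stringsAsFactors = FALSE), f)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
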