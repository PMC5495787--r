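#' Intrinsic amino-acid reactivity table (k/k_p)
#'
#' Per-residue-type rate constants for reaction with hydroxyl radical,
#' expressed relative to proline (k/k_p, dimensionless; PRO = 1 by
#' definition). The shipped defaults are compiled from aqueous
#' radiolysis rate-constant measurements on free amino acids; the table
#' is configuration, not code, and any analysis is conditional on it.
#'
#' @param path Optional CSV with columns `resname,kkp` to override the
#'   shipped table.
#' @return Named numeric vector k/k_p keyed by 3-letter code.
#' @export
reactivity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reactivity_kkp.csv", package = "hrpfsasa")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$kkp > 0))
  stats::setNames(tab$kkp, toupper(tab$resname))
}

#' Normalized protection factor (NPF)
#'
#' NPF of residue i = Slope_i / (k_i / k_p): the dose-response slope
#' divided by the residue type's intrinsic reactivity relative to
#' proline, putting residues of different chemistry on a common scale.
#'
#' @param slopes Data frame of per-residue fits from [fit_slopes()]
#'   (columns `resname`, `slope`, ...).
#' @param table Reactivity lookup from [reactivity_table()].
#' @return The input with columns `kkp` and `npf` appended.
#' @export
npf <- function(slopes, table = reactivity_table()) {
  kkp <- table[toupper(slopes$resname)]
  if (any(is.na(kkp))) {
    stop("amino acid(s) missing from reactivity table: ",
         paste(unique(slopes$resname[is.na(kkp)]), collapse = ", "))
  }
  if (any(kkp <= 0)) stop("k/k_p must be positive")
  slopes$kkp <- unname(kkp)
  slopes$npf <- slopes$slope / slopes$kkp
  slopes
}

#' Classify residues by intrinsic reactivity
#'
#' Thresholds on k/k_p: high (> 10), moderate (4 to 10), poor (< 4).
#' Boundary values fall downward (exactly 10 is moderate, exactly 4 is
#' poor), matching the strict inequalities of the class definitions.
#'
#' @param aa Vector of 3-letter codes.
#' @param table Reactivity lookup from [reactivity_table()].
#' @return Factor with levels `high`, `moderate`, `poor`.
#' @export
classify_reactivity <- function(aa, table = reactivity_table()) {
  kkp <- table[toupper(aa)]
  if (any(is.na(kkp))) {
    stop("amino acid(s) missing from reactivity table: ",
         paste(unique(aa[is.na(kkp)]), collapse = ", "))
  }
  cls <- ifelse(kkp > 10, "high", ifelse(kkp > 4, "moderate", "poor"))
  factor(unname(cls), levels = c("high", "moderate", "poor"))
}

#' Fractional side-chain SASA
#'
#' Divides a residue's ensemble-average side-chain SASA by the
#' fully-exposed Gly-X-Gly reference for its type, giving a fractional
#' exposure (0 = buried, 1 = as exposed as in the free tripeptide).
#' Values slightly above 1 can occur for surface residues and are kept
#' with a warning.
#'
#' @param residue_sasa `ResidueSASA` data frame (or any table with
#'   `resname` and `mean_sasa`).
#' @param ref Named GXG reference vector from [gxg_reference()].
#' @return Input with column `fractional_sasa` appended.
#' @export
fractional_sasa <- function(residue_sasa, ref = gxg_reference()) {
  if (any(residue_sasa$resname == "GLY")) {
    stop("glycine has no side-chain reference; exclude GLY first")
  }
  g <- ref[toupper(residue_sasa$resname)]
  if (any(is.na(g) | g <= 0)) {
    stop("no positive GXG reference for: ",
         paste(unique(residue_sasa$resname[is.na(g) | g <= 0]), collapse = ", "))
  }
  fs <- residue_sasa$mean_sasa / unname(g)
  if (any(fs > 1)) {
    warning(sum(fs > 1), " residue(s) with fractional SASA > 1 (kept)")
  }
  residue_sasa$fractional_sasa <- fs
  residue_sasa
}

#' Filter residues for calibration
#'
#' Applies the exclusion rules used before correlating reactivity with
#' SASA: sulfur-containing residues (Met, Cys; background oxidation
#' inflates their apparent reactivity) and, optionally, residues below
#' a minimum intrinsic reactivity (k/k_p <= `min_kkp`), whose
#' free-amino-acid normalization correlates poorly with SASA. Every
#' exclusion is logged.
#'
#' @param data Residue-keyed data frame with a `resname` column.
#' @param exclude_sulfur Drop MET and CYS (default `TRUE`).
#' @param min_kkp Keep only residues with k/k_p strictly greater than
#'   this value; `NULL` disables the filter.
#' @param exclude_gly Drop GLY (no side chain).
#' @param table Reactivity lookup (used for `min_kkp`).
#' @return Filtered data frame; dropped rows described in
#'   `attr(, "exclusion_log")`.
#' @export
exclude_residues <- function(data, exclude_sulfur = TRUE, min_kkp = NULL,
                             exclude_gly = TRUE, table = reactivity_table()) {
  log <- character()
  keep <- rep(TRUE, nrow(data))
  rn <- toupper(data$resname)
  lab <- if (!is.null(data$resseq)) paste0(data$resname, data$resseq) else data$resname
  if (exclude_sulfur) {
    drop <- rn %in% c("MET", "CYS")
    log <- c(log, paste0(lab[drop], ": sulfur-containing residue"))
    keep <- keep & !drop
  }
  if (exclude_gly) {
    drop <- keep & rn == "GLY"
    log <- c(log, paste0(lab[drop], ": glycine (no side chain)"))
    keep <- keep & !drop
  }
  if (!is.null(min_kkp)) {
    kkp <- table[rn]
    drop <- keep & (is.na(kkp) | kkp <= min_kkp)
    log <- c(log, paste0(lab[drop], ": k/k_p <= ", min_kkp))
    keep <- keep & !drop
  }
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  out
}

#' Native:denatured ratio observations
#'
#' Forms, per residue, the reactivity ratio Slope_N / Slope_D and the
#' accessibility ratio SASA_N / SASA_D. Because the intrinsic
#' (sequence-context-modified) reactivity of a residue is identical in
#' the native and thermally denatured protein, it cancels in the slope
#' ratio — no free-amino-acid rate table is needed. The denatured-state
#' SASA defaults to the Gly-X-Gly reference (a denatured chain is
#' modelled as fully exposed); a measured denatured ensemble SASA table
#' can be supplied instead.
#'
#' @param native,denatured Slope tables from [fit_slopes()] for the
#'   native and denatured states.
#' @param sasa_native `ResidueSASA` table for the native structure.
#' @param ref GXG reference from [gxg_reference()].
#' @param sasa_denatured Optional `ResidueSASA` table for the denatured
#'   state, overriding the GXG model.
#' @return Data frame: chain, resseq, resname, slope_ratio, sasa_ratio.
#'   Residues with nonpositive denatured slope are dropped and listed
#'   in `attr(, "unusable")`.
#' @export
native_denatured_ratio <- function(native, denatured, sasa_native,
                                   ref = gxg_reference(),
                                   sasa_denatured = NULL) {
  kn <- paste(native$chain, native$resseq, native$resname, sep = "|")
  kd <- paste(denatured$chain, denatured$resseq, denatured$resname, sep = "|")
  ks <- paste(sasa_native$chain, sasa_native$resseq, sasa_native$resname, sep = "|")
  common <- intersect(intersect(kn, kd), ks)
  if (length(common) == 0L) stop("no residues common to native, denatured and SASA tables")
  n <- native[match(common, kn), ]
  d <- denatured[match(common, kd), ]
  s <- sasa_native[match(common, ks), ]
  sasa_d <- if (is.null(sasa_denatured)) {
    unname(ref[toupper(n$resname)])
  } else {
    kdd <- paste(sasa_denatured$chain, sasa_denatured$resseq,
                 sasa_denatured$resname, sep = "|")
    sasa_denatured$mean_sasa[match(common, kdd)]
  }
  usable <- d$slope > 0 & !is.na(sasa_d) & sasa_d > 0
  out <- data.frame(
    chain = n$chain[usable], resseq = n$resseq[usable],
    resname = n$resname[usable],
    slope_ratio = n$slope[usable] / d$slope[usable],
    sasa_ratio = s$mean_sasa[usable] / sasa_d[usable],
    stringsAsFactors = FALSE
  )
  attr(out, "unusable") <- paste0(n$resname[!usable], n$resseq[!usable],
                                  ": nonpositive denatured slope or SASA")
  out
}
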