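#' Deterministic unit-sphere test points (golden spiral)
#'
#' Generates `n` near-uniform points on the unit sphere by the
#' Fibonacci / golden-spiral lattice. No random numbers are involved,
#' so SASA results are bit-stable across runs and platforms.
#'
#' @param n Number of points (>= 1).
#' @return An `n x 3` matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)           # polar angle
  theta <- pi * (1 + sqrt(5)) * i      # golden-angle increments
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over every atom: each atom is covered with
#' `n_points` test points on its solvent-expanded sphere of radius
#' r_vdw + probe, points falling inside any neighbouring expanded
#' sphere are occluded, and SASA = (exposed fraction) x 4 pi
#' (r_vdw + probe)^2.
#'
#' @param model A `StructureModel`, or a data frame of atoms with
#'   columns `x, y, z, vdw_radius`.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom; accuracy is ~1% of the exact
#'   sphere area at 960 points.
#' @return Numeric vector of per-atom SASA (Angstrom^2), in atom order.
#' @export
shrake_rupley <- function(model, probe_radius = 1.4, n_points = 960) {
  atoms <- if (inherits(model, "StructureModel")) model$atoms else model
  stopifnot(n_points >= 32, probe_radius >= 0)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in SASA input")
  r <- atoms$vdw_radius + probe_radius
  stopifnot(all(atoms$vdw_radius > 0))
  n <- nrow(xyz)
  sphere <- golden_spiral_points(n_points)
  area <- 4 * pi * r^2

  # pairwise neighbour lists: j occludes i iff d_ij < r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  lim <- outer(r, r, "+")^2
  nb <- d2 < lim
  diag(nb) <- FALSE

  sasa <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(nb[i, ])
    if (length(js) == 0L) {
      sasa[i] <- area[i]
      next
    }
    pts <- sphere * r[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    # test nearest neighbours first: they occlude most points
    js <- js[order(d2[i, js])]
    for (j in js) {
      if (!any(exposed)) break
      dx <- pts[exposed, 1L] - xyz[j, 1L]
      dy <- pts[exposed, 2L] - xyz[j, 2L]
      dz <- pts[exposed, 3L] - xyz[j, 3L]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz >= r[j]^2
    }
    sasa[i] <- sum(exposed) / n_points * area[i]
  }
  sasa
}

#' Per-residue side-chain SASA of a single structure
#'
#' Sums per-atom SASA over side-chain heavy atoms (everything except
#' N, CA, C, O, OXT). Glycine has no side-chain heavy atom and reports
#' 0 with `is_gly = TRUE`; it is excluded from downstream calibration.
#'
#' @inheritParams shrake_rupley
#' @param whole_residue If `TRUE`, sum over all heavy atoms of the
#'   residue instead of the side chain only.
#' @return A `ResidueSASA` data frame: chain, resseq, resname,
#'   mean_sasa, sd_sasa (0 for a single model), n_models, is_gly.
#' @export
residue_sidechain_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                                   whole_residue = FALSE) {
  stopifnot(inherits(model, "StructureModel"))
  atoms <- model$atoms
  sasa <- shrake_rupley(model, probe_radius, n_points)
  keep <- if (whole_residue) rep(TRUE, nrow(atoms)) else atoms$is_sidechain
  key <- paste(atoms$chain, atoms$resseq, atoms$resname, sep = "|")
  ukey <- unique(key)
  tot <- vapply(ukey, function(k) sum(sasa[keep & key == k]), numeric(1))
  parts <- do.call(rbind, strsplit(ukey, "|", fixed = TRUE))
  out <- data.frame(
    chain = parts[, 1L],
    resseq = as.integer(parts[, 2L]),
    resname = parts[, 3L],
    mean_sasa = unname(tot),
    sd_sasa = 0,
    n_models = 1L,
    is_gly = parts[, 3L] == "GLY",
    stringsAsFactors = FALSE
  )
  has_sc <- vapply(ukey, function(k) any(keep & key == k), logical(1))
  no_sc <- !out$is_gly & !has_sc
  if (!whole_residue && any(no_sc)) {
    warning("residue(s) without side-chain atoms reported as 0: ",
            paste(ukey[no_sc], collapse = ", "))
  }
  class(out) <- c("ResidueSASA", "data.frame")
  out
}

#' Ensemble-averaged per-residue side-chain SASA
#'
#' Computes [residue_sidechain_sasa()] for every model of an ensemble
#' and reports the (optionally weighted) mean and population SD across
#' models — the footprinting analogue of averaging SASA over molecular
#' dynamics snapshots.
#'
#' @param ens An `Ensemble` (see [ensemble()]) or list of
#'   `StructureModel`s with identical residue rosters.
#' @inheritParams residue_sidechain_sasa
#' @return A `ResidueSASA` data frame with `n_models` set to the
#'   ensemble size.
#' @export
ensemble_mean_sasa <- function(ens, probe_radius = 1.4, n_points = 960,
                               whole_residue = FALSE) {
  if (!inherits(ens, "Ensemble")) ens <- ensemble(ens)
  per <- lapply(ens$models, residue_sidechain_sasa,
                probe_radius = probe_radius, n_points = n_points,
                whole_residue = whole_residue)
  k <- length(per)
  w <- if (is.null(ens$weights)) rep(1 / k, k) else ens$weights
  vals <- sapply(per, function(p) p$mean_sasa)  # residues x models
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  mu <- as.numeric(vals %*% w)
  sdv <- sqrt(as.numeric((vals - mu)^2 %*% w))  # population SD
  out <- per[[1L]]
  out$mean_sasa <- mu
  out$sd_sasa <- sdv
  out$n_models <- k
  out
}

#' Write a per-residue SASA table as TSV
#'
#' @param res A `ResidueSASA` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sasa_tsv <- function(res, path) {
  out <- data.frame(chain = res$chain, resseq = res$resseq,
                    resname = res$resname,
                    mean_sasa_A2 = res$mean_sasa,
                    sd_sasa_A2 = res$sd_sasa,
                    n_models = res$n_models)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
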