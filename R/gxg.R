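AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

place_atom <- function(a, b, c, bond, angle, torsion) {
  # NeRF: position of atom d given positions a-b-c, the c-d bond length,
  # the b-c-d angle and the a-b-c-d torsion (degrees)
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

rotate_about_axis <- function(pts, origin, axis, theta_deg) {
  th <- theta_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(pts, 2L, origin)
  # Rodrigues rotation
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  r <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  sweep(p %*% t(r), 2L, origin, "+")
}

residue_templates <- function() {
  path <- system.file("extdata", "residue_templates.csv", package = "hrpfsasa")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build an extended Gly-X-Gly tripeptide
#'
#' Constructs a fully extended (phi = -120, psi = +120 degrees)
#' glycine-X-glycine tripeptide with idealized backbone geometry and
#' grafts the side chain of residue X from a shipped idealized
#' amino-acid geometry library. Used to generate the fully-exposed
#' reference SASA for each residue type.
#'
#' @param aa Three-letter amino-acid code of the central residue.
#' @param chi1 Rotation (degrees) applied to the side chain about the
#'   CA-CB axis, sweeping chi1 rotamers.
#' @param radii Radius table from [vdw_radii()].
#' @return A `StructureModel` of the tripeptide.
#' @export
build_gxg_tripeptide <- function(aa, chi1 = 0, radii = vdw_radii()) {
  aa <- toupper(aa)
  if (!aa %in% AA3) stop("nonstandard amino acid: ", aa)
  phi <- -120; psi <- 120; omega <- 180
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8

  # residue 1 seed atoms
  n1 <- c(0, 0, 0)
  ca1 <- c(b_nca, 0, 0)
  c1 <- ca1 + b_cac * c(-cos(a_ncac * pi / 180), sin(a_ncac * pi / 180), 0)
  bb <- list(list(N = n1, CA = ca1, C = c1))
  for (i in 2:3) {
    p <- bb[[i - 1L]]
    n <- place_atom(p$N, p$CA, p$C, b_cn, a_cacn, psi)
    ca <- place_atom(p$CA, p$C, n, b_nca, a_cnca, omega)
    cc <- place_atom(p$C, n, ca, b_cac, a_ncac, phi)
    bb[[i]] <- list(N = n, CA = ca, C = cc)
  }
  rows <- list()
  add <- function(resseq, resname, name, el, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = el, resname = resname, chain = "A",
      resseq = resseq, x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, stringsAsFactors = FALSE)
  }
  resnames <- c("GLY", aa, "GLY")
  for (i in 1:3) {
    p <- bb[[i]]
    o <- place_atom(p$N, p$CA, p$C, b_co, a_caco,
                    if (i < 3) psi + 180 else psi - 60)
    add(i, resnames[i], "N", "N", p$N)
    add(i, resnames[i], "CA", "C", p$CA)
    add(i, resnames[i], "C", "C", p$C)
    add(i, resnames[i], "O", "O", o)
  }
  atoms <- do.call(rbind, rows)

  if (aa != "GLY") {
    tpl <- residue_templates()
    tpl <- tpl[tpl$resname == aa, , drop = FALSE]
    bbsel <- match(c("N", "CA", "C"), tpl$atom)
    txyz <- as.matrix(tpl[, c("x", "y", "z")])
    tgt <- rbind(bb[[2]]$N, bb[[2]]$CA, bb[[2]]$C)
    tr <- superpose(txyz[bbsel, , drop = FALSE], tgt)
    sc <- !(tpl$atom %in% c("N", "CA", "C", "O", "OXT"))
    scxyz <- tr$apply(txyz[sc, , drop = FALSE])
    scnames <- tpl$atom[sc]
    if (chi1 != 0 && aa != "PRO" && "CB" %in% scnames && sum(sc) > 1L) {
      cb <- scxyz[scnames == "CB", ]
      beyond <- scnames != "CB"
      scxyz[beyond, ] <- rotate_about_axis(
        scxyz[beyond, , drop = FALSE], bb[[2]]$CA, cb - bb[[2]]$CA, chi1)
    }
    for (k in seq_along(scnames)) {
      add(2, aa, scnames[k], tpl$element[sc][k], scxyz[k, ])
    }
    atoms <- do.call(rbind, rows)
  }
  atoms$serial <- seq_len(nrow(atoms))
  atoms$is_sidechain <- !(atoms$name %in% BACKBONE_ATOMS)
  atoms <- assign_radii(atoms, radii)
  new_structure_model(atoms, model_id = paste0("GXG-", aa))
}

#' Fully-exposed side-chain SASA reference (Gly-X-Gly)
#'
#' Returns the side-chain SASA of residue type X in an extended
#' Gly-X-Gly tripeptide — the "fully exposed" denominator used to form
#' fractional SASA, and the denatured-state SASA model. Values are read
#' from the table shipped with the package; see
#' [build_gxg_reference()] to regenerate it.
#'
#' @param aa Three-letter code, or `NULL` for the whole table.
#' @return SASA in Angstrom^2 (scalar), or a named vector for the full
#'   table. Glycine returns 0 (no side-chain heavy atoms).
#' @export
gxg_reference <- function(aa = NULL) {
  tab <- utils::read.csv(
    system.file("extdata", "gxg_reference.csv", package = "hrpfsasa"),
    stringsAsFactors = FALSE)
  ref <- stats::setNames(tab$gxg_sasa_A2, tab$resname)
  if (is.null(aa)) return(ref)
  aa <- toupper(aa)
  if (!all(aa %in% names(ref))) {
    stop("nonstandard amino acid: ", paste(setdiff(aa, names(ref)), collapse = ", "))
  }
  unname(ref[aa])
}

#' Regenerate the Gly-X-Gly reference table
#'
#' Rebuilds extended Gly-X-Gly tripeptides for the 20 standard amino
#' acids, sweeps the side chain through chi1 rotamers, and averages the
#' central residue's side-chain SASA. This is the generator for the
#' table returned by [gxg_reference()].
#'
#' @param probe_radius,n_points SASA engine settings.
#' @param chi1_step Rotamer sweep step in degrees (proline is rigid and
#'   is not swept).
#' @return Data frame with columns `resname`, `gxg_sasa_A2`.
#' @export
build_gxg_reference <- function(probe_radius = 1.4, n_points = 960,
                                chi1_step = 30) {
  vals <- vapply(AA3, function(aa) {
    sweep_angles <- if (aa %in% c("GLY", "ALA", "PRO")) 0 else
      seq(0, 360 - chi1_step, by = chi1_step)
    mean(vapply(sweep_angles, function(th) {
      m <- build_gxg_tripeptide(aa, chi1 = th)
      r <- residue_sidechain_sasa(m, probe_radius, n_points)
      r$mean_sasa[r$resseq == 2L]
    }, numeric(1)))
  }, numeric(1))
  data.frame(resname = AA3, gxg_sasa_A2 = unname(vals),
             stringsAsFactors = FALSE)
}
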