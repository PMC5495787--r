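BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Van der Waals radii used by the SASA engine
#'
#' Returns the element -> radius (Angstrom) lookup used to assign
#' per-atom radii. The default set follows the united-atom convention of
#' classical accessibility calculators (carbon radii inflated to absorb
#' unmodelled hydrogens). A custom table can be supplied as a CSV with
#' columns `element,radius`.
#'
#' @param path Optional path to a CSV radius table. `NULL` uses the
#'   table shipped with the package.
#' @return Named numeric vector of radii in Angstrom, including a
#'   `"default"` entry used (with a warning) for unlisted elements.
#' @export
vdw_radii <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.csv", package = "hrpfsasa")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "radius") %in% names(tab)), all(tab$radius > 0))
  stats::setNames(tab$radius, tab$element)
}

element_from_name <- function(name, record = "ATOM") {
  # PDB convention: columns 13-16; names starting with a digit or with
  # "H" in a protein ATOM record are hydrogens ("1HB2", "HD11", ...)
  nm <- gsub("[ 0-9']", "", name)
  first <- substr(nm, 1L, 1L)
  ifelse(first == "H" | first == "D", "H", first)
}

assign_radii <- function(atoms, radii = vdw_radii()) {
  idx <- match(atoms$element, names(radii))
  missing <- is.na(idx)
  if (any(missing)) {
    warning("unknown element(s) ", paste(unique(atoms$element[missing]), collapse = ", "),
            "; using default radius ", radii[["default"]])
    idx[missing] <- match("default", names(radii))
  }
  atoms$vdw_radius <- unname(radii[idx])
  atoms
}

new_structure_model <- function(atoms, model_id = "1") {
  stopifnot(nrow(atoms) >= 1L)
  key <- paste(atoms$chain, atoms$resseq, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate atom after altloc resolution: ", dup)
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  structure(list(model_id = as.character(model_id), atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$model_id, ":", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resseq))), "residues\n")
  invisible(x)
}

#' Parse PDB-format text into structure models
#'
#' Reads ATOM (and optionally selected HETATM) records. Each MODEL block
#' becomes one `StructureModel`; files without MODEL records yield a
#' single model. Hydrogens are dropped, alternate locations are resolved
#' to the highest-occupancy conformer (ties broken by altloc letter),
#' and HETATM records are ignored unless their residue name is listed in
#' `hetatm_retain` (e.g. `"HEM"`).
#'
#' @param text Character scalar (or vector of lines) of PDB-format text.
#' @param hetatm_retain Character vector of HETATM residue names to keep.
#' @param radii Named radius table from [vdw_radii()].
#' @return List of `StructureModel` objects.
#' @export
parse_pdb <- function(text, hetatm_retain = character(), radii = vdw_radii()) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  if (length(lines) == 0L) stop("empty PDB input")
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no ATOM records in PDB input")

  model_no <- cumsum(is_model)
  if (!any(is_model)) model_no[] <- 1L
  model_no[model_no == 0L] <- 1L

  at <- which(is_atom)
  parse_num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v)
    if (any(bad)) {
      stop("malformed ATOM record (bad ", what, ") at line ", ln[bad][1L])
    }
    v
  }
  ln <- lines[at]
  ln <- formatC(ln, width = 80, flag = "-")  # pad short lines
  atoms <- data.frame(
    record = substr(ln, 1, 6),
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = trimws(substr(ln, 13, 16)),
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resseq = parse_num(substr(ln, 23, 26), "residue number", at),
    x = parse_num(substr(ln, 31, 38), "x coordinate", at),
    y = parse_num(substr(ln, 39, 46), "y coordinate", at),
    z = parse_num(substr(ln, 47, 54), "z coordinate", at),
    occupancy = suppressWarnings(as.numeric(substr(ln, 55, 60))),
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  blank_el <- atoms$element == ""
  atoms$element[blank_el] <- element_from_name(atoms$name[blank_el])
  atoms$model <- model_no[at]

  atoms <- atoms[atoms$record == "ATOM  " | atoms$resname %in% hetatm_retain, , drop = FALSE]
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms left after filtering")

  # altloc resolution: highest occupancy, ties by altloc letter order
  ord <- order(atoms$model, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$model, atoms$chain, atoms$resseq, atoms$name, sep = "|")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms <- atoms[order(atoms$model, atoms$serial), , drop = FALSE]

  atoms$is_sidechain <- !(atoms$name %in% BACKBONE_ATOMS)
  atoms <- assign_radii(atoms, radii)
  atoms$record <- NULL
  atoms$altloc <- NULL

  lapply(split(atoms, atoms$model), function(a) {
    id <- as.character(a$model[1L])
    a$model <- NULL
    rownames(a) <- NULL
    new_structure_model(a, model_id = id)
  })
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB file.
#' @inheritParams parse_pdb
#' @return List of `StructureModel` objects (see [parse_pdb()]).
#' @export
read_pdb <- function(path, hetatm_retain = character(), radii = vdw_radii()) {
  if (!file.exists(path)) stop("cannot open PDB file: ", path)
  parse_pdb(readLines(path, warn = FALSE), hetatm_retain = hetatm_retain,
            radii = radii)
}

#' Bundle structure models into an ensemble
#'
#' @param models List of `StructureModel` objects sharing one residue
#'   roster.
#' @param weights Optional nonnegative per-model weights; normalized to
#'   sum to 1. `NULL` means equal weights.
#' @return An `Ensemble` object.
#' @export
ensemble <- function(models, weights = NULL) {
  stopifnot(length(models) >= 1L)
  roster <- residue_roster(models[[1L]])
  for (m in models[-1L]) {
    r <- residue_roster(m)
    if (!identical(r, roster)) {
      off <- c(setdiff(r, roster), setdiff(roster, r))
      stop("ensemble models disagree on residue roster: ", off[1L])
    }
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(models), all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  structure(list(models = models, weights = weights), class = "Ensemble")
}

residue_roster <- function(model) {
  a <- model$atoms
  unique(paste(a$chain, a$resseq, a$resname, sep = "|"))
}

#' Write a structure model as PDB text
#'
#' Minimal fixed-column writer for round-tripping synthetic structures.
#'
#' @param models A `StructureModel` or list of them (written as MODEL
#'   blocks when more than one).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "StructureModel")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    a <- models[[i]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial, formatC(a$name, width = 4), a$resname, a$chain, a$resseq,
      a$x, a$y, a$z, a$occupancy, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
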