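# Shared fixtures, built once per test run. The synthetic study uses
# the generator defaults throughout.

study_cache <- new.env(parent = emptyenv())

shared_study <- function() {
  if (is.null(study_cache$study)) {
    cfg <- simulation_config()
    structures <- make_structures(cfg)
    sasa <- ensemble_mean_sasa(structures$ensemble)
    study_cache$study <- list(cfg = cfg, structures = structures, sasa = sasa)
  }
  study_cache$study
}

residue_key <- function(d) paste(d$chain, d$resseq, d$resname, sep = "|")

# fixed-column PDB ATOM line builder for parser fixtures
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, altloc = " ", element = "", record = "ATOM") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resseq, x, y, z, occ, 0, element)
}

# minimal single-chain test protein: ALA-GLY-TRP on a line
toy_tripeptide <- function() {
  lines <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(3, "C", "ALA", "A", 1, 2.5, 1, 0),
    pdb_line(4, "O", "ALA", "A", 1, 2.5, 2.2, 0),
    pdb_line(5, "CB", "ALA", "A", 1, 1.5, -1, 1.2),
    pdb_line(6, "N", "GLY", "A", 2, 3.8, 0.8, 0),
    pdb_line(7, "CA", "GLY", "A", 2, 5.0, 0, 0),
    pdb_line(8, "C", "GLY", "A", 2, 6.2, 1, 0),
    pdb_line(9, "O", "GLY", "A", 2, 6.2, 2.2, 0),
    pdb_line(10, "N", "TRP", "A", 3, 7.5, 0.8, 0),
    pdb_line(11, "CA", "TRP", "A", 3, 8.7, 0, 0),
    pdb_line(12, "C", "TRP", "A", 3, 9.9, 1, 0),
    pdb_line(13, "O", "TRP", "A", 3, 9.9, 2.2, 0),
    pdb_line(14, "CB", "TRP", "A", 3, 8.7, -1, 1.2),
    pdb_line(15, "CG", "TRP", "A", 3, 8.7, -2, 2.4)
  )
  parse_pdb(lines)[[1]]
}

# single free atom as a StructureModel-like atom table
lone_atom <- function(r = 1.7) {
  data.frame(x = 0, y = 0, z = 0, vdw_radius = r)
}
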