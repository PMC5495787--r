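kabsch_rotation <- function(a, b) {
  # rotation R minimizing ||a %*% R - b||_F for centered coordinate sets
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

superpose <- function(moving, fixed) {
  # least-squares rigid transform of `moving` (n x 3) onto `fixed`
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  r <- kabsch_rotation(sweep(moving, 2L, cm), sweep(fixed, 2L, cf))
  list(rotation = r, center_moving = cm, center_fixed = cf,
       apply = function(x) sweep(sweep(x, 2L, cm) %*% r, 2L, cf, "+"))
}

atom_xyz <- function(model, selection = c("backbone", "all")) {
  selection <- match.arg(selection)
  a <- model$atoms
  if (selection == "backbone") a <- a[a$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  key <- paste(a$chain, a$resseq, a$name, sep = "|")
  list(xyz = cbind(a$x, a$y, a$z), key = key)
}

#' Optimal-superposition RMSD between two structures
#'
#' Pairs atoms by (chain, residue number, atom name), finds the
#' least-squares rigid superposition (Kabsch algorithm) and returns the
#' coordinate RMSD in Angstrom. Invariant to rigid-body transforms of
#' either structure.
#'
#' @param model_a,model_b `StructureModel` objects.
#' @param selection `"backbone"` (N, CA, C, O) or `"all"` heavy atoms.
#' @return RMSD in Angstrom (>= 0).
#' @export
kabsch_rmsd <- function(model_a, model_b, selection = c("backbone", "all")) {
  sa <- atom_xyz(model_a, selection)
  sb <- atom_xyz(model_b, selection)
  common <- intersect(sa$key, sb$key)
  if (length(common) < 3L) stop("fewer than 3 paired atoms after selection")
  if (length(common) < length(sa$key) || length(common) < length(sb$key)) {
    if (length(sa$key) != length(sb$key) ||
        !setequal(sa$key, sb$key)) {
      warning("atom selections differ; using ", length(common), " common atoms")
    }
  }
  a <- sa$xyz[match(common, sa$key), , drop = FALSE]
  b <- sb$xyz[match(common, sb$key), , drop = FALSE]
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  r <- kabsch_rotation(a, b)
  sqrt(mean(rowSums((a %*% r - b)^2)))
}
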