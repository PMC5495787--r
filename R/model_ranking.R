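#' Build a per-residue SASA vector
#'
#' A `SASAVector` is a residue-keyed vector of absolute side-chain SASA
#' values used as either the candidate or the reference side of the
#' SASA-RMSD score. HRPF-derived references contain only residues with
#' experimental values; unmeasured residues are never imputed.
#'
#' @param data `ResidueSASA` table, a prediction table with
#'   `predicted_sasa`, or a data frame with a `sasa` column; must carry
#'   `chain`, `resseq`, `resname`.
#' @param source One of `"crystal"`, `"ensemble"`, `"hrpf"`.
#' @return A `SASAVector`: named numeric vector (names
#'   `chain|resseq|resname`) with a `source` attribute.
#' @export
sasa_vector <- function(data, source = c("crystal", "ensemble", "hrpf")) {
  source <- match.arg(source)
  vals <- data$mean_sasa %||% data$predicted_sasa %||% data$sasa
  if (is.null(vals)) stop("no SASA column found (mean_sasa/predicted_sasa/sasa)")
  stopifnot(all(vals >= 0))
  key <- paste(data$chain, data$resseq, data$resname, sep = "|")
  if (anyDuplicated(key)) stop("duplicate residue keys in SASA vector")
  structure(stats::setNames(as.numeric(vals), key),
            source = source, class = "SASAVector")
}

#' SASA root-mean-square deviation between two residue vectors
#'
#' The model-selection score: sqrt of the mean squared difference of
#' per-residue SASA between a candidate and a reference, over the n
#' residues present in both vectors.
#'
#' @param current,ref `SASAVector`s (see [sasa_vector()]).
#' @return List: `rmsd_sasa` (Angstrom^2), `n` residues compared.
#' @export
rmsd_sasa <- function(current, ref) {
  common <- intersect(names(current), names(ref))
  if (length(common) == 0L) stop("no residues in common between SASA vectors")
  d <- unclass(current)[common] - unclass(ref)[common]
  list(rmsd_sasa = sqrt(mean(d^2)), n = length(common))
}

#' Score and rank candidate structural models against a reference
#'
#' Converts each candidate structure to a per-residue side-chain SASA
#' vector (single-conformer: candidates are static structures) and
#' ranks candidates by ascending SASA RMSD against the reference,
#' which may be crystal-derived or HRPF-derived. Ties are broken by
#' model id; unscoreable candidates are skipped and logged.
#'
#' @param candidates Named list of `StructureModel`s and/or
#'   `SASAVector`s.
#' @param ref Reference `SASAVector`.
#' @param native Optional native `StructureModel`; when given, each
#'   structural candidate also gets a backbone RMSD (Angstrom).
#' @param probe_radius,n_points SASA engine settings for structural
#'   candidates.
#' @return Data frame sorted by `rmsd_sasa`: model_id, rmsd_sasa_A2, n,
#'   backbone_rmsd_A (NA for vector candidates or without `native`);
#'   skipped candidates in `attr(, "skipped")`.
#' @export
rank_models <- function(candidates, ref, native = NULL,
                        probe_radius = 1.4, n_points = 960) {
  ids <- vapply(seq_along(candidates), function(i) {
    if (inherits(candidates[[i]], "StructureModel")) candidates[[i]]$model_id
    else as.character(i)
  }, character(1))
  if (!is.null(names(candidates))) {
    named <- names(candidates) != ""
    ids[named] <- names(candidates)[named]
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  rows <- list()
  skipped <- character()
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    id <- ids[i]
    vec <- tryCatch({
      if (inherits(cand, "SASAVector")) cand
      else if (inherits(cand, "StructureModel")) {
        sasa_vector(residue_sidechain_sasa(cand, probe_radius, n_points),
                    source = "crystal")
      } else stop("unsupported candidate type")
    }, error = function(e) e)
    if (inherits(vec, "error")) {
      skipped <- c(skipped, paste0(id, ": ", conditionMessage(vec)))
      next
    }
    sc <- tryCatch(rmsd_sasa(vec, ref), error = function(e) e)
    if (inherits(sc, "error")) {
      skipped <- c(skipped, paste0(id, ": ", conditionMessage(sc)))
      next
    }
    bb <- NA_real_
    if (!is.null(native) && inherits(cand, "StructureModel")) {
      bb <- kabsch_rmsd(cand, native, selection = "backbone")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = id, rmsd_sasa_A2 = sc$rmsd_sasa, n = sc$n,
      backbone_rmsd_A = bb, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no scoreable candidates")
  out <- do.call(rbind, rows)
  out <- out[order(out$rmsd_sasa_A2, out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Good/bad model discrimination report
#'
#' Classifies scored models by backbone RMSD against the native
#' structure — good (< 3 Angstrom), indeterminate (3-4), bad (> 4) —
#' and reports whether the SASA-RMSD score separates the classes:
#' `separated` is `TRUE` when every bad model scores strictly higher
#' than every good model.
#'
#' @param scores Data frame from [rank_models()] with non-missing
#'   `backbone_rmsd_A`.
#' @return List: `scores` (with a `class` column), `separated`,
#'   `n_good`, `n_bad`, `n_indeterminate`.
#' @export
discrimination_report <- function(scores) {
  bb <- scores$backbone_rmsd_A
  if (any(is.na(bb))) stop("backbone RMSD required for every model")
  cls <- ifelse(bb < 3, "good", ifelse(bb > 4, "bad", "indeterminate"))
  scores$class <- cls
  good <- scores$rmsd_sasa_A2[cls == "good"]
  bad <- scores$rmsd_sasa_A2[cls == "bad"]
  separated <- if (length(good) == 0L || length(bad) == 0L) TRUE else
    min(bad) > max(good)
  list(scores = scores, separated = separated,
       n_good = sum(cls == "good"), n_bad = sum(cls == "bad"),
       n_indeterminate = sum(cls == "indeterminate"))
}

#' Write ranked model scores as TSV
#'
#' @param scores Output of [rank_models()] (optionally with `class`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
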