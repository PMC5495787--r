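#' Peptide-level oxidation fraction from species intensities
#'
#' The oxidized fraction of a peptide is the summed intensity of all
#' oxidized species (one or more +O additions) over the summed
#' intensity of all observed species of that peptide. Invariant to
#' rescaling all intensities by a common factor.
#'
#' @param species Data frame with columns `ox_state` (integer number of
#'   oxygen additions, >= 0) and `intensity` (>= 0).
#' @return Fraction in \[0, 1\].
#' @export
peptide_oxidation_fraction <- function(species) {
  stopifnot(nrow(species) >= 1L, all(species$intensity >= 0),
            all(species$ox_state >= 0))
  tot <- sum(species$intensity)
  if (tot <= 0) stop("all species intensities are zero")
  sum(species$intensity[species$ox_state >= 1L]) / tot
}

#' Apportion peptide oxidation to residues from ETD fragment ions
#'
#' For a c-ion (N-terminal) series, the oxidized intensity fraction at
#' a cleavage, f(p) = ox / (ox + unox), estimates the share of the
#' peptide's oxidation located N-terminal to that cleavage. The
#' difference of f between consecutive observed cleavages is the share
#' carried by the residue segment between them (boundaries f(0) = 0 and
#' f(L) = 1); segments spanning several residues are reported as
#' unresolved ranges rather than split arbitrarily. Shares are clipped
#' at zero (fragment noise can make f locally decreasing) and rescaled
#' to sum to the peptide-level fraction. z-ion (C-terminal) series are
#' handled by mirroring positions.
#'
#' @param peptide_fraction Peptide-level oxidation fraction from
#'   [peptide_oxidation_fraction()].
#' @param fragments Data frame with columns `series` ("c" or "z"),
#'   `position` (cleavage index, 1-based from the series terminus),
#'   `unox`, `ox` (intensities).
#' @param peptide_length Number of residues in the peptide.
#' @return Data frame with columns `start`, `end` (1-based residue
#'   range within the peptide; single-residue ranges are resolved
#'   sites), `fraction`.
#' @export
residue_oxidation_fraction <- function(peptide_fraction, fragments,
                                       peptide_length) {
  stopifnot(peptide_fraction >= 0, peptide_fraction <= 1,
            all(fragments$unox >= 0), all(fragments$ox >= 0))
  L <- as.integer(peptide_length)
  fr <- fragments
  # express every cleavage as "after residue p", N-terminal convention
  pos <- ifelse(fr$series == "z", L - fr$position, fr$position)
  f <- fr$ox / (fr$ox + fr$unox)
  # z-series f measures the C-terminal share; convert to cumulative-N
  f <- ifelse(fr$series == "z", 1 - f, f)
  keep <- is.finite(f) & pos >= 1L & pos <= L - 1L
  pos <- pos[keep]; f <- f[keep]
  o <- order(pos)
  pos <- pos[o]; f <- f[o]
  if (anyDuplicated(pos)) {
    f <- tapply(f, pos, mean)
    pos <- sort(unique(pos))
  }
  cuts <- c(0L, pos, L)
  cum <- c(0, as.numeric(f), 1)
  share <- diff(cum)
  neg <- share < 0
  if (any(neg)) {
    warning("negative fragment-difference share(s) clipped to 0")
    share[neg] <- 0
  }
  if (sum(share) > 0) share <- share / sum(share)
  out <- data.frame(start = cuts[-length(cuts)] + 1L,
                    end = cuts[-1L],
                    fraction = share * peptide_fraction)
  out
}
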