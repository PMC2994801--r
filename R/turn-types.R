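#' The nine beta-turn types
#'
#' Eight dihedral-defined types plus the catch-all type IV, in the fixed
#' precedence order used to break ties when several definitions match.
#' @export
TURN_TYPES <- c("I", "I'", "II", "II'", "VIII", "VIa1", "VIa2", "VIb", "IV")

#' Canonical dihedral-angle table for the defined beta-turn types
#'
#' One row per defined type (all except the catch-all IV) with the
#' canonical phi/psi values, in degrees, of the two central residues i+1
#' and i+2 of the four-residue turn, plus whether a cis-proline is required
#' at position i+2. Values are the standard Hutchinson--Thornton /
#' PROMOTIF-convention centers; pass a modified copy to the classifier to
#' use a different convention.
#'
#' @param vib_requires_cis Require cis-proline for type VIb as well
#'   (default `FALSE`; only VIa1 and VIa2 carry the requirement).
#' @return Tibble with columns `type`, `phi1`, `psi1`, `phi2`, `psi2`,
#'   `cis_pro`.
#' @export
canonical_turn_table <- function(vib_requires_cis = FALSE) {
  tibble::tibble(
    type = c("I", "I'", "II", "II'", "VIII", "VIa1", "VIa2", "VIb"),
    phi1 = c(-60,  60, -60,  60,  -60,  -60, -120, -135),
    psi1 = c(-30,  30, 120, -120, -30,  120,  120,  135),
    phi2 = c(-90,  90,  80, -80, -120,  -90,  -60,  -75),
    psi2 = c(  0,   0,   0,   0,  120,    0,    0,  160),
    cis_pro = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                vib_requires_cis)
  )
}

#' Classify a candidate beta-turn window into one of the nine types
#'
#' The four central dihedrals (phi/psi of residues i+1 and i+2) are compared
#' with each canonical type definition. A defined type matches when every
#' deviation is at most `tol_one` degrees, at most one deviation exceeds
#' `tol`, and the cis-proline requirement (where flagged) is satisfied.
#' Deviations are measured on the circle, so -179 and +179 are 2 degrees
#' apart. If no defined type matches, the catch-all type IV is returned;
#' when several match, ties are broken by the fixed precedence order of
#' `table` rows (or, with `best_fit = TRUE`, by smallest total deviation).
#'
#' @param angles Numeric length-4 vector `(phi1, psi1, phi2, psi2)` in
#'   degrees, or a 4-column matrix of such rows.
#' @param cis_pro_at_3 Logical (recycled over rows): is residue i+2 a
#'   proline preceded by a cis peptide bond?
#' @param table Canonical table from [canonical_turn_table()].
#' @param tol Base tolerance in degrees (default 30).
#' @param tol_one Relaxed tolerance allowed for a single angle (default 40).
#' @param best_fit Break multi-type matches by smallest total circular
#'   deviation instead of precedence.
#' @return Character vector of types (one per row).
#' @export
classify_turn_type <- function(angles, cis_pro_at_3 = FALSE,
                               table = canonical_turn_table(),
                               tol = 30, tol_one = 40, best_fit = FALSE) {
  if (is.null(dim(angles))) angles <- matrix(angles, ncol = 4, byrow = TRUE)
  if (ncol(angles) != 4) stop("angles must have four columns")
  if (any(is.na(angles))) stop("classify_turn_type: undefined dihedral angle")
  n <- nrow(angles)
  cis_pro_at_3 <- rep_len(cis_pro_at_3, n)
  nt <- nrow(table)
  dev_tot <- matrix(Inf, n, nt)
  match_m <- matrix(FALSE, n, nt)
  for (t in seq_len(nt)) {
    d <- cbind(angle_dev(angles[, 1], table$phi1[t]),
               angle_dev(angles[, 2], table$psi1[t]),
               angle_dev(angles[, 3], table$phi2[t]),
               angle_dev(angles[, 4], table$psi2[t]))
    ok <- rowSums(d > tol) <= 1 & rowSums(d > tol_one) == 0
    if (table$cis_pro[t]) ok <- ok & cis_pro_at_3
    match_m[, t] <- ok
    dev_tot[, t] <- rowSums(d)
  }
  out <- rep("IV", n)
  any_match <- rowSums(match_m) > 0
  if (any(any_match)) {
    pick <- if (best_fit) {
      dev_tot[!match_m] <- Inf
      max.col(-dev_tot, ties.method = "first")
    } else {
      max.col(match_m, ties.method = "first")
    }
    out[any_match] <- table$type[pick[any_match]]
  }
  out
}
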