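# A beta-turn closes when CA(i) and CA(i+3) come within this distance.
TURN_CA_CUTOFF <- 7

# Build the per-residue annotation implied by a set of turn instances.
.annotation_from_instances <- function(chain, instances) {
  n <- nrow(chain)
  types <- vector("list", n)
  positions <- vector("list", n)
  for (i in seq_len(n)) {
    types[[i]] <- character(0)
    positions[[i]] <- integer(0)
  }
  if (nrow(instances) > 0) {
    for (k in seq_len(nrow(instances))) {
      s <- instances$start[k]
      for (p in 1:4) {
        r <- s + p - 1
        types[[r]] <- union(types[[r]], instances$type[k])
        positions[[r]] <- sort(union(positions[[r]], p))
      }
    }
  }
  cid <- chain_id(chain)
  seqidx <- chain$seq_index
  aa1 <- aa_one(chain$residue_name)
  out <- tibble::tibble(
    chain = cid,
    seq_index = seqidx,
    aa = aa1,
    in_turn = lengths(positions) > 0,
    types = types,
    positions = positions
  )
  attr(out, "instances") <- tibble::as_tibble(instances)
  class(out) <- c("bturn_annotation", class(tibble::tibble()))
  out
}

#' Assign beta-turns and their types along a backbone chain
#'
#' Every four-residue window i..i+3 whose CA(i)-CA(i+3) distance is below 7
#' Angstrom, whose two central residues are not helical, and whose central
#' phi/psi torsions are defined becomes a turn instance; its type comes from
#' [classify_turn_type()]. The cis-proline flag passed to the classifier is
#' true only when residue i+2 is a proline whose preceding peptide bond is
#' cis.
#'
#' @param chain A `bturn_chain`.
#' @param helix_mask Logical per-residue helix flags (default all `FALSE`;
#'   supply flags from any secondary-structure source to exclude helical
#'   central residues).
#' @param table Canonical angle table, see [canonical_turn_table()].
#' @param tol,tol_one,best_fit Classifier tolerances, see
#'   [classify_turn_type()].
#' @param ca_cutoff CA(i)-CA(i+3) closure cutoff in Angstrom.
#' @param cis_cutoff Cis-peptide omega cutoff in degrees.
#' @return A `bturn_annotation`: per-residue tibble with columns `chain`,
#'   `seq_index`, `aa`, `in_turn`, and list-columns `types` and
#'   `positions`; the turn instances are in `attr(, "instances")` (see
#'   [turn_instances()]).
#' @export
assign_turns <- function(chain, helix_mask = NULL,
                         table = canonical_turn_table(),
                         tol = 30, tol_one = 40, best_fit = FALSE,
                         ca_cutoff = TURN_CA_CUTOFF, cis_cutoff = 30) {
  n <- nrow(chain)
  if (is.null(helix_mask)) helix_mask <- rep(FALSE, n)
  stopifnot(length(helix_mask) == n)
  empty <- tibble::tibble(start = integer(0), type = character(0))
  if (n < 4) return(.annotation_from_instances(chain, empty))

  tor <- compute_torsions(chain)
  ca <- .coord_matrix(chain, "ca")
  starts <- integer(0)
  types <- character(0)
  for (i in seq_len(n - 3)) {
    if (!all(chain$complete[i:(i + 3)])) next
    if (helix_mask[i + 1] || helix_mask[i + 2]) next
    ang <- c(tor$phi[i + 1], tor$psi[i + 1], tor$phi[i + 2], tor$psi[i + 2])
    if (any(is.na(ang))) next
    if (sqrt(sum((ca[i, ] - ca[i + 3, ])^2)) >= ca_cutoff) next
    cis3 <- chain$residue_name[i + 2] == "PRO" &&
      !is.na(tor$omega[i + 2]) &&
      abs(wrap_angle(tor$omega[i + 2])) < cis_cutoff
    starts <- c(starts, i)
    types <- c(types, classify_turn_type(ang, cis_pro_at_3 = cis3,
                                         table = table, tol = tol,
                                         tol_one = tol_one,
                                         best_fit = best_fit))
  }
  .annotation_from_instances(chain, tibble::tibble(start = starts,
                                                   type = types))
}

#' Turn instances recorded in an annotation
#' @param annotation A `bturn_annotation`.
#' @return Tibble with columns `start`, `type` plus the four residue
#'   numbers.
#' @export
turn_instances <- function(annotation) {
  inst <- attr(annotation, "instances")
  if (nrow(inst) == 0) {
    return(tibble::tibble(start = integer(0), type = character(0),
                          res1 = integer(0), res2 = integer(0),
                          res3 = integer(0), res4 = integer(0)))
  }
  dplyr::mutate(inst,
                res1 = annotation$seq_index[.data$start],
                res2 = annotation$seq_index[.data$start + 1],
                res3 = annotation$seq_index[.data$start + 2],
                res4 = annotation$seq_index[.data$start + 3])
}

#' Per-residue turn-position sets
#'
#' Residue r belongs to position p when some turn instance starting at s
#' covers it with r - s + 1 = p; overlapping instances give multi-position
#' sets (a residue can be both position 1 of one turn and position 2 of
#' another).
#'
#' @param annotation A `bturn_annotation`.
#' @return Tibble with `seq_index` and list-column `positions`.
#' @export
position_labels <- function(annotation) {
  tibble::tibble(seq_index = annotation$seq_index,
                 positions = annotation$positions)
}

#' Binary label tracks for network training
#'
#' Expands an annotation into the residue-level label tracks the
#' predictors are trained on: the general turn/not-turn track, one track
#' per turn type (positive only for residues covered by an instance of
#' that type), and one per turn position 1..4.
#'
#' @param annotation A `bturn_annotation`.
#' @return List with `general` (logical), `type` (named list of 9
#'   logicals) and `position` (list of 4 logicals).
#' @export
label_sets <- function(annotation) {
  n <- nrow(annotation)
  type_tracks <- lapply(TURN_TYPES, function(tt) {
    vapply(annotation$types, function(x) tt %in% x, logical(1))
  })
  names(type_tracks) <- TURN_TYPES
  pos_tracks <- lapply(1:4, function(p) {
    vapply(annotation$positions, function(x) p %in% x, logical(1))
  })
  list(general = annotation$in_turn, type = type_tracks,
       position = pos_tracks)
}

#' Flat tabular form of an annotation
#'
#' One row per residue with comma-joined type memberships and position
#' sets, suitable for TSV export.
#'
#' @param annotation A `bturn_annotation`.
#' @return Plain tibble with character `types` and `positions` columns.
#' @export
annotation_table <- function(annotation) {
  tibble::tibble(
    chain = annotation$chain,
    seq_index = annotation$seq_index,
    aa = annotation$aa,
    in_turn = annotation$in_turn,
    types = vapply(annotation$types, paste, character(1), collapse = ","),
    positions = vapply(annotation$positions, paste, character(1),
                       collapse = ",")
  )
}
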