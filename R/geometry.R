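#' @useDynLib betaturn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# Backbone atoms required for a residue to take part in torsion / turn
# computation.
BACKBONE_ATOMS <- c("N", "CA", "C")

#' Construct a backbone chain object
#'
#' A `bturn_chain` holds the ordered backbone of one protein chain: one row
#' per residue with the N, CA and C coordinates in Angstrom. Residues that
#' are missing any of the three backbone atoms are kept but flagged
#' incomplete; torsions are never computed across them and turns may not
#' span them.
#'
#' @param residues Tibble with columns `seq_index` (strictly increasing
#'   integers), `residue_name` (3-letter code), and the nine coordinate
#'   columns `n_x,n_y,n_z,ca_x,ca_y,ca_z,c_x,c_y,c_z` (`NA` allowed only on
#'   incomplete residues), plus logical `complete`.
#' @param chain_id Single chain identifier.
#' @return A `bturn_chain` (tibble subclass).
#' @export
new_backbone_chain <- function(residues, chain_id = "A") {
  stopifnot(is.data.frame(residues))
  need <- c("seq_index", "residue_name",
            "n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")
  miss <- setdiff(need, names(residues))
  if (length(miss) > 0) {
    stop("backbone chain is missing columns: ", paste(miss, collapse = ", "))
  }
  res <- tibble::as_tibble(residues)
  if (!"complete" %in% names(res)) {
    coord <- as.matrix(res[, need[-(1:2)]])
    res$complete <- stats::complete.cases(coord) & apply(is.finite(coord), 1, all)
  }
  if (is.unsorted(res$seq_index, strictly = TRUE)) {
    stop("seq_index must be strictly increasing")
  }
  structure(res, chain_id = chain_id,
            class = c("bturn_chain", class(tibble::tibble())))
}

#' @export
print.bturn_chain <- function(x, ...) {
  cat(sprintf("<bturn_chain %s: %d residues, %d complete>\n",
              chain_id(x), nrow(x), sum(x$complete)))
  NextMethod()
}

#' Chain identifier of a backbone chain
#' @param chain A `bturn_chain`.
#' @return Single character chain id.
#' @export
chain_id <- function(chain) attr(chain, "chain_id")

#' Read a protein backbone from PDB-format text
#'
#' Parses ATOM records (via [bio3d::read.pdb()]) and extracts the N, CA and
#' C atoms of one chain in author order. Alternate locations are resolved to
#' the highest-occupancy altloc (first on ties); residues missing any
#' backbone atom are flagged incomplete.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines.
#' @param chain_id One-letter chain identifier; `NULL` selects the first
#'   chain in the file.
#' @return A [new_backbone_chain()] object.
#' @export
read_backbone <- function(pdb, chain_id = "A") {
  if (is.null(chain_id)) chain_id <- NA_character_
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || grepl("^ATOM", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], path)
  }
  parsed <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                             rm.alt = FALSE))
  at <- tibble::as_tibble(parsed$atom)
  at <- dplyr::filter(at, .data$type == "ATOM")
  chains <- unique(at$chain)
  if (is.na(chain_id)) chain_id <- chains[1]
  if (!chain_id %in% chains) {
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain_id, paste(chains, collapse = ", ")))
  }
  at <- dplyr::filter(at, .data$chain == chain_id,
                      .data$elety %in% BACKBONE_ATOMS)
  # altloc: keep highest occupancy, then first record
  at$o[is.na(at$o)] <- 1
  at <- at |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  res <- at |>
    dplyr::group_by(.data$resno, .data$insert) |>
    dplyr::summarise(
      residue_name = .data$resid[1],
      .first = min(.data$.ord),
      n_x = .atom_coord(.data$elety, .data$x, "N"),
      n_y = .atom_coord(.data$elety, .data$y, "N"),
      n_z = .atom_coord(.data$elety, .data$z, "N"),
      ca_x = .atom_coord(.data$elety, .data$x, "CA"),
      ca_y = .atom_coord(.data$elety, .data$y, "CA"),
      ca_z = .atom_coord(.data$elety, .data$z, "CA"),
      c_x = .atom_coord(.data$elety, .data$x, "C"),
      c_y = .atom_coord(.data$elety, .data$y, "C"),
      c_z = .atom_coord(.data$elety, .data$z, "C"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.first) |>
    dplyr::mutate(seq_index = dplyr::row_number()) |>
    dplyr::select(-".first", -"resno", -"insert") |>
    dplyr::relocate("seq_index", "residue_name")
  out <- new_backbone_chain(res, chain_id = chain_id)
  if (sum(out$complete) == 0) {
    stop(sprintf("chain '%s' has no residue with complete N/CA/C backbone",
                 chain_id))
  }
  out
}

.atom_coord <- function(elety, v, name) {
  i <- which(elety == name)
  if (length(i) == 0) NA_real_ else v[i[1]]
}

# dihedral angle (degrees, IUPAC sign, in (-180, 180]) for points given as
# rows of 3-column matrices; vectorized over rows
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / sqrt(rowSums(b2 * b2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(-y, x) * 180 / pi
  # convention: angles live in (-180, 180]
  ifelse(ang <= -180, ang + 360, ang)
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.coord_matrix <- function(chain, atom) {
  cols <- paste0(tolower(atom), c("_x", "_y", "_z"))
  m <- as.matrix(chain[, cols])
  dimnames(m) <- NULL
  m
}

#' Backbone torsion angles of a chain
#'
#' Computes phi, psi and omega for every residue, in degrees with the IUPAC
#' sign convention, in the interval (-180, 180]. `phi(i)` uses
#' C(i-1),N(i),CA(i),C(i); `psi(i)` uses N(i),CA(i),C(i),N(i+1); `omega(i)`
#' (the peptide bond preceding residue i) uses CA(i-1),C(i-1),N(i),CA(i).
#' Angles are `NA` at chain termini and across incomplete residues.
#'
#' @param chain A `bturn_chain`.
#' @return Tibble with columns `seq_index`, `phi`, `psi`, `omega`.
#' @export
compute_torsions <- function(chain) {
  n <- nrow(chain)
  N <- .coord_matrix(chain, "n")
  CA <- .coord_matrix(chain, "ca")
  C <- .coord_matrix(chain, "c")
  phi <- psi <- omega <- rep(NA_real_, n)
  ok <- chain$complete
  if (n >= 2) {
    prev_ok <- c(FALSE, ok[-n])
    i <- which(ok & prev_ok)          # residues with a complete predecessor
    if (length(i) > 0) {
      phi[i] <- dihedral_deg(C[i - 1, , drop = FALSE], N[i, , drop = FALSE],
                             CA[i, , drop = FALSE], C[i, , drop = FALSE])
      omega[i] <- dihedral_deg(CA[i - 1, , drop = FALSE], C[i - 1, , drop = FALSE],
                               N[i, , drop = FALSE], CA[i, , drop = FALSE])
    }
    next_ok <- c(ok[-1], FALSE)
    j <- which(ok & next_ok)          # residues with a complete successor
    if (length(j) > 0) {
      psi[j] <- dihedral_deg(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                             C[j, , drop = FALSE], N[j + 1, , drop = FALSE])
    }
  }
  tibble::tibble(seq_index = chain$seq_index, phi = phi, psi = psi,
                 omega = omega)
}

#' C-alpha distance between two residues
#'
#' @param chain A `bturn_chain`.
#' @param i,j Row positions (1-based) of the two residues.
#' @return Euclidean CA(i)-CA(j) distance in Angstrom.
#' @export
ca_distance <- function(chain, i, j) {
  if (!chain$complete[i] || !chain$complete[j]) {
    stop("ca_distance requires complete residues at both positions")
  }
  ca <- .coord_matrix(chain, "ca")
  sqrt(sum((ca[i, ] - ca[j, ])^2))
}

#' Is a peptide bond cis?
#'
#' A peptide bond is called cis when its omega torsion is within
#' `cis_cutoff` of 0 degrees; the usual trans state is near 180.
#'
#' @param omega Omega torsion(s) in degrees.
#' @param cis_cutoff Cutoff in degrees (default 30).
#' @return Logical vector.
#' @export
is_cis_peptide <- function(omega, cis_cutoff = 30) {
  if (any(is.na(omega))) stop("is_cis_peptide: omega is undefined (NA)")
  abs(wrap_angle(omega)) < cis_cutoff
}

#' Wrap angles into (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

# absolute circular difference in degrees, in [0, 180]
angle_dev <- function(a, b) abs(wrap_angle(a - b))
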