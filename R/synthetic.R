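# Standard backbone bond lengths (Angstrom) and angles (degrees). Turn
# assignment depends only on the torsions and CA distances these produce,
# so any self-consistent set works; literature values are used.
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

# Extended-strand backbone used for flanking (non-turn) regions.
EXTENDED_PHI <- -120
EXTENDED_PSI <- 130

# Residues over-represented in beta-turns; used by the sequence and profile
# generators.
TURN_FAVORED_AA <- c("G", "D", "S", "P", "N")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' One-letter to three-letter amino-acid codes and back
#' @param x Character vector of codes.
#' @return Converted codes (`"UNK"`/`"X"` for unknowns).
#' @export
aa_three <- function(x) {
  out <- AA3[match(toupper(x), AA1)]
  out[is.na(out)] <- "UNK"
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  out[is.na(out)] <- "X"
  out
}

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D bond
# angle (degrees) and the A-B-C-D torsion (degrees). Sequential natural
# extension reference frame.
.place_atom <- function(A, B, C, len, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + len * (-cos(th) * bc + sin(th) * (cos(chi) * m + sin(chi) * n))
}

#' Build a backbone chain from torsion angles
#'
#' Places N/CA/C atoms sequentially from internal coordinates using
#' standard bond lengths and angles. `phi[1]` and `omega[1]` have no
#' geometric meaning (no preceding residue) and are ignored, as is
#' `psi[n]`. Recomputing torsions on the result reproduces the inputs to
#' well below 1e-4 degrees.
#'
#' @param torsions Data frame with columns `phi`, `psi` and optionally
#'   `omega` (default 180, i.e. trans) -- one row per residue, degrees.
#' @param residue_names Three-letter residue names (recycled; default ALA).
#' @param chain_id Chain identifier for the result.
#' @return A [new_backbone_chain()] object.
#' @export
build_backbone_from_torsions <- function(torsions, residue_names = "ALA",
                                         chain_id = "A") {
  torsions <- tibble::as_tibble(torsions)
  n <- nrow(torsions)
  if (n < 2) stop("need at least two residues of torsions")
  if (!"omega" %in% names(torsions)) torsions$omega <- 180
  torsions$omega[is.na(torsions$omega)] <- 180
  phi <- torsions$phi
  psi <- torsions$psi
  omega <- torsions$omega
  residue_names <- rep_len(residue_names, n)

  xyz <- matrix(NA_real_, 3 * n, 3)   # rows: N1, CA1, C1, N2, ...
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  xyz[3, ] <- xyz[2, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    Np <- xyz[3 * (i - 2) + 1, ]
    CAp <- xyz[3 * (i - 2) + 2, ]
    Cp <- xyz[3 * (i - 2) + 3, ]
    Ni <- .place_atom(Np, CAp, Cp, BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CAi <- .place_atom(CAp, Cp, Ni, BOND_N_CA, ANGLE_C_N_CA, omega[i])
    Ci <- .place_atom(Cp, Ni, CAi, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    xyz[3 * (i - 1) + 1, ] <- Ni
    xyz[3 * (i - 1) + 2, ] <- CAi
    xyz[3 * (i - 1) + 3, ] <- Ci
  }
  idx <- seq_len(n)
  new_backbone_chain(tibble::tibble(
    seq_index = idx,
    residue_name = residue_names,
    n_x = xyz[3 * (idx - 1) + 1, 1], n_y = xyz[3 * (idx - 1) + 1, 2],
    n_z = xyz[3 * (idx - 1) + 1, 3],
    ca_x = xyz[3 * (idx - 1) + 2, 1], ca_y = xyz[3 * (idx - 1) + 2, 2],
    ca_z = xyz[3 * (idx - 1) + 2, 3],
    c_x = xyz[3 * (idx - 1) + 3, 1], c_y = xyz[3 * (idx - 1) + 3, 2],
    c_z = xyz[3 * (idx - 1) + 3, 3]
  ), chain_id = chain_id)
}

# Background amino-acid distribution (loosely globular-protein-like) and the
# turn-enriched distribution used for planted turn residues.
.aa_background <- function() {
  p <- rep(1, 20)
  names(p) <- AA1
  p[c("A", "L", "G", "S", "V", "E", "K")] <- 1.6
  p / sum(p)
}

.aa_turnlike <- function(strength = 3) {
  p <- .aa_background()
  p[TURN_FAVORED_AA] <- p[TURN_FAVORED_AA] * strength
  p / sum(p)
}

#' Fixture specification for the synthetic generator
#'
#' Bundles the knobs of the synthetic study set: number of chains, length
#' range, planted turns per chain, the profile effect size `delta` (mean
#' log-odds shift added to turn-favoring columns at turn residues), the
#' profile noise `sigma`, the secondary-structure/RSA effects, and the
#' seed. Defaults give a learnable but non-trivial set with roughly a
#' quarter of residues inside turns.
#'
#' @param n_chains Number of chains.
#' @param length_range Min/max chain length.
#' @param turns_per_chain Planted turns per chain.
#' @param jitter Max absolute dihedral jitter (degrees, < 30) applied to
#'   planted canonical angles.
#' @param delta Profile log-odds shift on turn-favoring columns at turn
#'   residues.
#' @param sigma Standard deviation of the integer profile noise.
#' @param coil_shift Added coil probability at turn residues.
#' @param rsa_shift Added relative surface accessibility at turn residues.
#' @param type_weights Sampling weights for planted types (named, over the
#'   eight defined types); default mirrors their relative natural abundance.
#' @param seed Integer seed; every draw is derived from it.
#' @return A list of class `bturn_fixture_spec`.
#' @export
fixture_spec <- function(n_chains = 50, length_range = c(80, 120),
                         turns_per_chain = 6, jitter = 15,
                         delta = 4, sigma = 1,
                         coil_shift = 0.25, rsa_shift = 0.2,
                         type_weights = NULL, seed = 1) {
  if (is.null(type_weights)) {
    type_weights <- c("I" = 0.45, "I'" = 0.055, "II" = 0.16, "II'" = 0.035,
                      "VIII" = 0.12, "VIa1" = 0.008, "VIa2" = 0.004,
                      "VIb" = 0.012)
    # remaining mass spread evenly
    type_weights <- type_weights / sum(type_weights)
  }
  structure(list(n_chains = n_chains, length_range = length_range,
                 turns_per_chain = turns_per_chain, jitter = jitter,
                 delta = delta, sigma = sigma, coil_shift = coil_shift,
                 rsa_shift = rsa_shift, type_weights = type_weights,
                 seed = seed),
            class = "bturn_fixture_spec")
}

# Outer-residue "opener" torsions per planted type. The phi/psi of turn
# residues i and i+3 affect neither the planted window's CA(i)-CA(i+3)
# distance nor its classification (which reads only i+1/i+2), but they do
# control whether the windows straddling the plant boundary stay above the
# 7 A closure cutoff. These values were chosen (numerically, worst case
# over +/-25 deg jitter) to keep every straddling window open; only the
# window after a VIa2 plant is inherently compact (cis bond), where the
# generator falls back on resampling.
.OPENERS <- list(
  "I"    = list(left = c(-180,  60), right = c(   0,  160)),
  "I'"   = list(left = c(-180, -60), right = c( -20,  160)),
  "II"   = list(left = c(-180,  40), right = c( -20,  160)),
  "II'"  = list(left = c(-160, -20), right = c(   0,  160)),
  "VIII" = list(left = c(-180,  60), right = c(-100, -180)),
  "VIa1" = list(left = c(-180,   0), right = c(  40, -180)),
  "VIa2" = list(left = c(-180,  60), right = c(  50, -180)),
  "VIb"  = list(left = c(-180,  80), right = c(-120,  160))
)

# Sample jitter for one planted window, avoiding precedence collisions.
# With symmetric jitter up to 25 deg, a planted VIa2 can also satisfy the
# VIa1 definition (their centers differ by 60/0/30/0 deg: the phi(i+1)
# deviation from VIa1 is 60 minus the jitter, within the 40-deg one-angle
# allowance once the jitter exceeds +20) and would then be relabelled VIa1
# by precedence. Capping the phi(i+1) jitter of VIa2 at +15 keeps that
# deviation at >= 45 deg, outside every allowance. All other type pairs
# are separated by at least one angle > 65 deg or two angles > 55 deg,
# which +/-25 deg jitter cannot bridge.
.sample_plant_angles <- function(type, jitter, table) {
  row <- table[table$type == type, ]
  j <- stats::runif(4, -jitter, jitter)
  if (type == "VIa2") j[1] <- stats::runif(1, -jitter, min(15, jitter))
  c(row$phi1 + j[1], row$psi1 + j[2], row$phi2 + j[3], row$psi2 + j[4])
}

#' Build one chain with planted beta-turns
#'
#' Flanking residues take extended-strand torsions (phi,psi = -120,130);
#' each planted four-residue window gets the canonical angles of its type
#' plus uniform jitter. VIa1/VIa2 windows receive a proline at i+2 with a
#' cis peptide bond (omega = 0); VIb windows are also built cis-proline
#' (their natural geometry) although the classifier does not require it.
#' The true annotation is recorded from the construction, not from
#' reassignment. The construction is validated geometrically: exactly the
#' planted windows may satisfy the 7-Angstrom CA(i)-CA(i+3) criterion;
#' jitter is resampled (deterministically) if a flank-straddling window
#' accidentally closes.
#'
#' @param length Chain length in residues.
#' @param turns Tibble with columns `start` and `type` (defined types
#'   only), or an integer number of turns to place at random (non-adjacent
#'   by >= 2 residues).
#' @param jitter Max absolute jitter in degrees (must be < 30 so planted
#'   types stay inside the base tolerance).
#' @param overlap Allow explicitly requested overlapping instances.
#' @param table Canonical angle table.
#' @param chain_id Chain id.
#' @return List with `chain` (a `bturn_chain`), `truth` (per-residue
#'   annotation tibble as from [assign_turns()]), and `instances`.
#' @export
plant_turn_chain <- function(length = 100, turns = 4, jitter = 15,
                             overlap = FALSE, table = canonical_turn_table(),
                             chain_id = "A") {
  if (jitter >= 30) stop("jitter must stay below 30 degrees")
  if (is.numeric(turns) && length(turns) == 1) {
    n_turns <- turns
    starts <- integer(0)
    # random non-adjacent starts separated by >= 6 (>= 2 residues between
    # four-residue windows)
    cand <- sample(seq(2, length - 4))
    for (s in cand) {
      if (length(starts) == n_turns) break
      if (all(abs(s - starts) >= 6)) starts <- c(starts, s)
    }
    types <- sample(table$type, length(starts), replace = TRUE)
    turns <- tibble::tibble(start = sort(starts),
                            type = types[order(starts)])
  } else {
    turns <- tibble::as_tibble(turns)
    if (any(turns$start < 2 | turns$start + 3 > length)) {
      stop("planted turns must leave one flanking residue at each end")
    }
    if (!overlap && nrow(turns) > 1) {
      if (min(diff(sort(turns$start))) < 6) {
        stop("planted turns closer than the non-adjacency gap; ",
             "set overlap = TRUE to request overlapping instances")
      }
    }
  }
  if (!all(turns$type %in% table$type)) {
    stop("planted types must come from the defined (non-IV) types")
  }

  for (attempt in 1:25) {
    phi <- rep(EXTENDED_PHI, length)
    psi <- rep(EXTENDED_PSI, length)
    omega <- rep(180, length)
    # hard positions: central residues of some instance; openers never
    # overwrite them (overlapping instances share central residues)
    hard <- logical(length)
    resname <- aa_three(sample(AA1, length, replace = TRUE,
                               prob = .aa_background()))
    for (k in seq_len(nrow(turns))) {
      s <- turns$start[k]
      ty <- turns$type[k]
      ang <- .sample_plant_angles(ty, jitter, table)
      if (overlap) {
        # shared central residues must agree between the two definitions
        for (off in 1:2) {
          if (hard[s + off] &&
              max(angle_dev(phi[s + off], ang[2 * off - 1]),
                  angle_dev(psi[s + off], ang[2 * off])) > 2 * jitter + 1e-9) {
            stop("requested overlap is geometrically inconsistent")
          }
        }
      }
      phi[s + 1] <- ang[1]; psi[s + 1] <- ang[2]
      phi[s + 2] <- ang[3]; psi[s + 2] <- ang[4]
      hard[c(s + 1, s + 2)] <- TRUE
      if (table$cis_pro[table$type == ty] || ty == "VIb") {
        resname[s + 2] <- "PRO"
        omega[s + 2] <- 0
      }
      # turn-favoured sequence at planted residues (except forced PRO)
      pick <- sample(AA1, 4, replace = TRUE, prob = .aa_turnlike())
      for (p in 0:3) {
        if (resname[s + p] != "PRO") resname[s + p] <- aa_three(pick[p + 1])
      }
    }
    # opener torsions on the outer turn residues keep straddling windows
    # open; applied only where no instance claims the position centrally
    for (k in seq_len(nrow(turns))) {
      s <- turns$start[k]
      op <- .OPENERS[[turns$type[k]]]
      if (!hard[s]) {
        phi[s] <- op$left[1]; psi[s] <- op$left[2]
      }
      if (!hard[s + 3]) {
        phi[s + 3] <- op$right[1]; psi[s + 3] <- op$right[2]
      }
    }
    chain <- build_backbone_from_torsions(
      tibble::tibble(phi = phi, psi = psi, omega = omega),
      residue_names = resname, chain_id = chain_id)
    # geometric validation: only planted windows may close below 7 A
    ca <- .coord_matrix(chain, "ca")
    d <- sqrt(rowSums((ca[seq_len(length - 3), , drop = FALSE] -
                         ca[4:length, , drop = FALSE])^2))
    closed <- which(d < TURN_CA_CUTOFF)
    if (setequal(closed, turns$start)) {
      ok <- TRUE
      break
    }
    ok <- FALSE
  }
  if (!ok) stop("could not realise the requested plant geometrically")

  inst <- tibble::tibble(start = turns$start, type = turns$type)
  truth <- .annotation_from_instances(chain, inst)
  list(chain = chain, truth = truth, instances = inst)
}

#' Synthesize label-correlated profile and structure tracks
#'
#' Emulates what a profile tool and a secondary-structure/accessibility
#' predictor would produce for a chain with known turns: integer log-odds
#' profiles that are pure noise (sd `sigma`) except for a `+delta` shift on
#' the turn-favoring columns (Gly/Asp/Ser/Pro/Asn) of turn residues, and
#' coil probability / RSA raised on turn residues by `coil_shift` /
#' `rsa_shift`. The profile carries no trace of the residue letters
#' themselves, so with all effects at zero the tracks are pure noise.
#'
#' @param chain A `bturn_chain`.
#' @param truth Annotation tibble with an `in_turn` column aligned to the
#'   chain.
#' @param delta,sigma,coil_shift,rsa_shift Effect sizes, see
#'   [fixture_spec()].
#' @return List with `profile` (a `bturn_profile`) and `struct` (tibble
#'   with columns `aa`, `position`, `rsa`, `p_helix`, `p_strand`,
#'   `p_coil`).
#' @export
synth_tracks <- function(chain, truth, delta = 4, sigma = 1,
                         coil_shift = 0.25, rsa_shift = 0.2) {
  L <- nrow(chain)
  stopifnot(nrow(truth) == L)
  seq1 <- aa_one(chain$residue_name)
  scores <- matrix(round(stats::rnorm(L * 20, 0, sigma)), L, 20,
                   dimnames = list(NULL, AA1))
  fav <- match(TURN_FAVORED_AA, AA1)
  scores[truth$in_turn, fav] <- scores[truth$in_turn, fav] + round(delta)
  profile <- new_sequence_profile(paste(seq1, collapse = ""), scores)

  base_coil <- 0.35 + truth$in_turn * coil_shift
  logit <- function(p) log(p / (1 - p))
  p_coil <- stats::plogis(logit(pmin(pmax(base_coil, 0.02), 0.98)) +
                            stats::rnorm(L, 0, 0.3))
  rest <- 1 - p_coil
  frac_h <- stats::runif(L, 0.2, 0.8)
  struct <- tibble::tibble(
    aa = seq1,
    position = seq_len(L),
    rsa = pmin(pmax(0.35 + truth$in_turn * rsa_shift +
                      stats::rnorm(L, 0, 0.12), 0), 1),
    p_helix = rest * frac_h,
    p_strand = rest * (1 - frac_h),
    p_coil = p_coil
  )
  list(profile = profile, struct = struct)
}

#' Generate a full synthetic study set
#'
#' Draws `n_chains` chains with planted turns plus matching profile and
#' structure tracks under a single seed.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble with one row per chain: `chain_id`, and list-columns
#'   `chain`, `truth`, `instances`, `profile`, `struct`.
#' @export
synth_dataset <- function(spec = fixture_spec()) {
  withr_seed <- spec$seed %% .Machine$integer.max
  set.seed(withr_seed)
  ids <- sprintf("SYN%03d", seq_len(spec$n_chains))
  rows <- purrr::map(seq_len(spec$n_chains), function(i) {
    L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    n_turns <- spec$turns_per_chain
    starts <- integer(0)
    cand <- sample(seq(2, L - 4))
    for (s in cand) {
      if (length(starts) == n_turns) break
      if (all(abs(s - starts) >= 6)) starts <- c(starts, s)
    }
    types <- sample(names(spec$type_weights), length(starts), replace = TRUE,
                    prob = spec$type_weights)
    plant <- plant_turn_chain(
      L, turns = tibble::tibble(start = sort(starts),
                                type = types[order(starts)]),
      jitter = spec$jitter, chain_id = ids[i])
    tr <- synth_tracks(plant$chain, plant$truth, delta = spec$delta,
                       sigma = spec$sigma, coil_shift = spec$coil_shift,
                       rsa_shift = spec$rsa_shift)
    tibble::tibble(chain_id = ids[i], chain = list(plant$chain),
                   truth = list(plant$truth),
                   instances = list(plant$instances),
                   profile = list(tr$profile), struct = list(tr$struct))
  })
  dplyr::bind_rows(rows)
}

#' Write a backbone chain as PDB-format ATOM records
#'
#' @param chain A `bturn_chain`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when written).
#' @export
write_pdb_chain <- function(chain, path = NULL) {
  ch1 <- substr(chain_id(chain), 1, 1)  # PDB chain field is one column
  fmt <- function(serial, name, resname, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, resname, ch1, resno, x, y, z,
            substr(name, 1, 1))
  }
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(chain))) {
    for (atom in BACKBONE_ATOMS) {
      xyz <- unlist(chain[i, paste0(tolower(atom), c("_x", "_y", "_z"))])
      if (any(is.na(xyz))) next
      serial <- serial + 1
      lines <- c(lines, fmt(serial, atom, chain$residue_name[i],
                            chain$seq_index[i], xyz[1], xyz[2], xyz[3]))
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
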