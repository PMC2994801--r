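#' Logistic squashing of profile log-odds
#'
#' Maps a raw log-odds score into (0,1) with the logistic function
#' `1/(1+exp(-x))`; monotone increasing, 0 maps to 0.5.
#'
#' @param score Numeric score(s).
#' @return Value(s) in (0,1).
#' @export
squash <- function(score) 1 / (1 + exp(-score))

# Column index carrying the out-of-chain indicator in the first-layer
# track (the 25-neuron encoding: 20 profile + indicator + H/E/C + RSA).
FIRST_LAYER_OOB_COL <- 21L

#' Per-residue 25-value feature track
#'
#' Builds the residue encoding the first-layer networks consume: 20
#' logistic-squashed profile log-odds, one out-of-chain indicator (0 for
#' every real residue; 1 only on virtual window positions outside the
#' chain), the three secondary-structure probabilities and the relative
#' surface accessibility. All values lie in `[0, 1]`.
#'
#' @param profile A `bturn_profile`.
#' @param struct Structure tibble as from [read_struct_table()] /
#'   [synth_tracks()].
#' @return L x 25 numeric matrix with attribute `oob_col = 21`.
#' @export
feature_track <- function(profile, struct) {
  L <- nchar(profile$sequence)
  if (nrow(struct) != L) stop("profile and structure tracks differ in length")
  m <- cbind(squash(profile$scores),
             0,
             struct$p_helix, struct$p_strand, struct$p_coil,
             struct$rsa)
  dimnames(m) <- NULL
  attr(m, "oob_col") <- FIRST_LAYER_OOB_COL
  m
}

# Rows used to pad a track outside the chain: indicator 1, all else 0.
.oob_row <- function(track) {
  r <- numeric(ncol(track))
  r[attr(track, "oob_col")] <- 1
  r
}

#' Window the track around one residue
#'
#' Concatenates the per-residue vectors of the `w` positions centred on
#' `center`, in position order; virtual positions before residue 1 or
#' after residue L carry the out-of-chain pattern.
#'
#' @param track Feature track matrix (from [feature_track()] or
#'   [build_second_layer_track()]).
#' @param center Residue index.
#' @param w Odd window size.
#' @return Numeric vector of length `ncol(track) * w`.
#' @export
encode_window <- function(track, center, w) {
  if (w %% 2 == 0) stop("window size must be odd")
  encode_windows(track, w)[center, ]
}

#' Window the whole track
#'
#' One row per residue (so a chain of length L yields exactly L examples
#' for every window size), columns as in [encode_window()].
#'
#' @param track Feature track matrix.
#' @param w Odd window size.
#' @return L x (ncol(track)*w) matrix.
#' @export
encode_windows <- function(track, w) {
  if (w %% 2 == 0) stop("window size must be odd")
  L <- nrow(track)
  k <- ncol(track)
  half <- (w - 1) / 2
  pad <- matrix(rep(.oob_row(track), each = half), nrow = half)
  padded <- rbind(pad, unclass(track)[, , drop = FALSE], pad)
  out <- matrix(0, L, k * w)
  for (p in seq_len(w)) {
    out[, ((p - 1) * k + 1):(p * k)] <- padded[p:(p + L - 1), , drop = FALSE]
  }
  out
}

# Second-layer setup table: which channel blocks each setup letter uses.
SETUP_TABLE <- list(
  A = c("pssm", "secrsa"),
  B = c("pssm", "g", "secrsa"),
  C = c("pssm", "g"),
  D = c("pssm", "p"),
  E = c("p"),
  F = c("g", "secrsa"),
  G = c("g"),
  H = c("pssm", "p", "secrsa"),
  I = c("p", "secrsa"),
  J = c("pssm", "p", "g", "secrsa"),
  K = c("pssm", "p", "g"),
  L = c("p", "g"),
  M = c("p", "g", "secrsa")
)

#' Per-residue input track for a second-layer network
#'
#' Composes the per-residue channel vector of the requested setup letter
#' (A..M) from the first-layer output channels and/or raw features, and
#' appends one out-of-chain indicator channel (0 on real residues). Setup
#' M, the final-method choice, is the four position scores + the general
#' turn score + helix/strand/coil + RSA: 9 channels, 10 with the
#' indicator. Setup A (PSSM + sec-rsa) reproduces the first-layer encoding
#' exactly.
#'
#' @param first_layer Tibble or list with per-residue first-layer outputs:
#'   `g` (general score) and `p1`..`p4` (position scores); may be `NULL`
#'   for setups that use neither. An optional `s` column (type score) is
#'   appended when present (used by type-specific second layers).
#' @param struct Structure tibble (needed by setups with sec-rsa).
#' @param profile A `bturn_profile` (needed by setups with PSSM).
#' @param setup Setup letter A..M.
#' @return L x (channels+1) matrix with `oob_col` attribute.
#' @export
build_second_layer_track <- function(first_layer = NULL, struct = NULL,
                                     profile = NULL, setup = "M") {
  setup <- toupper(setup)
  if (!setup %in% names(SETUP_TABLE)) {
    stop("setup must be one of ", paste(names(SETUP_TABLE), collapse = ""))
  }
  blocks <- SETUP_TABLE[[setup]]
  parts <- list()
  if ("pssm" %in% blocks) {
    if (is.null(profile)) stop(sprintf("setup %s requires a PSSM", setup))
    parts$pssm <- squash(profile$scores)
  }
  if ("p" %in% blocks) {
    if (is.null(first_layer)) stop("setup needs first-layer position scores")
    parts$p <- cbind(first_layer$p1, first_layer$p2, first_layer$p3,
                     first_layer$p4)
  }
  if ("g" %in% blocks) {
    if (is.null(first_layer)) stop("setup needs the first-layer turn score")
    parts$g <- cbind(first_layer$g)
  }
  if (!is.null(first_layer) && !is.null(first_layer$s)) {
    parts$s <- cbind(first_layer$s)
  }
  if ("secrsa" %in% blocks) {
    if (is.null(struct)) stop(sprintf("setup %s requires structure tracks",
                                      setup))
    parts$secrsa <- cbind(struct$p_helix, struct$p_strand, struct$p_coil,
                          struct$rsa)
  }
  m <- do.call(cbind, parts)
  # setup A keeps the first-layer column layout (indicator at column 21)
  if (setup == "A") {
    m <- cbind(m[, 1:20, drop = FALSE], 0, m[, 21:24, drop = FALSE])
    dimnames(m) <- NULL
    attr(m, "oob_col") <- FIRST_LAYER_OOB_COL
    return(m)
  }
  m <- cbind(m, 0)
  dimnames(m) <- NULL
  attr(m, "oob_col") <- ncol(m)
  m
}
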