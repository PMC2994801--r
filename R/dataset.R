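#' Chain records for dataset construction
#'
#' @param id Chain identifiers.
#' @param sequence Amino-acid strings.
#' @param resolution Structure resolution in Angstrom.
#' @param pdb_length Number of residues with coordinates (defaults to the
#'   full sequence length).
#' @return Tibble with columns `id`, `sequence`, `resolution`,
#'   `sequence_length`, `pdb_length`.
#' @export
chain_records <- function(id, sequence, resolution, pdb_length = NULL) {
  sequence_length <- nchar(sequence)
  if (is.null(pdb_length)) pdb_length <- sequence_length
  if (any(pdb_length > sequence_length)) {
    stop("pdb_length cannot exceed sequence_length")
  }
  if (any(resolution <= 0)) stop("resolution must be positive")
  tibble::tibble(id = id, sequence = sequence, resolution = resolution,
                 sequence_length = sequence_length,
                 pdb_length = pdb_length)
}

#' Empiric ranking score for chain selection
#'
#' Lower is better. The default surrogate `resolution * sequence_length /
#' pdb_length` prefers high-resolution structures whose deposited
#' coordinates cover as much of the sequence as possible: it is strictly
#' increasing in resolution and strictly decreasing in coordinate
#' coverage. Any alternative with the same monotonicity contract can be
#' passed wherever a ranking is consumed.
#'
#' @param records Tibble from [chain_records()].
#' @return Numeric score vector (lower = better rank).
#' @export
rank_score <- function(records) {
  if (any(records$pdb_length == 0)) {
    stop("pdb_length must be positive to rank a record")
  }
  records$resolution * records$sequence_length / records$pdb_length
}

#' Pairwise sequence identity in percent
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62, gap opening 11 and
#' extension 1; identity is the number of identical aligned positions
#' over the alignment length (including internal gap columns). Symmetric
#' in its arguments.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("pairwise_identity: empty sequence")
  }
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 11, gapExtension = 1, type = "global")
  Biostrings::pid(aln, type = "PID1")
}

#' Length-corrected identity threshold
#'
#' The classic homology-detection curve: short alignments need much
#' higher identity than long ones before two sequences count as
#' homologous. `290.15 * L^-0.562` percent for alignment lengths up to
#' 450 residues, constant beyond.
#'
#' @param length Alignment (or shorter-sequence) length in residues.
#' @return Identity threshold in percent.
#' @export
length_corrected_threshold <- function(length) {
  ifelse(length > 450, 290.15 * 450^-0.562, 290.15 * length^-0.562)
}

#' Greedy homology reduction (Hobohm algorithm 1)
#'
#' Records are visited from best to worst rank; a record is accepted when
#' its identity to every previously accepted record does not exceed the
#' threshold. The result is an independent set of the similarity graph
#' that is greedily maximal with respect to the ranking.
#'
#' @param records Tibble from [chain_records()].
#' @param threshold Maximum allowed identity percentage (default 25), or
#'   the string `"length"` for the length-corrected curve
#'   ([length_corrected_threshold()] evaluated at the shorter sequence's
#'   length for each pair).
#' @param rank Ranking function (lower = better); default [rank_score()].
#' @param identity Pairwise identity function (defaults to
#'   [pairwise_identity()]).
#' @return Accepted subset of `records`, in acceptance order.
#' @export
hobohm1 <- function(records, threshold = 25, rank = rank_score,
                    identity = pairwise_identity) {
  if (nrow(records) == 0) stop("hobohm1 needs at least one record")
  pair_threshold <- if (identical(threshold, "length")) {
    function(a, b) length_corrected_threshold(min(nchar(a), nchar(b)))
  } else {
    function(a, b) threshold
  }
  ord <- order(rank(records))
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      a <- records$sequence[i]
      b <- records$sequence[j]
      if (identity(a, b) > pair_threshold(a, b)) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  records[accepted, ]
}

#' Record filter mirroring structure-quality culling
#'
#' Plain record-level filter with the usual selection criteria: maximum
#' mutual identity is handled by [hobohm1()]; this filter applies the
#' resolution, R-factor and length windows.
#'
#' @param records Tibble with at least `resolution` and `sequence_length`
#'   (optionally `r_factor`).
#' @param max_resolution Maximum resolution in Angstrom (default 3.0).
#' @param max_r_factor Maximum crystallographic R-factor (default 0.2;
#'   ignored when the column is absent).
#' @param length_range Allowed sequence-length window (default 40-10000).
#' @return Filtered tibble.
#' @export
filter_chain_records <- function(records, max_resolution = 3.0,
                                 max_r_factor = 0.2,
                                 length_range = c(40, 10000)) {
  keep <- records$resolution <= max_resolution &
    records$sequence_length >= length_range[1] &
    records$sequence_length <= length_range[2]
  if ("r_factor" %in% names(records)) {
    keep <- keep & records$r_factor <= max_r_factor
  }
  records[keep, ]
}

#' Amino-acid composition inside and outside beta-turns
#'
#' Per-residue counting over a set of annotated chains: the frequency of
#' each amino acid among turn residues and among all residues, each
#' normalized to 100 percent.
#'
#' @param annotations List of `bturn_annotation` (or tibbles with `aa`
#'   and `in_turn` columns).
#' @return Tibble `aa`, `freq_turn`, `freq_overall` (percent), sorted by
#'   decreasing turn frequency.
#' @export
composition_stats <- function(annotations) {
  if (inherits(annotations, "data.frame")) annotations <- list(annotations)
  aa <- unlist(lapply(annotations, function(a) a$aa), use.names = FALSE)
  turn <- unlist(lapply(annotations, function(a) a$in_turn),
                 use.names = FALSE)
  if (length(aa) != length(turn)) stop("annotation columns misaligned")
  tab_all <- table(factor(aa, levels = AA1))
  tab_turn <- table(factor(aa[turn], levels = AA1))
  tibble::tibble(
    aa = AA1,
    freq_turn = 100 * as.numeric(tab_turn) / max(sum(tab_turn), 1),
    freq_overall = 100 * as.numeric(tab_all) / max(sum(tab_all), 1)
  ) |>
    dplyr::arrange(dplyr::desc(.data$freq_turn))
}
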