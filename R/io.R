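#' Construct a sequence profile
#'
#' A `bturn_profile` pairs an amino-acid sequence with its L x 20 matrix of
#' position-specific log-odds scores (integer-valued as emitted by the
#' profile tool). Columns follow the fixed order
#' `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @param sequence Amino-acid string of length L.
#' @param scores L x 20 numeric matrix.
#' @return A `bturn_profile` object.
#' @export
new_sequence_profile <- function(sequence, scores) {
  L <- nchar(sequence)
  scores <- as.matrix(scores)
  if (nrow(scores) != L) {
    stop(sprintf("profile has %d rows but sequence has %d residues",
                 nrow(scores), L))
  }
  if (ncol(scores) != 20) stop("profile must have 20 score columns")
  colnames(scores) <- AA1
  structure(list(sequence = sequence, scores = scores),
            class = "bturn_profile")
}

#' @export
print.bturn_profile <- function(x, ...) {
  cat(sprintf("<bturn_profile: %d residues>\n", nchar(x$sequence)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard ASCII PSSM layout: a header, a column-letter line,
#' then one row per residue starting with the position index and residue
#' letter followed by (at least) 20 integer log-odds columns. Trailing
#' statistics footers are ignored.
#'
#' @param path File path, or a character vector of lines.
#' @param sequence Optional amino-acid string to cross-check the row count
#'   against; a mismatch is an error.
#' @return A [new_sequence_profile()].
#' @export
read_psiblast_pssm <- function(path, sequence = NULL) {
  lines <- if (length(path) > 1) path else readLines(path)
  # locate the header line carrying the 20 (or 40) column letters
  hdr <- which(vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) >= 20 && all(f[1:20] %in% AA1)
  }, logical(1), USE.NAMES = FALSE))
  if (length(hdr) == 0) stop("not a PSI-BLAST ASCII PSSM: no column header")
  hdr <- hdr[1]
  rows <- list()
  letters_seen <- character(0)
  for (ln in seq(hdr + 1, length(lines))) {
    l <- trimws(lines[ln])
    if (l == "") break
    f <- strsplit(l, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) break   # statistics footer
    if (length(f) < 22 || !f[2] %in% c(AA1, "X")) {
      stop(sprintf("malformed PSSM row at line %d", ln))
    }
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (any(is.na(v))) stop(sprintf("malformed PSSM row at line %d", ln))
    rows[[length(rows) + 1]] <- v
    letters_seen <- c(letters_seen, f[2])
  }
  if (length(rows) == 0) stop("PSSM contains no residue rows")
  scores <- do.call(rbind, rows)
  seq_from_rows <- paste(letters_seen, collapse = "")
  if (!is.null(sequence) && !identical(sequence, seq_from_rows)) {
    stop(sprintf("PSSM has %d rows but sequence has %d residues (mismatch)",
                 nrow(scores), nchar(sequence)))
  }
  new_sequence_profile(seq_from_rows, scores)
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' @param profile A `bturn_profile`.
#' @param path Optional output path; lines returned otherwise.
#' @param footer Append a statistics-style footer (exercises reader
#'   tolerance).
#' @return Character lines (invisibly when written).
#' @export
write_psiblast_pssm <- function(profile, path = NULL, footer = TRUE) {
  hdr1 <- "Last position-specific scoring matrix computed"
  hdr2 <- paste0("            ", paste(sprintf("%3s", AA1), collapse = " "))
  letters <- strsplit(profile$sequence, "")[[1]]
  body <- vapply(seq_along(letters), function(i) {
    paste0(sprintf("%5d %s  ", i, letters[i]),
           paste(sprintf("%3d", round(profile$scores[i, ])), collapse = " "))
  }, character(1))
  lines <- c(hdr1, "", hdr2, body, "")
  if (footer) {
    lines <- c(lines,
               "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a per-residue structure-prediction table
#'
#' Accepts the whitespace-delimited per-residue dialect emitted by
#' surface/secondary-structure predictors: columns `aa` (one-letter),
#' `chain`, `position`, `rsa` (relative surface accessibility in [0,1]),
#' and the three class probabilities `p_helix`, `p_strand`, `p_coil`.
#' Lines starting with `#` are comments. A header row naming the columns
#' is accepted in any order; a headerless file is read in the column order
#' above. When the three probabilities do not sum to ~1 a warning is
#' emitted (values are kept).
#'
#' @param path File path or character lines.
#' @return Tibble with columns `aa`, `chain`, `position`, `rsa`,
#'   `p_helix`, `p_strand`, `p_coil`.
#' @export
read_struct_table <- function(path) {
  lines <- if (length(path) > 1) path else readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("structure table is empty")
  cols <- c("aa", "chain", "position", "rsa", "p_helix", "p_strand", "p_coil")
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  has_header <- all(cols %in% tolower(first))
  df <- utils::read.table(text = lines, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 7) stop("structure table needs 7 columns")
    df <- df[, 1:7]
    names(df) <- cols
  } else {
    names(df) <- tolower(names(df))
    df <- df[, cols]
  }
  df <- tibble::as_tibble(df)
  tot <- df$p_helix + df$p_strand + df$p_coil
  if (any(tot < 0.99 | tot > 1.01)) {
    warning("helix/strand/coil probabilities do not sum to 1 ",
            "(un-normalized predictor output?)")
  }
  df
}

#' Write a per-residue structure-prediction table
#' @param struct Tibble as from [read_struct_table()] (a missing `chain`
#'   column is filled with `"A"`).
#' @param path Optional output path.
#' @return Character lines (invisibly when written).
#' @export
write_struct_table <- function(struct, path = NULL) {
  if (!"chain" %in% names(struct)) struct$chain <- "A"
  lines <- c("# per-residue structure predictions",
             "aa chain position rsa p_helix p_strand p_coil",
             sprintf("%s %s %d %.4f %.4f %.4f %.4f",
                     struct$aa, struct$chain, struct$position, struct$rsa,
                     struct$p_helix, struct$p_strand, struct$p_coil))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(x)),
                 sequence = unname(as.character(x)))
}

#' Write sequences to a FASTA file
#' @param seqs Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs$sequence)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
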