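#' Canonical amino-acid order used for integer encoding
#'
#' The 20 canonical one-letter codes in alphabetical order, mapped to the
#' integer states 1..20. State 0 is the gap.
#'
#' @export
AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")
AMBIGUITY_CHARS <- c("B", "Z", "X", "U", "O", "J")

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm 1.0 file. For Stockholm input,
#' insert-state columns (columns carrying lowercase residues or '.') are
#' removed so that only match columns remain.
#'
#' @param path path to the alignment file
#' @param format `"fasta"` or `"stockholm"`
#' @return an object of class `Alignment`: a list with `ids` (sequence
#'   identifiers) and `rows` (equal-length uppercase-preserving strings)
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(seqs) == 0L) stop("empty input: no sequences in ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    rows <- as.character(seqs)
  } else {
    parsed <- parse_stockholm(path)
    ids <- parsed$ids
    rows <- parsed$rows
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("malformed alignment: rows have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (format == "stockholm") {
    rows <- strip_insert_columns(rows)
  }
  aln <- structure(list(ids = ids, rows = unname(rows)), class = "Alignment")
  validate_alignment(aln)
  aln
}

# Stockholm 1.0 sequence lines, case preserved (Biostrings' reader folds
# case, which would lose the insert-state annotation). Handles multi-block
# (interleaved) files; annotation lines (#=...) and markup are skipped.
parse_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty input: ", path)
  acc <- list()
  order <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "//")) break
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L)
      stop("malformed alignment: unparseable Stockholm line: ", ln)
    id <- parts[1L]
    if (!id %in% order) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], parts[2L])
  }
  if (length(order) == 0L) stop("empty input: no sequences in ", path)
  list(ids = order, rows = unlist(acc[order], use.names = FALSE))
}

# drop columns that are insert states in any row (lowercase or '.')
strip_insert_columns <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  is_insert <- apply(mat, 2L, function(col) any(col == "." | col %in% letters))
  if (all(is_insert)) stop("malformed alignment: no match columns remain")
  apply(mat[, !is_insert, drop = FALSE], 1L, paste0, collapse = "")
}

validate_alignment <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  if (length(aln$rows) < 1L) stop("empty input: alignment has no rows")
  lens <- nchar(aln$rows)
  if (length(unique(lens)) != 1L)
    stop("malformed alignment: rows have unequal lengths")
  if (lens[1L] < 2L) stop("alignment must have at least 2 columns")
  invisible(aln)
}

#' Encode an alignment over the 21-state alphabet
#'
#' Maps gap symbols (`-`, `.`) to state 0, the 20 canonical amino acids to
#' states 1..20 in alphabetical one-letter order (see [AA_ALPHABET_20]), and
#' lowercase letters to their uppercase encoding. Ambiguity and non-standard
#' codes (B, Z, X, U, O, J) are treated as gaps by default, the common
#' convention in coupling analysis.
#'
#' @param aln an `Alignment`
#' @param ambiguity `"gap"` (default) to encode ambiguity codes as state 0,
#'   or `"error"` to reject them
#' @return an `EncodedMSA`: list with integer matrix `data` (rows =
#'   sequences, entries in 0..20), `weights` (all 1 until
#'   [compute_weights()] is called), `b_eff`, `q = 21`, and `ids`
#' @export
encode_msa <- function(aln, ambiguity = c("gap", "error")) {
  ambiguity <- match.arg(ambiguity)
  validate_alignment(aln)
  code <- integer(0)
  code[GAP_CHARS] <- 0L
  code[AA_ALPHABET_20] <- seq_along(AA_ALPHABET_20)
  if (ambiguity == "gap") code[AMBIGUITY_CHARS] <- 0L
  B <- length(aln$rows)
  N <- nchar(aln$rows[1L])
  chars <- toupper(do.call(rbind, strsplit(aln$rows, "")))
  hit <- chars %in% names(code)
  if (!all(hit)) {
    bad <- which(!hit)[1L]
    stop(sprintf("encoding error: unhandled character '%s' at row %d, column %d",
                 chars[bad], (bad - 1L) %% B + 1L, (bad - 1L) %/% B + 1L))
  }
  data <- matrix(code[chars], nrow = B, ncol = N)
  new_encoded_msa(data, ids = aln$ids)
}

#' Construct an EncodedMSA from an integer state matrix
#'
#' @param data B x N integer matrix with entries in `0..(q-1)`; 0 is the gap
#' @param weights per-sequence weights (default all 1)
#' @param q alphabet size (21 for protein data: 20 amino acids + gap)
#' @param ids optional sequence identifiers
#' @export
new_encoded_msa <- function(data, weights = rep(1, nrow(data)), q = 21L,
                            ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (any(data < 0L) || any(data >= q)) stop("states must lie in [0, q-1]")
  if (length(weights) != nrow(data)) stop("one weight per sequence required")
  if (any(weights <= 0) || any(weights > 1 + 1e-12))
    stop("weights must lie in (0, 1]")
  structure(list(data = data, weights = as.numeric(weights),
                 b_eff = sum(weights), q = as.integer(q),
                 ids = ids %||% paste0("seq", seq_len(nrow(data)))),
            class = "EncodedMSA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fractional identity of two encoded sequences
#'
#' Fraction of positions at which the encoded states agree, the gap state
#' counting as an ordinary state (the convention of the asymmetric
#' pseudo-likelihood lineage).
#'
#' @param x,y equal-length integer vectors of encoded states
#' @return a number in `[0, 1]`
#' @export
sequence_identity <- function(x, y) {
  if (length(x) != length(y)) stop("sequences differ in length")
  mean(x == y)
}

#' Reweight sequences by local neighbourhood density
#'
#' Each sequence receives weight `1 / n_s`, where `n_s` counts the sequences
#' (itself included) whose identity with it is at least `1 - threshold_x`.
#' With the default threshold 0.1 this down-weights sequences that are more
#' than 90% identical to others. The effective alignment depth `b_eff` is
#' the sum of the weights.
#'
#' @param msa an `EncodedMSA`
#' @param threshold_x similarity threshold in (0, 1); default 0.1
#' @return the `EncodedMSA` with `weights` and `b_eff` set
#' @export
compute_weights <- function(msa, threshold_x = 0.1) {
  stopifnot(inherits(msa, "EncodedMSA"))
  if (!is.numeric(threshold_x) || length(threshold_x) != 1L ||
      threshold_x <= 0 || threshold_x >= 1)
    stop("threshold_x must lie strictly between 0 and 1")
  msa$weights <- msa_weights_cpp(msa$data, threshold_x)
  msa$b_eff <- sum(msa$weights)
  msa
}

#' Maximal gap runs of an encoded sequence
#'
#' @param row integer vector of encoded states (0 = gap)
#' @return data frame with columns `start` (1-based) and `length`, one row
#'   per maximal run of gaps, ordered by start; zero rows if gap-free
#' @export
find_gap_runs <- function(row) {
  r <- rle(row == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Decode an encoded MSA back to residue strings
#'
#' Inverse of [encode_msa()] on canonical residues: state 0 becomes `-`,
#' states 1..20 the alphabetical one-letter codes.
#'
#' @param msa an `EncodedMSA` with `q = 21`
#' @return character vector of aligned rows
#' @export
decode_msa <- function(msa) {
  stopifnot(inherits(msa, "EncodedMSA"), msa$q == 21L)
  chars <- c("-", AA_ALPHABET_20)
  apply(msa$data, 1L, function(row) paste0(chars[row + 1L], collapse = ""))
}

#' Write an encoded MSA as aligned FASTA
#'
#' @param msa an `EncodedMSA`
#' @param path output file
#' @export
write_msa_fasta <- function(msa, path) {
  rows <- decode_msa(msa)
  writeLines(paste0(">", msa$ids, "\n", rows), path)
  invisible(path)
}

#' Write per-sequence weights as two-column text
#'
#' @param msa an `EncodedMSA` with weights computed
#' @param path output file
#' @export
export_weights <- function(msa, path) {
  stopifnot(inherits(msa, "EncodedMSA"))
  write.table(data.frame(id = msa$ids, weight = msa$weights),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
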