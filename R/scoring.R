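#' Frobenius-norm coupling scores
#'
#' Per-pair coupling strength from the gauge-fixed symmetric blocks:
#' `fn21` uses the full q x q block, `fn20` restricts the sum of squares to
#' the 20 x 20 amino-acid submatrix, discarding the gap row and column of
#' the *already gauge-fixed* block (no re-gauging of the submatrix). The
#' latter is the plmDCA20 scoring variant: gap observations still shape the
#' inferred couplings through the fit and the gauge, but gap couplings do
#' not enter the score.
#'
#' @param fit a `FitResult` from [fit_model()] or [decimate_fit()]
#' @param variant `"fn21"` (full block) or `"fn20"` (gap-excluded)
#' @return a `ScoreMatrix`: list with symmetric `values` (N x N, diagonal
#'   zero and ignored), `variant`, `apc_applied = FALSE`
#' @export
frobenius_scores <- function(fit, variant = c("fn21", "fn20")) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "FitResult"))
  J <- fit$params$J
  q <- dim(J)[1L]; N <- dim(J)[3L]
  keep <- if (variant == "fn20") 2L:q else 1L:q
  S <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    S[i, j] <- S[j, i] <- sqrt(sum(J[keep, keep, i, j]^2))
  }
  structure(list(values = S, variant = variant, apc_applied = FALSE),
            class = "ScoreMatrix")
}

#' Average product correction
#'
#' Subtracts the product of row and column means divided by the grand mean,
#' all means taken over off-diagonal entries:
#' `CN_ij = FN_ij - mean_j'(FN_ij') * mean_i'(FN_i'j) / mean(FN)`.
#' Suppresses the per-column background (conservation, gap content,
#' phylogeny) that inflates raw coupling norms. An all-zero input returns
#' all zeros rather than dividing by zero.
#'
#' @param fn a `ScoreMatrix` with `apc_applied = FALSE`
#' @return a `ScoreMatrix` with `apc_applied = TRUE`
#' @export
apc_correct <- function(fn) {
  stopifnot(inherits(fn, "ScoreMatrix"), !fn$apc_applied)
  S <- fn$values
  N <- nrow(S)
  diag(S) <- 0
  row_mean <- rowSums(S) / (N - 1)      # diagonal excluded (it is zero)
  grand <- sum(S) / (N * (N - 1))
  out <- fn
  if (grand == 0) {
    out$values <- matrix(0, N, N)
  } else {
    out$values <- S - outer(row_mean, row_mean) / grand
    diag(out$values) <- 0
  }
  out$apc_applied <- TRUE
  out
}

#' Rank residue pairs by score
#'
#' Orders all pairs i < j with `j - i >= min_separation` by descending
#' score; ties are broken lexicographically by (i, j) so rankings are
#' bit-reproducible. Short-range pairs are excluded because trivially close
#' positions along the chain carry no predictive information.
#'
#' @param scores a `ScoreMatrix`
#' @param min_separation minimum sequence separation (default 5)
#' @return a `RankedContacts` data frame with columns `i`, `j`, `score`
#' @export
rank_contacts <- function(scores, min_separation = 5L) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  S <- scores$values
  N <- nrow(S)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  keep <- pairs[, 2L] - pairs[, 1L] >= min_separation
  pairs <- pairs[keep, , drop = FALSE]
  sc <- S[pairs]
  ord <- order(-sc, pairs[, 1L], pairs[, 2L])
  out <- data.frame(i = pairs[ord, 1L], j = pairs[ord, 2L], score = sc[ord])
  rownames(out) <- NULL
  structure(out, class = c("RankedContacts", "data.frame"),
            min_separation = min_separation,
            variant = scores$variant, apc = scores$apc_applied, n_col = N)
}

#' Iterative decimation of weak couplings
#'
#' Repeatedly fits the model, ranks pair blocks by current APC-corrected
#' Frobenius score, freezes the weakest fraction of still-active blocks at
#' zero, and refits with the frozen blocks constrained to stay zero.
#' `rounds = 0` reproduces [fit_model()] exactly. Masks are monotone: a
#' block decimated in one round stays decimated in all later rounds.
#'
#' @inheritParams fit_model
#' @param rounds number of decimation rounds (default 0, off)
#' @param fraction_per_round fraction of remaining active pair blocks frozen
#'   per round (default 0.1)
#' @param variant score variant used for the per-round ranking
#' @return the final `FitResult` with `$mask_history`, a list of N x N
#'   logical masks after each round
#' @export
decimate_fit <- function(msa, reg = reg_config(), use_gaps = FALSE,
                         rounds = 0L, fraction_per_round = 0.1,
                         settings = optim_settings(), cores = 1L,
                         variant = "fn21") {
  stopifnot(rounds >= 0L)
  if (rounds > 0L)
    stopifnot(fraction_per_round > 0, fraction_per_round < 1)
  N <- ncol(msa$data)
  mask <- matrix(FALSE, N, N)
  history <- list()
  fit <- fit_model(msa, reg, use_gaps, settings, cores, mask = mask)
  for (k in seq_len(rounds)) {
    apc <- apc_correct(frobenius_scores(fit, variant))
    up <- which(upper.tri(mask) & !mask, arr.ind = TRUE)
    n_drop <- floor(fraction_per_round * nrow(up))
    if (n_drop > 0L) {
      sc <- apc$values[up]
      ord <- order(sc, up[, 1L], up[, 2L])   # weakest first
      drop <- up[ord[seq_len(n_drop)], , drop = FALSE]
      mask[drop] <- TRUE
      mask[drop[, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    if (all(mask[upper.tri(mask)]))
      stop("decimation has masked every pair block; nothing left to refit")
    history[[k]] <- mask
    fit <- fit_model(msa, reg, use_gaps, settings, cores, mask = mask)
  }
  fit$mask_history <- history
  fit
}

#' Write ranked contact scores as tab-separated text
#'
#' One line per eligible pair, `i<TAB>j<TAB>score` (1-based, i < j),
#' descending by score, preceded by a header comment recording the scoring
#' setup.
#'
#' @param ranked a `RankedContacts`
#' @param path output file
#' @param model label recorded in the header (plmDCA, gplmDCA, plmDCA20,
#'   decgplmDCA(r), ...)
#' @export
write_scores <- function(ranked, path, model = "plmDCA") {
  stopifnot(inherits(ranked, "RankedContacts"))
  hdr <- sprintf("# model=%s variant=%s apc=%s min_separation=%d",
                 model, attr(ranked, "variant"),
                 tolower(as.character(attr(ranked, "apc"))),
                 attr(ranked, "min_separation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(as.data.frame(ranked), scientific = FALSE,
                     trim = TRUE, digits = 10),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a score file written by [write_scores()]
#'
#' @param path score file
#' @return a `RankedContacts` data frame (header metadata in attributes)
#' @export
read_scores <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- strsplit(strsplit(sub("^#\\s*", "", first), "\\s+")[[1]], "=")
    meta <- setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  }
  df <- read.table(path, comment.char = "#", sep = "\t",
                   col.names = c("i", "j", "score"))
  structure(df, class = c("RankedContacts", "data.frame"),
            min_separation = as.integer(meta$min_separation %||% NA),
            variant = meta$variant %||% NA_character_,
            apc = identical(meta$apc, "true"),
            model = meta$model %||% NA_character_)
}
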