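#' Contact map from a crystal structure
#'
#' Extracts a symmetric boolean contact map for the alignment columns
#' described by `mapping`. Two criteria are supported: `cbeta_8` marks a
#' contact when the C-beta atoms (C-alpha for glycine) are at most 8 A
#' apart; `heavy_8p5` when any two non-hydrogen atoms are at most 8.5 A
#' apart. Columns whose residue is absent from the structure (or lacks the
#' needed atoms) are marked unresolved and excluded from contacts.
#'
#' Multi-model files use MODEL 1 only; alternate locations keep the
#' highest-occupancy conformer.
#'
#' @param pdb_path path to a PDB file
#' @param chain chain identifier
#' @param mapping data frame with columns `column` (1-based alignment
#'   column) and `resno` (residue number in the structure); must be
#'   injective
#' @param criterion `"cbeta_8"` or `"heavy_8p5"`
#' @param n_col alignment length (defaults to `max(mapping$column)`)
#' @return a `ContactMap`: list with boolean `contacts` (n_col x n_col),
#'   `resolved` flags, `criterion`
#' @export
contact_map_from_structure <- function(pdb_path, chain, mapping,
                                       criterion = c("cbeta_8", "heavy_8p5"),
                                       n_col = max(mapping$column)) {
  criterion <- match.arg(criterion)
  stopifnot(all(c("column", "resno") %in% names(mapping)))
  if (anyDuplicated(mapping$column) || anyDuplicated(mapping$resno))
    stop("mapping must be injective in both columns")
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' absent from ", pdb_path)
  at <- pick_altloc(at)
  heavy <- is.na(at$elesy) | !(toupper(trimws(at$elesy)) %in% c("H", "D"))
  at <- at[heavy, , drop = FALSE]

  coords <- lapply(seq_len(nrow(mapping)), function(k) {
    res <- at[at$resno == mapping$resno[k], , drop = FALSE]
    if (nrow(res) == 0L) return(NULL)
    if (criterion == "cbeta_8") {
      name <- if (any(res$elety == "CB")) "CB" else
              if (res$resid[1L] == "GLY" && any(res$elety == "CA")) "CA" else
              return(NULL)
      xyz <- res[match(name, res$elety), c("x", "y", "z")]
      matrix(as.numeric(xyz), ncol = 3L)
    } else {
      as.matrix(res[, c("x", "y", "z")])
    }
  })
  resolved_map <- !vapply(coords, is.null, logical(1))
  if (!any(resolved_map)) stop("no mapped residues found in chain ", chain)

  resolved <- logical(n_col)
  resolved[mapping$column[resolved_map]] <- TRUE
  cutoff <- if (criterion == "cbeta_8") 8.0 else 8.5
  contacts <- matrix(FALSE, n_col, n_col)
  idx <- which(resolved_map)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      d <- min_pair_dist(coords[[idx[a]]], coords[[idx[b]]])
      if (d <= cutoff) {
        ci <- mapping$column[idx[a]]; cj <- mapping$column[idx[b]]
        contacts[ci, cj] <- contacts[cj, ci] <- TRUE
      }
    }
  }
  structure(list(contacts = contacts, resolved = resolved,
                 criterion = criterion), class = "ContactMap")
}

pick_altloc <- function(at) {
  alt <- trimws(as.character(at$alt))
  alt[is.na(alt)] <- ""
  if (!any(nzchar(alt))) return(at)
  key <- paste(at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
    ix[which.max(at$o[ix])]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

min_pair_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Positive-predictive-value curve of a ranked prediction
#'
#' Walks the ranked pair list; after each counted pair, PPV(n) is the number
#' of true contacts among the first n counted pairs divided by n. Pairs
#' touching unresolved residues are skipped and do not consume a rank
#' position. `relative` mode reports PPV at `n = ceiling(f * N)` over a
#' fraction grid (default 0.1 to 2 in steps of 0.1), with N the alignment
#' length.
#'
#' @param pred a `RankedContacts`
#' @param truth a `ContactMap`
#' @param mode `"absolute"` or `"relative"`
#' @param fractions fraction grid for relative mode
#' @return a `PPVCurve` data frame with `n` (and `fraction` when relative)
#'   and `ppv`
#' @export
ppv_curve <- function(pred, truth, mode = c("absolute", "relative"),
                      fractions = seq(0.1, 2, by = 0.1)) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "ContactMap"))
  N <- nrow(truth$contacts)
  if (nrow(pred) && max(pred$i, pred$j) > N)
    stop("prediction indices exceed contact-map dimension")
  usable <- truth$resolved[pred$i] & truth$resolved[pred$j]
  hits <- truth$contacts[cbind(pred$i, pred$j)][usable]
  if (length(hits) == 0L) {
    out <- data.frame(n = integer(0), ppv = numeric(0))
    return(structure(out, class = c("PPVCurve", "data.frame"), mode = mode))
  }
  cum <- cumsum(hits)
  nvec <- seq_along(hits)
  if (mode == "absolute") {
    out <- data.frame(n = nvec, ppv = cum / nvec)
  } else {
    n_at <- pmin(ceiling(fractions * N), length(hits))
    out <- data.frame(fraction = fractions, n = n_at, ppv = cum[n_at] / n_at)
  }
  structure(out, class = c("PPVCurve", "data.frame"), mode = mode)
}

#' Mean precision at L/5, L/2 and L predictions
#'
#' For each (prediction, truth) pair, evaluates PPV at n = round(L/5),
#' round(L/2) and L, with L the protein (alignment) length, then averages
#' over proteins without weighting.
#'
#' @param pred_set list of lists, each with elements `pred`
#'   (`RankedContacts`) and `truth` (`ContactMap`)
#' @return data frame with one row per threshold: `threshold`, `mean_ppv`,
#'   `n_proteins`
#' @export
mean_ppv_at <- function(pred_set) {
  stopifnot(length(pred_set) >= 1L)
  per <- vapply(pred_set, function(el) {
    curve <- ppv_curve(el$pred, el$truth, mode = "absolute")
    L <- nrow(el$truth$contacts)
    at <- function(n) {
      n <- min(max(1L, n), nrow(curve))
      curve$ppv[n]
    }
    c(at(round(L / 5)), at(round(L / 2)), at(L))
  }, numeric(3))
  data.frame(threshold = c("L/5", "L/2", "L"),
             mean_ppv = rowMeans(per),
             n_proteins = length(pred_set))
}

#' Weighted moving average with arithmetically decreasing weights
#'
#' Smooths a series with a window of `2w + 1` values centred on each
#' position; the centre is weighted `w`, offsets +-k are weighted `w - k`
#' (so offsets at `|k| >= w` get zero weight). The window and its weights
#' are truncated at the series boundaries.
#'
#' @param series numeric vector
#' @param w half-window size, `>= 1`; `w = 1` returns the series unchanged
#' @export
weighted_moving_average <- function(series, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 1)
    stop("parameter error: w must be a single integer >= 1")
  w <- as.integer(w)
  n <- length(series)
  out <- numeric(n)
  offs <- -w:w
  wts <- pmax(w - abs(offs), 0)
  for (t in seq_len(n)) {
    pos <- t + offs
    ok <- pos >= 1L & pos <= n & wts > 0
    out[t] <- sum(wts[ok] * series[pos[ok]]) / sum(wts[ok])
  }
  out
}

#' Write a contact map as an `i j` pair list
#'
#' @param map a `ContactMap`
#' @param path output file
#' @export
export_contact_map <- function(map, path) {
  stopifnot(inherits(map, "ContactMap"))
  up <- which(upper.tri(map$contacts) & map$contacts, arr.ind = TRUE)
  write.table(up[order(up[, 1L], up[, 2L]), , drop = FALSE], path,
              sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
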