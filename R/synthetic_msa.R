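#' Plant a sparse Potts model with known contact support
#'
#' Builds a ground-truth model for recovery experiments: `n_pairs` distinct
#' position pairs with sequence separation >= 5 receive random coupling
#' blocks drawn in the zero-sum gauge and rescaled to a common Frobenius
#' norm; all other blocks are exactly zero. Fields are i.i.d. Gaussian.
#' Because the planted blocks are already in the inference gauge, generation
#' truth and post-fit gauge coincide.
#'
#' Each block starts from `block_sparsity` random cells set to +-1 — real
#' contact energetics favour a handful of residue-pair combinations rather
#' than perturbing all q x q combinations at once — and is then projected to
#' the zero-sum gauge and rescaled, so the declared Frobenius norm is exact.
#'
#' @param N alignment length
#' @param n_pairs number of coupled pairs (separation >= 5)
#' @param coupling_strength Frobenius norm of every planted block
#' @param field_scale standard deviation of the fields
#' @param seed RNG seed (model is reproducible from it)
#' @param q alphabet size (default 21)
#' @param block_sparsity number of seeded +-1 cells per block before the
#'   gauge projection
#' @return a `PlantedModel`: list with `params` ([potts_parameters()]),
#'   `true_pairs` (data frame i < j), `seed`
#' @export
make_planted_model <- function(N, n_pairs, coupling_strength = 5,
                               field_scale = 0, seed = 1L, q = 21L,
                               block_sparsity = 4L) {
  eligible <- which(outer(seq_len(N), seq_len(N),
                          function(i, j) j - i >= 5L), arr.ind = TRUE)
  if (n_pairs > nrow(eligible))
    stop("n_pairs exceeds the ", nrow(eligible),
         " pairs with separation >= 5")
  set.seed(seed)
  pick <- if (n_pairs > 0L)
    eligible[sample.int(nrow(eligible), n_pairs), , drop = FALSE]
  else eligible[0L, , drop = FALSE]
  J <- array(0, c(q, q, N, N))
  for (k in seq_len(n_pairs)) {
    repeat {
      M <- matrix(0, q, q)
      M[cbind(sample.int(q, block_sparsity, replace = TRUE),
              sample.int(q, block_sparsity, replace = TRUE))] <-
        sample(c(-1, 1), block_sparsity, replace = TRUE)
      blk <- zero_sum_gauge(M)
      if (sum(blk^2) > 1e-12) break   # seeded cells can cancel; redraw
    }
    blk <- blk * (coupling_strength / sqrt(sum(blk^2)))
    i <- pick[k, 1L]; j <- pick[k, 2L]
    J[, , i, j] <- blk
    J[, , j, i] <- t(blk)
  }
  h <- matrix(rnorm(q * N, sd = field_scale), q, N)
  true_pairs <- data.frame(i = pick[, 1L], j = pick[, 2L])
  true_pairs <- true_pairs[order(true_pairs$i, true_pairs$j), , drop = FALSE]
  rownames(true_pairs) <- NULL
  structure(list(params = potts_parameters(h, J), true_pairs = true_pairs,
                 seed = seed), class = "PlantedModel")
}

#' Sample an alignment from a Potts(+gap) model by Gibbs sampling
#'
#' Runs a single-site Gibbs chain over the model's conditionals (gap-run
#' energies included when `use_gaps`); a row is recorded after
#' `burn_in + k * thinning` full sweeps for k = 1..B. Gap parameters are
#' clamped to |g| <= 10 to keep the chain away from degenerate all-gap
#' attractors.
#'
#' @param model a `PlantedModel` or [potts_parameters()] object
#' @param B number of rows to draw
#' @param burn_in sweeps discarded before recording (default 100)
#' @param thinning sweeps between recorded rows (default 10)
#' @param seed RNG seed
#' @param use_gaps include the model's gap-run energies
#' @return an `EncodedMSA` with unit weights; the seed is kept in
#'   `attr(, "seed")`
#' @export
sample_msa_gibbs <- function(model, B, burn_in = 100L, thinning = 10L,
                             seed = 1L, use_gaps = FALSE) {
  params <- if (inherits(model, "PlantedModel")) model$params else model
  stopifnot(inherits(params, "PottsParameters"), B >= 1L)
  q <- params$q; N <- params$N
  gtab <- matrix(0, N, max(1L, params$gaps$max_length_L %||% 1L))
  if (use_gaps && !is.null(params$gaps)) {
    ent <- params$gaps$entries
    if (length(ent)) {
      il <- do.call(rbind, lapply(strsplit(names(ent), ":"), as.integer))
      gtab[il] <- pmax(pmin(ent, 10), -10)
    }
  }
  set.seed(seed)
  data <- gibbs_sample_cpp(params$h, as.numeric(params$J), q, as.integer(B),
                           as.integer(burn_in), as.integer(thinning),
                           use_gaps, gtab)
  msa <- new_encoded_msa(data, q = q)
  attr(msa, "seed") <- seed
  msa
}

#' Specification of an injected gap stretch
#'
#' Describes the long shared gap stretches real alignments acquire from
#' modular insertions/deletions: a column range, the fraction of rows that
#' carry the stretch, and whether each affected row is gapped over the full
#' range or over a random-length prefix of it.
#'
#' @param column_range integer `c(start, end)`, 1-based inclusive
#' @param fraction_of_rows fraction in (0, 1] of rows to modify
#' @param pattern `"full_range"` or `"random_length"`
#' @export
gap_injection_spec <- function(column_range, fraction_of_rows,
                               pattern = c("full_range", "random_length")) {
  pattern <- match.arg(pattern)
  stopifnot(length(column_range) == 2L,
            column_range[1L] >= 1L, column_range[2L] >= column_range[1L],
            fraction_of_rows > 0, fraction_of_rows <= 1)
  structure(list(column_range = as.integer(column_range),
                 fraction_of_rows = fraction_of_rows, pattern = pattern),
            class = "GapInjectionSpec")
}

#' Overwrite a column range with gaps in a random subset of rows
#'
#' @param msa an `EncodedMSA`
#' @param spec a [gap_injection_spec()]
#' @param seed RNG seed selecting the affected rows (and prefix lengths for
#'   `random_length`)
#' @return the modified `EncodedMSA`; affected row indices are kept in
#'   `attr(, "modified_rows")`
#' @export
inject_gap_stretches <- function(msa, spec, seed = 1L) {
  stopifnot(inherits(msa, "EncodedMSA"), inherits(spec, "GapInjectionSpec"))
  B <- nrow(msa$data); N <- ncol(msa$data)
  if (spec$column_range[2L] > N) stop("column range exceeds alignment width")
  set.seed(seed)
  n_mod <- round(spec$fraction_of_rows * B)
  rows <- sort(sample.int(B, n_mod))
  s <- spec$column_range[1L]; e <- spec$column_range[2L]
  if (spec$pattern == "full_range") {
    msa$data[rows, s:e] <- 0L
  } else {
    lens <- sample.int(e - s + 1L, n_mod, replace = TRUE)
    for (k in seq_along(rows))
      msa$data[rows[k], s:(s + lens[k] - 1L)] <- 0L
  }
  attr(msa, "modified_rows") <- rows
  msa
}

#' Synthetic structure fixture with a closed-form contact map
#'
#' Emits PDB-format text for a toy backbone, the identity column-to-residue
#' mapping, and the C-beta contact map implied by the coordinates. Residue 1
#' is glycine (C-alpha stands in for its C-beta); all others are alanine
#' with an explicit C-beta. Geometries: `"straight"` — a straight chain with
#' 3.8 A spacing, so contacts are exactly the pairs with |i - j| <= 2;
#' `"hairpin"` — two antiparallel strands whose facing C-beta atoms sit 6 A
#' apart, adding long-range contacts between hairpin partners.
#'
#' @param N number of residues (>= 4 for the hairpin)
#' @param seed recorded for provenance (the geometry is deterministic)
#' @param geometry `"straight"` or `"hairpin"`
#' @return list with `pdb_text` (character vector of PDB lines), `mapping`
#'   (identity data frame), `map` (`ContactMap`, cbeta_8), `seed`
#' @export
toy_structure_fixture <- function(N, seed = 1L,
                                  geometry = c("straight", "hairpin")) {
  geometry <- match.arg(geometry)
  stopifnot(N >= 2L, geometry == "straight" || N >= 4L)
  if (geometry == "straight") {
    ca <- cbind(3.8 * (seq_len(N) - 1), 0, 0)
    cb <- cbind(3.8 * (seq_len(N) - 1), 1.0, 0)
  } else {
    M <- ceiling(N / 2)
    ca <- matrix(0, N, 3); cb <- matrix(0, N, 3)
    for (i in seq_len(N)) {
      if (i <= M) {
        ca[i, ] <- c(3.8 * (i - 1), 0, 0)
        cb[i, ] <- c(3.8 * (i - 1), 0.5, 0)
      } else {
        k <- i - M
        ca[i, ] <- c(3.8 * (M - k), 7.0, 0)
        cb[i, ] <- c(3.8 * (M - k), 6.5, 0)
      }
    }
  }
  cb[1L, ] <- ca[1L, ]  # glycine: C-alpha stands in for C-beta
  d <- as.matrix(dist(cb))
  contacts <- d <= 8.0
  diag(contacts) <- FALSE
  dimnames(contacts) <- NULL
  map <- structure(list(contacts = contacts, resolved = rep(TRUE, N),
                        criterion = "cbeta_8"), class = "ContactMap")

  lines <- character(0)
  serial <- 0L
  emit <- function(name, resn, resno, xyz, elem) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, sprintf(" %-3s", name), resn, "A", resno,
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
  }
  for (i in seq_len(N)) {
    resn <- if (i == 1L) "GLY" else "ALA"
    lines <- c(lines, emit("CA", resn, i, ca[i, ], "C"))
    if (i > 1L) lines <- c(lines, emit("CB", resn, i, cb[i, ], "C"))
  }
  lines <- c(lines, "TER", "END")
  list(pdb_text = lines,
       mapping = data.frame(column = seq_len(N), resno = seq_len(N)),
       map = map, seed = seed)
}
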