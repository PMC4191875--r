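#' Regularization configuration
#'
#' L2 penalty strengths applied to the weight-normalized per-site
#' pseudo-likelihood objective. The defaults (0.01 for fields, couplings and
#' gap-run parameters alike) follow common practice in the asymmetric
#' pseudo-likelihood lineage; inference is over-parameterized relative to
#' typical alignment depths, so some shrinkage is always required.
#'
#' @param lambda_h penalty on fields
#' @param lambda_J penalty on couplings
#' @param lambda_g penalty on gap-run parameters
#' @export
reg_config <- function(lambda_h = 0.01, lambda_J = 0.01, lambda_g = 0.01) {
  stopifnot(lambda_h >= 0, lambda_J >= 0, lambda_g >= 0)
  structure(list(lambda_h = lambda_h, lambda_J = lambda_J,
                 lambda_g = lambda_g), class = "reg_config")
}

#' Optimizer settings for per-site fits
#'
#' Per-site conditionals are maximized with L-BFGS-B from zero
#' initialization, so fits are deterministic without any seed. A site is
#' flagged converged when the final gradient max-norm is below `grad_tol`.
#'
#' @param maxit iteration cap per site
#' @param grad_tol gradient max-norm tolerance (optim's `pgtol`)
#' @param factr relative objective-change stopping factor (see
#'   [stats::optim]); kept tight so `grad_tol` is the operative criterion
#' @export
optim_settings <- function(maxit = 500L, grad_tol = 1e-5, factr = 1e4) {
  structure(list(maxit = as.integer(maxit), grad_tol = grad_tol,
                 factr = factr), class = "optim_settings")
}

#' Sparse table of gap-run parameters
#'
#' Holds propensities g_i^l for a maximal gap run of length `l` beginning at
#' column `i`. Absent entries are implicitly zero.
#'
#' @param starts,lengths,values parallel vectors defining the entries
#' @param n_col alignment length N (bounds check)
#' @param max_length_L largest run length carried by the table
#' @export
gap_run_table <- function(starts = integer(0), lengths = integer(0),
                          values = numeric(0), n_col,
                          max_length_L = max(lengths, 1L)) {
  stopifnot(length(starts) == length(lengths),
            length(starts) == length(values))
  if (length(starts)) {
    stopifnot(all(lengths >= 1L), all(lengths <= max_length_L),
              all(starts >= 1L), all(starts + lengths - 1L <= n_col))
  }
  entries <- setNames(as.numeric(values), paste(starts, lengths, sep = ":"))
  structure(list(entries = entries, max_length_L = as.integer(max_length_L),
                 n_col = as.integer(n_col)), class = "GapRunTable")
}

gap_lookup <- function(gaps, start, len) {
  if (is.null(gaps) || len > gaps$max_length_L) return(0)
  v <- unname(gaps$entries[paste(start, len, sep = ":")])
  if (is.na(v)) 0 else v
}

# consecutive gap counts immediately left/right of column r, per row
gap_flanks <- function(data, r) {
  B <- nrow(data); N <- ncol(data)
  lam <- integer(B); alive <- rep(TRUE, B)
  j <- r - 1L
  while (j >= 1L) {
    alive <- alive & (data[, j] == 0L)
    if (!any(alive)) break
    lam <- lam + alive
    j <- j - 1L
  }
  rho <- integer(B); alive <- rep(TRUE, B)
  j <- r + 1L
  while (j <= N) {
    alive <- alive & (data[, j] == 0L)
    if (!any(alive)) break
    rho <- rho + alive
    j <- j + 1L
  }
  list(lam = lam, rho = rho)
}

# longest maximal gap run anywhere in the alignment: the model's
# meta-parameter L; 0 for gap-free data (no gap parameters at all)
alignment_max_gap_run <- function(data) {
  if (!any(data == 0L)) return(0L)
  max(apply(data == 0L, 1L, function(g) {
    r <- rle(g); m <- r$lengths[r$values]; if (length(m)) max(m) else 0L
  }))
}

# The gap-run parameters a site-r conditional can touch: toggling site r in
# row s either merges the flanking runs into one run of length lam+rho+1
# starting at r-lam (site r gapped) or leaves the two flanking runs (site r
# occupied). Runs longer than max_len (the meta-parameter L) carry no
# parameter and are dropped. Returns the unique key set and per-row 1-based
# indices into it.
site_gap_index <- function(data, r, max_len = alignment_max_gap_run(data)) {
  fl <- gap_flanks(data, r)
  lam <- fl$lam; rho <- fl$rho
  key0 <- paste(r - lam, lam + rho + 1L, sep = ":")
  keyL <- ifelse(lam > 0L, paste(r - lam, lam, sep = ":"), NA)
  keyR <- ifelse(rho > 0L, paste(r + 1L, rho, sep = ":"), NA)
  keys <- unique(c(key0, keyL[!is.na(keyL)], keyR[!is.na(keyR)]))
  keylen <- as.integer(vapply(strsplit(keys, ":"), `[`, "", 2L))
  keys <- keys[keylen <= max_len]
  idx <- function(k) { m <- match(k, keys); m[is.na(m)] <- 0L; as.integer(m) }
  list(keys = keys, gidx0 = idx(key0), gidxL = idx(keyL), gidxR = idx(keyR),
       lam = lam, rho = rho)
}

#' Local gap-run energy of a candidate state
#'
#' Difference the total gap-run energy of a sequence makes when column `r`
#' takes `candidate_state`, all other columns held fixed. With `lam`
#' consecutive gaps immediately left of `r` and `rho` immediately right:
#' a gap at `r` activates the merged run g_(r-lam)^(lam+rho+1); a non-gap
#' leaves the flanking runs g_(r-lam)^lam and g_(r+1)^rho (each only if
#' nonempty). Absent table entries contribute zero.
#'
#' @param row full-length encoded row; the value at position `r` is ignored
#' @param r 1-based column index
#' @param candidate_state integer state in `0..(q-1)`
#' @param gaps a [gap_run_table()] (or NULL for no gap energy)
#' @export
local_gap_energy <- function(row, r, candidate_state, gaps) {
  N <- length(row)
  if (r < 1L || r > N) stop("index error: column ", r, " outside 1..", N)
  lam <- 0L; j <- r - 1L
  while (j >= 1L && row[j] == 0L) { lam <- lam + 1L; j <- j - 1L }
  rho <- 0L; j <- r + 1L
  while (j <= N && row[j] == 0L) { rho <- rho + 1L; j <- j + 1L }
  if (candidate_state == 0L) {
    gap_lookup(gaps, r - lam, lam + rho + 1L)
  } else {
    (if (lam > 0L) gap_lookup(gaps, r - lam, lam) else 0) +
      (if (rho > 0L) gap_lookup(gaps, r + 1L, rho) else 0)
  }
}

#' Construct a Potts parameter set
#'
#' @param h q x N field matrix
#' @param J q x q x N x N coupling array, `J[, , i, j]` the block for the
#'   ordered pair (i, j) with `J[, , j, i]` its transpose; diagonal blocks 0
#' @param gaps optional [gap_run_table()]
#' @export
potts_parameters <- function(h, J, gaps = NULL) {
  q <- nrow(h); N <- ncol(h)
  stopifnot(identical(dim(J), c(q, q, N, N)))
  structure(list(h = h, J = J, gaps = gaps, q = q, N = N),
            class = "PottsParameters")
}

#' Conditional log-probabilities of states at one site
#'
#' Log of P(a_r = s | rest of the row) under the (gap-extended) Potts model:
#' the soft-max of h_r(s) + sum_i J_ri(s, a_i) plus, when `use_gaps`, the
#' local gap-run energy.
#'
#' @param row full-length encoded row (entry at `r` ignored)
#' @param r conditioned column
#' @param params a [potts_parameters()] object
#' @param use_gaps include the gap-run energy term
#' @return length-q vector of log-probabilities (exp sums to 1)
#' @export
conditional_logprobs <- function(row, r, params, use_gaps = FALSE) {
  q <- params$q; N <- params$N
  if (r < 1L || r > N) stop("index error: column ", r, " outside 1..", N)
  e <- params$h[, r]
  for (j in seq_len(N)) {
    if (j == r) next
    e <- e + params$J[, row[j] + 1L, r, j]
  }
  if (use_gaps && !is.null(params$gaps)) {
    e[1L] <- e[1L] + local_gap_energy(row, r, 0L, params$gaps)
    eg <- local_gap_energy(row, r, 1L, params$gaps)
    e[-1L] <- e[-1L] + eg
  }
  if (any(!is.finite(e))) stop("numeric error: non-finite parameter energy")
  e - log_sum_exp(e)
}

log_sum_exp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# flat parameter vector layout shared with the C++ objective
theta_length <- function(q, N, n_g) q + N * q * q + n_g

flatten_site_params <- function(h, J, g, q, N, keys) {
  th <- numeric(theta_length(q, N, length(keys)))
  th[seq_len(q)] <- h
  th[q + seq_len(N * q * q)] <- as.numeric(J)
  if (length(keys)) {
    m <- match(names(g), keys)
    th[q + N * q * q + m[!is.na(m)]] <- g[!is.na(m)]
  }
  th
}

#' Per-site pseudo-likelihood objective and gradient
#'
#' Weighted negative conditional log-likelihood of column `r` given the
#' rest, normalized by `b_eff`, plus the L2 penalties of `reg`; the
#' gradient is exact. Mainly useful for inspection and testing — fitting
#' goes through [fit_site()] / [fit_model()].
#'
#' @param msa an `EncodedMSA` (weighted)
#' @param r conditioned column
#' @param site_params list with `h` (length q), `J` (q x q x N, slice i the
#'   block against column i; slice r ignored) and optional named vector `g`
#'   of gap parameters keyed `"start:length"`
#' @param reg a [reg_config()]
#' @param use_gaps include gap-run terms
#' @param max_gap_length cap on parameterized run lengths (the model's
#'   meta-parameter L); defaults to the longest run observed in the data
#' @return list with `objective` and `gradient` (same shapes as
#'   `site_params`)
#' @export
site_objective_and_gradient <- function(msa, r, site_params,
                                        reg = reg_config(),
                                        use_gaps = FALSE,
                                        max_gap_length = NULL) {
  stopifnot(inherits(msa, "EncodedMSA"))
  q <- msa$q; N <- ncol(msa$data)
  gi <- if (use_gaps)
          site_gap_index(msa$data, r,
                         max_gap_length %||% alignment_max_gap_run(msa$data))
        else list(keys = character(0),
                  gidx0 = integer(nrow(msa$data)),
                  gidxL = integer(nrow(msa$data)),
                  gidxR = integer(nrow(msa$data)))
  g <- site_params$g %||% numeric(0)
  keys <- union(gi$keys, names(g))
  gi2 <- remap_gap_index(gi, keys)
  th <- flatten_site_params(site_params$h, site_params$J, g, q, N, keys)
  res <- plm_site_obj_grad(msa$data, msa$weights, r, th, q,
                           reg$lambda_h, reg$lambda_J, reg$lambda_g,
                           logical(N), use_gaps,
                           gi2$gidx0, gi2$gidxL, gi2$gidxR, length(keys))
  gr <- res$gradient
  list(objective = res$objective,
       gradient = list(h = gr[seq_len(q)],
                       J = array(gr[q + seq_len(N * q * q)], c(q, q, N)),
                       g = setNames(gr[q + N * q * q + seq_along(keys)],
                                    keys)))
}

remap_gap_index <- function(gi, keys) {
  if (identical(gi$keys, keys)) return(gi)
  remap <- match(gi$keys, keys)
  fix <- function(ix) { out <- ifelse(ix > 0L, remap[ix], 0L)
                        out[is.na(out)] <- 0L; as.integer(out) }
  list(keys = keys, gidx0 = fix(gi$gidx0), gidxL = fix(gi$gidxL),
       gidxR = fix(gi$gidxR))
}

#' Fit one site's conditional model
#'
#' Minimizes the per-site objective by L-BFGS-B from zero initialization.
#' Deterministic given settings; non-convergence within the iteration cap is
#' flagged, not fatal.
#'
#' @inheritParams site_objective_and_gradient
#' @param settings an [optim_settings()]
#' @param mask logical length-N vector; TRUE partners are frozen at zero
#'   coupling (used by decimation); column `r` is always excluded
#' @return list with `h`, `J` (q x q x N, slice r zero), `g` (named vector),
#'   `objective`, `converged`, `grad_max`, `counts`
#' @export
fit_site <- function(msa, r, reg = reg_config(), use_gaps = FALSE,
                     settings = optim_settings(), mask = NULL,
                     max_gap_length = NULL) {
  stopifnot(inherits(msa, "EncodedMSA"))
  q <- msa$q; N <- ncol(msa$data); B <- nrow(msa$data)
  if (is.null(mask)) mask <- logical(N)
  stopifnot(length(mask) == N)
  gi <- if (use_gaps)
          site_gap_index(msa$data, r,
                         max_gap_length %||% alignment_max_gap_run(msa$data))
        else list(keys = character(0), gidx0 = integer(B),
                  gidxL = integer(B), gidxR = integer(B))
  n_g <- length(gi$keys)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (is.null(cache$theta) || !identical(th, cache$theta)) {
      cache$res <- plm_site_obj_grad(msa$data, msa$weights, r, th, q,
                                     reg$lambda_h, reg$lambda_J,
                                     reg$lambda_g, mask, use_gaps,
                                     gi$gidx0, gi$gidxL, gi$gidxR, n_g)
      cache$theta <- th
    }
    cache$res
  }
  th0 <- numeric(theta_length(q, N, n_g))
  opt <- optim(th0, fn = function(th) eval_at(th)$objective,
               gr = function(th) eval_at(th)$gradient,
               method = "L-BFGS-B",
               control = list(maxit = settings$maxit,
                              pgtol = settings$grad_tol,
                              factr = settings$factr))
  final <- eval_at(opt$par)
  grad_max <- max(abs(final$gradient))
  list(h = opt$par[seq_len(q)],
       J = array(opt$par[q + seq_len(N * q * q)], c(q, q, N)),
       g = setNames(opt$par[q + N * q * q + seq_len(n_g)], gi$keys),
       objective = opt$value,
       converged = grad_max <= settings$grad_tol * (1 + 1e-8),
       grad_max = grad_max,
       counts = opt$counts)
}

#' Fit the full model by asymmetric pseudo-likelihood
#'
#' Fits every site's conditional independently (sites are separable, so the
#' result is identical under any execution order or degree of parallelism),
#' then symmetrizes the two directed coupling estimates of each pair and
#' applies the zero-sum gauge block-wise. Gap-run parameters are per-site
#' nuisance parameters: they absorb gap-stretch statistics during inference
#' and are reported per site, but only the couplings feed contact scoring.
#'
#' Duplicate alignment rows are collapsed to (pattern, summed weight) pairs
#' before fitting; the objective is unchanged by this.
#'
#' @inheritParams fit_site
#' @param cores number of worker processes (forked; results identical to
#'   serial execution)
#' @param mask optional N x N logical matrix of pair blocks frozen at zero
#' @return a `FitResult`: gauge-fixed symmetric couplings in
#'   `$params$J` (q x q x N x N), fields in `$params$h`, per-site
#'   objectives, convergence flags, per-site gap parameters, config echo
#' @export
fit_model <- function(msa, reg = reg_config(), use_gaps = FALSE,
                      settings = optim_settings(), cores = 1L,
                      mask = NULL, max_gap_length = NULL) {
  stopifnot(inherits(msa, "EncodedMSA"))
  N <- ncol(msa$data); q <- msa$q
  if (N < 2L) stop("alignment must have at least 2 columns")
  if (is.null(mask)) mask <- matrix(FALSE, N, N)
  stopifnot(identical(dim(mask), c(N, N)))
  cmsa <- collapse_duplicates(msa)
  L_meta <- max_gap_length %||% alignment_max_gap_run(cmsa$data)
  one <- function(r) fit_site(cmsa, r, reg, use_gaps, settings,
                              mask = mask[r, ], max_gap_length = L_meta)
  sites <- if (cores > 1L) {
    parallel::mclapply(seq_len(N), one, mc.cores = cores)
  } else {
    lapply(seq_len(N), one)
  }
  h <- vapply(sites, `[[`, numeric(q), "h")
  Jsym <- symmetrize_couplings(lapply(sites, `[[`, "J"))
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    blk <- zero_sum_gauge(Jsym[, , i, j])
    Jsym[, , i, j] <- blk
    Jsym[, , j, i] <- t(blk)
  }
  structure(list(
    params = potts_parameters(h, Jsym),
    per_site_objectives = vapply(sites, `[[`, numeric(1), "objective"),
    converged_flags = vapply(sites, `[[`, logical(1), "converged"),
    site_gap_params = lapply(sites, `[[`, "g"),
    config = list(reg = reg, use_gaps = use_gaps, settings = settings,
                  mask = mask, max_gap_length = L_meta),
    msa_info = list(B = nrow(msa$data), b_eff = msa$b_eff, q = q, N = N)),
    class = "FitResult")
}

collapse_duplicates <- function(msa) {
  key <- apply(msa$data, 1L, paste, collapse = ",")
  if (!anyDuplicated(key)) return(msa)
  first <- !duplicated(key)
  wsum <- tapply(msa$weights, key, sum)
  data <- msa$data[first, , drop = FALSE]
  w <- as.numeric(wsum[key[first]])
  out <- msa
  out$data <- data
  out$weights <- w
  out$ids <- msa$ids[first]
  out
}

#' Symmetrize directed coupling estimates
#'
#' The asymmetric fit produces two estimates of each pair block: J_ij seen
#' from site i and J_ji seen from site j. The symmetrized block is their
#' average, `(J_i[ , , j] + t(J_j[ , , i])) / 2`.
#'
#' @param J_list list over sites r of q x q x N arrays from [fit_site()]
#' @return q x q x N x N array with `J[, , j, i] = t(J[, , i, j])`
#' @export
symmetrize_couplings <- function(J_list) {
  N <- length(J_list)
  q <- dim(J_list[[1L]])[1L]
  J <- array(0, c(q, q, N, N))
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    blk <- (J_list[[i]][, , j] + t(J_list[[j]][, , i])) / 2
    J[, , i, j] <- blk
    J[, , j, i] <- t(blk)
  }
  J
}

#' Zero-sum (Ising) gauge of a coupling block
#'
#' Shifts a q x q block so every row and column sums to zero:
#' `J'(a,b) = J(a,b) - mean_a J(., b) - mean_b J(a, .) + mean J`. This is
#' the gauge in which Frobenius-norm scoring is meaningful; it is an
#' idempotent linear projection.
#'
#' @param M q x q matrix
#' @export
zero_sum_gauge <- function(M) {
  rm <- rowMeans(M); cm <- colMeans(M); mm <- mean(M)
  M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), cm) + mm
}

#' Save / load a fit result
#'
#' The container is R's RDS serialization of the `FitResult` list (gauge-
#' fixed couplings, fields, config and convergence metadata); the round
#' trip is lossless.
#'
#' @param fit a `FitResult`
#' @param path file path
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "FitResult"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "FitResult"))
  fit
}
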