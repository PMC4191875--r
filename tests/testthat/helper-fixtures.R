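# shared fixture builders and brute-force oracles

write_tmp_fasta <- function(rows, ids = paste0("s", seq_along(rows))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", rows), path)
  path
}

rand_msa <- function(B, N, q = 21L, gap_frac = 0.1, seed = 1L) {
  set.seed(seed)
  data <- matrix(sample.int(q, B * N, replace = TRUE) - 1L, B, N)
  if (gap_frac > 0) {
    ng <- round(gap_frac * B * N)
    data[sample.int(B * N, ng)] <- 0L
  }
  new_encoded_msa(data, q = q)
}

# O(B^2) reweighting oracle built directly on sequence_identity
bf_weights <- function(data, threshold_x) {
  B <- nrow(data)
  n <- integer(B)
  for (s in seq_len(B)) {
    for (t in seq_len(B)) {
      if (sequence_identity(data[s, ], data[t, ]) >= 1 - threshold_x)
        n[s] <- n[s] + 1L
    }
  }
  1 / n
}

# exact joint distribution of a two-site model (fields h q x 2, block q x q)
enum_joint_n2 <- function(h, blk) {
  q <- nrow(h)
  E <- outer(seq_len(q), seq_len(q),
             Vectorize(function(a, b) h[a, 1] + h[b, 2] + blk[a, b]))
  P <- exp(E - max(E))
  P / sum(P)
}

# scoring tests build fit containers directly from a coupling array
fake_fit <- function(J, h = NULL) {
  q <- dim(J)[1L]; N <- dim(J)[3L]
  if (is.null(h)) h <- matrix(0, q, N)
  structure(list(params = potts_parameters(h, J)), class = "FitResult")
}

symmetric_J <- function(q, N, seed = 1L, gauge = FALSE) {
  set.seed(seed)
  J <- array(0, c(q, q, N, N))
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    blk <- matrix(rnorm(q * q), q, q)
    if (gauge) blk <- zero_sum_gauge(blk)
    J[, , i, j] <- blk
    J[, , j, i] <- t(blk)
  }
  J
}

# PDB ATOM record with the fixed-column layout the benchmark reader expects
pdb_atom <- function(serial, name, resn, resno, x, y, z,
                     chain = "A", elem = "C", alt = " ", occ = 1.00) {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), alt, resn, chain, resno,
          x, y, z, occ, 0.00, elem)
}

write_tmp_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "TER", "END"), path)
  path
}
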