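# independent oracles used by several test files; deliberately naive
# implementations that never share code with the functions they check

# bound fraction by bisection on the mass balance:
# free L satisfies  L_free + P*L_free/(Kd + L_free) = L_tot
oracle_bound_fraction <- function(p_tot, l_tot, kd) {
  if (l_tot == 0) {
    return(0)
  }
  f <- function(l_free) l_free + p_tot * l_free / (kd + l_free) - l_tot
  lo <- 0
  hi <- l_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  l_free <- (lo + hi) / 2
  (l_free / (kd + l_free)) # fraction of P bound = [PL]/P = L_free/(Kd+L_free)
}

# brute-force per-column conservation counter
oracle_conservation <- function(seq_mat, ref_idx, min_species) {
  ref <- seq_mat[ref_idx, ]
  cols <- which(ref != "-")
  vapply(cols, function(j) {
    hits <- 0L
    for (i in seq_len(nrow(seq_mat))) {
      if (seq_mat[i, j] == ref[j]) hits <- hits + 1L
    }
    hits >= min_species
  }, logical(1))
}

# random gapped toy alignment written to a FASTA file; returns path + matrix
random_msa_fixture <- function(n_seq, n_col, gap_prob = 0.15) {
  letters_aa <- c("A", "R", "G", "S", "K", "E", "D", "V", "L", "T")
  mat <- matrix(
    sample(letters_aa, n_seq * n_col, replace = TRUE),
    nrow = n_seq
  )
  gaps <- matrix(runif(n_seq * n_col) < gap_prob, nrow = n_seq)
  mat[gaps] <- "-"
  # keep the reference row from being all gaps
  if (all(mat[1, ] == "-")) mat[1, 1] <- "A"
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(
    unlist(lapply(seq_len(n_seq), function(i) {
      c(paste0(">seq", i), paste(mat[i, ], collapse = ""))
    })),
    path
  )
  list(path = path, mat = mat)
}

# small noiseless truth used across files; tight segments for speed
tiny_truth <- function(...) {
  synthetic_truth(
    first_residue = 1, last_residue = 60,
    helix_segment = c(21, 31),
    broadened_segment = c(41, 50),
    binding_segment = c(45, 55),
    noise_sd = 0,
    seed = 42,
    ...
  )
}
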