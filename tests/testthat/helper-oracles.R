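# Independent brute-force implementations of the entropy definitions, coded
# directly from the formulas with explicit loops over an explicit transition
# matrix. They deliberately share no code with the package internals.

oracle_stationary <- function(states) {
  cells <- unique(states)
  p <- numeric(length(cells))
  for (i in seq_along(cells)) p[i] <- sum(states == cells[i]) / length(states)
  H <- 0
  for (i in seq_along(cells)) H <- H - p[i] * log2(p[i])
  Hmax <- log2(length(cells))
  list(H = H, Hmax = Hmax, Hnorm = if (Hmax > 0) H / Hmax else 0)
}

oracle_transition <- function(states) {
  cells <- unique(states)
  k <- length(cells)
  n <- length(states)
  # explicit first-order transition count matrix
  M <- matrix(0, k, k, dimnames = list(cells, cells))
  for (t in seq_len(n - 1)) {
    M[states[t], states[t + 1]] <- M[states[t], states[t + 1]] + 1
  }
  diag(M) <- 0  # self-transitions excluded
  n_pairs <- sum(M > 0)
  if (n_pairs == 0) return(list(H = 0, Hmax = 0, Hnorm = 0, degenerate = TRUE))
  # outer weights: empirical fixation proportions over the whole bin
  H <- 0
  for (i in seq_len(k)) {
    row_total <- sum(M[i, ])
    if (row_total == 0) next
    p_i <- sum(states == cells[i]) / n
    inner <- 0
    for (j in seq_len(k)) {
      if (M[i, j] > 0) {
        pij <- M[i, j] / row_total
        inner <- inner - pij * log2(pij)
      }
    }
    H <- H + p_i * inner
  }
  Hmax <- log2(n_pairs)
  list(H = H, Hmax = Hmax,
       Hnorm = if (Hmax > 0) H / Hmax else 0, degenerate = FALSE)
}

random_state_seq <- function(n_max = 50, k_max = 9) {
  n <- sample(2:n_max, 1)
  k <- sample(1:k_max, 1)
  sample(letters[seq_len(k)], n, replace = TRUE)
}

# constant-position gaze samples at 50 Hz, convenience for detection tests
const_samples <- function(n, x, y, t0 = 0, valid = TRUE, step = 20) {
  gaze_samples(seq(t0, by = step, length.out = n), rep(x, n), rep(y, n),
               valid = valid)
}
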