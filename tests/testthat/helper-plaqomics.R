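# shared fixtures and independent oracles used across test files

# tiny spectral-count matrix with a sprinkling of zeros
toy_counts <- function(seed = 42, n_proteins = 40, zero_rate = 0.1) {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = seed, n_proteins = n_proteins, zero_rate = zero_rate))
  sim$matrix
}

# exam with a single plaque placed at one site
exam_with_plaque <- function(subject_id, visit, side, segment, wall,
                             thickness, narrowing = 0) {
  e <- blank_exam(subject_id, visit)
  i <- e$side == side & e$segment == segment & e$wall == wall
  e$thickness_mm[i] <- thickness
  art <- ifelse(grepl("ica", segment), "ica", "cca")
  j <- e$side == side & grepl(art, e$segment)
  e$narrowing_pct[j] <- narrowing
  e
}

# brute-force concordance oracle: explicit double loop over subject pairs
brute_force_c <- function(pred, outcomes = NULL, survival = FALSE,
                          times = NULL, status = NULL) {
  n <- length(pred)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      usable <- if (survival) {
        status[i] == 1 && times[i] < times[j]
      } else {
        outcomes[i] == 1 && outcomes[j] == 0
      }
      if (!usable) next
      den <- den + 1
      if (pred[i] > pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  num / den
}

# definitional Pearson r oracle
brute_force_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
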