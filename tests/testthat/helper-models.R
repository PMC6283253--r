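# Shared fixtures: random schedule generators and independent brute-force
# oracles kept deliberately separate from the implementation paths they
# check.

# Random substochastic schedules (optionally with fertility). Column sums
# of each U_j are scaled below `max_col`, so absorption is certain.
random_schedules <- function(s, omega, fertile = TRUE, max_col = 0.9,
                             single_offspring_type = FALSE) {
  U <- replicate(omega, {
    M <- matrix(stats::runif(s * s), s, s)
    sweep(M, 2, colSums(M) / stats::runif(s, 0.3, max_col), "/")
  }, simplify = FALSE)
  F <- replicate(omega, {
    M <- matrix(0, s, s)
    if (fertile) {
      if (single_offspring_type) M[1, ] <- stats::runif(s, 0, 2)
      else M[] <- stats::runif(s * s, 0, 1)
    }
    M
  }, simplify = FALSE)
  make_schedules(U = U, F = F)
}

# Independent construction oracle: block-Leslie layout written directly
# (fertility blocks across the first block row, transition blocks on the
# subdiagonal, open-ended corner), no vec-permutation involved.
brute_force_block_leslie <- function(schedules) {
  s <- schedules$s; omega <- schedules$omega
  n <- s * omega
  Ut <- matrix(0, n, n); Ft <- matrix(0, n, n)
  idx <- function(j) (j - 1) * s + seq_len(s)
  for (j in seq_len(omega)) Ft[idx(1), idx(j)] <- schedules$F[[j]]
  if (omega > 1) {
    for (j in seq_len(omega - 1)) Ut[idx(j + 1), idx(j)] <- schedules$U[[j]]
  }
  Ut[idx(omega), idx(omega)] <- Ut[idx(omega), idx(omega)] + schedules$U[[omega]]
  list(U = Ut, F = Ft, A = Ut + Ft)
}

expect_near <- function(object, expected, tol = 1e-10) {
  expect_lt(max(abs(object - expected)), tol)
}

rand_mixing <- function(s) {
  p <- stats::runif(s)
  p / sum(p)
}
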