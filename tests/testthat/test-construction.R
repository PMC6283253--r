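test_that("vec-permutation matrix realizes vec of the transpose", {
  # hand-enumerated 2x2 case: rows (1, 3, 2, 4) of the identity
  K22 <- vec_perm_matrix(2, 2)
  expect_equal(K22, diag(4)[c(1, 3, 2, 4), ])

  # m = 1 (or n = 1): a row/column vector is its own transpose-vec
  expect_equal(vec_perm_matrix(1, 5), diag(5))
  expect_equal(vec_perm_matrix(4, 1), diag(4))

  set.seed(11)
  for (m in 1:6) for (n in 1:6) {
    K <- vec_perm_matrix(m, n)
    # exactly one 1 per row and column
    expect_true(all(rowSums(K) == 1) && all(colSums(K) == 1))
    X <- matrix(rnorm(m * n), m, n)
    expect_identical(as.vector(K %*% as.vector(X)), as.vector(t(X)))
  }
  expect_error(vec_perm_matrix(0, 3), "positive")
})

test_that("default age operators match the open-ended Leslie pattern", {
  ops <- default_age_operators(2, 3)
  Dexp <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  Hexp <- rbind(c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  for (i in 1:2) {
    expect_equal(ops$D[[i]], Dexp)
    expect_equal(ops$H[[i]], Hexp)
  }
  # closing the open-ended corner kills individuals at the final age
  ops0 <- default_age_operators(1, 3, final_survival = 0)
  expect_equal(ops0$D[[1]][3, 3], 0)
  # degenerate single age class
  ops1 <- default_age_operators(1, 1)
  expect_equal(ops1$D[[1]], matrix(1))
  expect_equal(ops1$H[[1]], matrix(1))
})

test_that("block diagonal equals the Kronecker-sum construction", {
  set.seed(21)
  for (omega in 1:3) {
    blocks <- replicate(omega, matrix(rnorm(9), 3, 3), simplify = FALSE)
    direct <- Reduce(`+`, lapply(seq_len(omega), function(j) {
      E <- matrix(0, omega, omega); E[j, j] <- 1
      E %x% blocks[[j]]
    }))
    expect_equal(block_diagonal(blocks), direct)
  }
  expect_equal(block_diagonal(list(matrix(1:4, 2))), matrix(1:4, 2))
  expect_error(block_diagonal(list(matrix(0, 2, 2), matrix(0, 3, 3))), "same size")
})

test_that("impossible-combination masking zeroes rows and columns", {
  sch <- make_schedules(
    U = list(matrix(c(0.4, 0.2, 0.1, 0.5), 2), matrix(c(0.3, 0, 0, 0.3), 2)),
    F = list(matrix(0, 2, 2), matrix(1, 2, 2)),
    impossible = cbind(2, 1))   # stage 2 cannot occur at age 1
  masked <- apply_impossible_mask(sch)
  expect_equal(masked$U[[1]][2, ], c(0, 0))
  expect_equal(masked$U[[1]][, 2], c(0, 0))
  expect_equal(masked$U[[1]][1, 1], 0.4)
  expect_equal(masked$F[[1]], matrix(0, 2, 2))
  expect_equal(masked$U[[2]], sch$U[[2]])  # other ages untouched

  # empty mask is a no-op
  sch2 <- make_schedules(U = sch$U, F = sch$F)
  expect_equal(apply_impossible_mask(sch2)$U, sch2$U)

  # the masked state is absent from the stable structure
  model <- assemble_model(sch)
  w <- stable_analysis(model)$w
  expect_equal(w[2], 0)

  expect_error(make_schedules(U = sch$U, F = sch$F, impossible = cbind(3, 1)),
               "out of range")
})

test_that("vec-permutation assembly equals direct block-Leslie construction", {
  set.seed(31)
  for (rep in 1:5) {
    s <- sample(1:4, 1); omega <- sample(1:4, 1)
    sch <- random_schedules(s, omega)
    model <- assemble_model(sch)
    direct <- brute_force_block_leslie(sch)
    expect_near(model$U, direct$U, 1e-12)
    expect_near(model$F, direct$F, 1e-12)
    expect_near(model$A, direct$A, 1e-12)
    # column sums of the joint transition matrix stay substochastic
    expect_true(all(colSums(model$U) <= 1 + 1e-10))
  }
})

test_that("s = 1 assembly reduces to the classic Leslie matrix", {
  surv <- c(0.5, 0.8, 0.6)
  fert <- c(0, 1.2, 2)
  sch <- make_schedules(U = lapply(surv, matrix), F = lapply(fert, matrix))
  A <- assemble_model(sch)$A
  leslie <- matrix(0, 3, 3)
  leslie[1, ] <- fert
  leslie[2, 1] <- surv[1]; leslie[3, 2] <- surv[2]; leslie[3, 3] <- surv[3]
  expect_equal(A, leslie)
})

test_that("assembly validates substochasticity naming the offender", {
  U <- list(matrix(c(0.9, 0.3, 0, 0.5), 2), matrix(0, 2, 2))
  expect_error(
    make_schedules(U = U, F = list(matrix(0, 2, 2), matrix(0, 2, 2))),
    "age class 1, stage 1")
})

test_that("age-invariant schedules aggregate exactly over age", {
  set.seed(41)
  s <- 3; omega <- 6
  U0 <- matrix(runif(9), s, s); U0 <- sweep(U0, 2, colSums(U0) / 0.85, "/")
  F0 <- matrix(runif(9, 0, 0.5), s, s)
  sch <- make_schedules(U = rep(list(U0), omega), F = rep(list(F0), omega))
  lam_joint <- stable_analysis(assemble_model(sch))$lam
  lam_stage <- max(Mod(eigen(U0 + F0, only.values = TRUE)$values))
  expect_equal(lam_joint, lam_stage, tolerance = 1e-10)
})

test_that("age-primary reordering is an involutive similarity transform", {
  set.seed(51)
  sch <- random_schedules(3, 4)
  model <- assemble_model(sch)
  flipped <- reorder_age_primary(model)
  expect_equal(flipped$convention, "age_within_stage")
  # eigenvalues preserved
  expect_equal(sort(Mod(eigen(flipped$A, only.values = TRUE)$values)),
               sort(Mod(eigen(model$A, only.values = TRUE)$values)),
               tolerance = 1e-10)
  # conjugation by the explicit K matches
  K <- vec_perm_matrix(model$s, model$omega)
  expect_near(flipped$A, K %*% model$A %*% t(K), 1e-12)
  # applying twice returns the original
  back <- reorder_age_primary(flipped)
  expect_equal(back$A, model$A)
  expect_equal(back$convention, "stage_within_age")
  # s = 1: K is the identity
  t1 <- toy_fixture("T1")$model
  expect_equal(reorder_age_primary(t1)$A, t1$A)
})

test_that("marginal and mixture operators act as R N C on the vec ordering", {
  set.seed(61)
  s <- 3; omega <- 4
  N <- matrix(runif(s * omega), s, omega)   # stages x ages
  v <- as.vector(N)
  # stage marginal = row sums, age marginal = column sums
  expect_equal(as.vector(stage_marginal_operator(s, omega) %*% v), rowSums(N))
  expect_equal(as.vector(age_marginal_operator(s, omega) %*% v), colSums(N))
  # generic R, C
  R <- matrix(rnorm(2 * s), 2, s); C <- matrix(rnorm(omega * 2), omega, 2)
  expect_near(matrix(marginal_operator(R, C) %*% v, 2, 2), R %*% N %*% C, 1e-12)
  # identity operators
  expect_equal(marginal_operator(diag(s), diag(omega)), diag(s * omega))
  # age-1 mixture picks the pi-weighted first column
  pi <- c(0.2, 0.5, 0.3)
  expect_equal(as.vector(age1_mixture_operator(pi, omega) %*% v),
               sum(pi * N[, 1]))
  # marginals of a probability vector conserve mass
  p <- v / sum(v)
  expect_equal(sum(age_marginal_operator(s, omega) %*% p), 1)
  expect_equal(sum(stage_marginal_operator(s, omega) %*% p), 1)
})
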