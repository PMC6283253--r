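test_that("eigenvalue sensitivity to matrix entries is the v-w outer product", {
  # 1x1: d lambda / d a = 1
  sch1 <- make_schedules(U = list(matrix(0.4)), F = list(matrix(0.8)))
  mod1 <- assemble_model(sch1)
  expect_equal(as.vector(dlambda_dA(stable_analysis(mod1))), 1)

  # 2x2 toy checked against central finite differences
  t1 <- toy_fixture("T1", m = 2)
  sens <- matrix(dlambda_dA(stable_analysis(t1$model)), 2, 2)
  A0 <- t1$model$A
  fd <- matrix(NA, 2, 2)
  h <- 1e-6
  for (i in 1:2) for (j in 1:2) {
    up <- A0; up[i, j] <- up[i, j] + h
    dn <- A0; dn[i, j] <- dn[i, j] - h
    fd[i, j] <- (max(Re(eigen(up)$values)) - max(Re(eigen(dn)$values))) / (2 * h)
  }
  expect_near(sens, fd, 1e-6)
  expect_near(sens, rbind(c(0.5, 0.25), c(1, 0.5)), 1e-12)
})

test_that("elasticities of lambda sum to one", {
  set.seed(111)
  for (rep in 1:4) {
    mod <- assemble_model(random_schedules(sample(1:3, 1), sample(1:3, 1)))
    st <- stable_analysis(mod)
    expect_equal(sum(elasticity_lambda(mod, st)), 1, tolerance = 1e-10)
  }
})

test_that("net-reproductive-rate gradients match finite differences on T1", {
  # R0 = sigma1 * m: dR0/dm through the fertility path, dR0/dsigma1
  # through the transition path
  m0 <- 2; s0 <- 0.5
  build <- function(sigma1, m) {
    assemble_model(make_schedules(U = list(matrix(sigma1), matrix(0)),
                                  F = list(matrix(0), matrix(m))))
  }
  mod <- build(s0, m0)
  N <- fundamental_matrix(mod)
  rp <- net_reproductive_rate(mod, N)
  d <- dR0_dA(mod, N, rp)
  # F entry (1,2) of the 2x2 joint matrix is vec position 3
  expect_equal(d$dF[3], s0, tolerance = 1e-10)
  # U entry (2,1) is vec position 2
  expect_equal(d$dU[2], m0, tolerance = 1e-10)
  fdF <- finite_difference(function(th) {
    md <- build(s0, th)
    net_reproductive_rate(md, fundamental_matrix(md))$R0
  }, m0)
  fdU <- finite_difference(function(th) {
    md <- build(th, m0)
    net_reproductive_rate(md, fundamental_matrix(md))$R0
  }, s0)
  expect_equal(d$dF[3], fdF[1, 1], tolerance = 1e-6)
  expect_equal(d$dU[2], fdU[1, 1], tolerance = 1e-6)

  # no reproduction: flagged zero derivative
  t2 <- toy_fixture("T2")
  N2 <- fundamental_matrix(t2$model)
  d2 <- dR0_dA(t2$model, N2, net_reproductive_rate(t2$model, N2))
  expect_true(d2$zero)
  expect_equal(max(abs(d2$dF)), 0)
})

test_that("structural Jacobians are 0-1 matrices fixed by the construction", {
  set.seed(112)
  sch <- random_schedules(2, 3)
  mod <- assemble_model(sch)
  sj <- structural_jacobians(mod, dense = TRUE)
  # entries are 0/1 and independent of the vital rates
  for (M in c(list(sj$term2_U, sj$term2_F), sj$term3)) {
    expect_true(all(M %in% c(0, 1)))
  }
  sch2 <- random_schedules(2, 3)
  sj2 <- structural_jacobians(assemble_model(sch2), dense = TRUE)
  expect_identical(sj$term2_U, sj2$term2_U)
  expect_identical(sj$term3, sj2$term3)

  # term3 places vec(U_i) into diagonal block i of vec(U)
  for (i in 1:3) {
    placed <- matrix(sj$term3[[i]] %*% as.vector(sch$U[[i]]), 6, 6)
    direct <- matrix(0, 6, 6)
    direct[(i - 1) * 2 + 1:2, (i - 1) * 2 + 1:2] <- sch$U[[i]]
    expect_equal(placed, direct)
  }

  # s = 1: the permutation collapses and term2_U = I (x) D
  sch1 <- make_schedules(U = list(matrix(0.5), matrix(0)),
                         F = list(matrix(0), matrix(2)))
  mod1 <- assemble_model(sch1)
  sj1 <- structural_jacobians(mod1, dense = TRUE)
  expect_equal(sj1$term2_U, diag(2) %x% sch1$D[[1]])

  # term2 applied to vec(blockdiag U) reproduces vec(Utilde)
  UU <- block_diagonal(sch$U)
  expect_near(matrix(sj$term2_U %*% as.vector(UU), 6, 6), mod$U, 1e-12)
})

test_that("survival decomposition and its Jacobian match finite differences", {
  set.seed(113)
  U_i <- matrix(runif(4), 2, 2)
  U_i <- sweep(U_i, 2, colSums(U_i) / c(0.8, 0.6), "/")
  dec <- survival_decomposition(U_i)
  expect_equal(colSums(dec$G), c(1, 1))
  expect_near(dec$G %*% diag(dec$sigma), U_i, 1e-12)

  # theta = 1 baseline reproduces U_i; Jacobian matches entrywise FD
  J <- survival_parameter_jacobian(dec$G, dec$sigma)
  U_of_theta <- function(th) as.vector(dec$G %*% diag(dec$sigma * th))
  expect_equal(U_of_theta(c(1, 1)), as.vector(U_i))
  fd <- finite_difference(U_of_theta, c(1, 1))
  expect_near(J, fd, 1e-6)

  # scalar case: dU/dtheta = sigma_hat
  dec1 <- survival_decomposition(matrix(0.5))
  expect_equal(as.vector(survival_parameter_jacobian(dec1$G, dec1$sigma)), 0.5)

  # a zero-survival column leaves G unconstrained there
  expect_silent(survival_parameter_jacobian(matrix(0.7), 0))
  expect_error(survival_parameter_jacobian(matrix(0.7), 0.5), "sum to 1")
})

test_that("the assembled five-term chain matches finite differences", {
  set.seed(114)
  for (rep in 1:3) {
    s <- sample(2:3, 1); omega <- sample(2:4, 1)
    sch <- random_schedules(s, omega)
    age <- sample(seq_len(omega), 1)
    decs <- lapply(sch$U, survival_decomposition)
    build <- function(theta) {
      U <- sch$U
      U[[age]] <- decs[[age]]$G %*% diag(decs[[age]]$sigma * theta)
      make_schedules(U = U, F = sch$F)
    }
    mod <- assemble_model(sch)
    for (out in c("lambda", "R0")) {
      analytic <- sensitivity_survival(mod, out, ages = age)
      evalf <- function(th) {
        md <- assemble_model(build(th))
        if (out == "lambda") stable_analysis(md)$lam
        else net_reproductive_rate(md, fundamental_matrix(md))$R0
      }
      fd <- finite_difference(evalf, rep(1, s))
      expect_near(analytic, fd, 1e-6 * max(1, max(abs(fd))))
    }
  }
})

test_that("a perturbation touching only masked fertility has zero sensitivity", {
  sch <- make_schedules(
    U = list(matrix(c(0.5, 0.2, 0, 0.6), 2), matrix(c(0.3, 0, 0, 0.4), 2)),
    F = list(matrix(0, 2, 2), matrix(c(0, 0, 1, 0.5), 2)),
    impossible = cbind(2, 2))        # stage 2 masked at age 2
  mod <- assemble_model(sch)
  st <- stable_analysis(mod)
  t1 <- dlambda_dA(st)
  # parameter enters only F[, 2] of age class 2 (the masked column)
  term5 <- vector("list", 2)
  J <- matrix(0, 4, 1); J[3:4, 1] <- 1   # d vec(F_2) / d theta
  term5[[2]] <- J
  sens <- assemble_sensitivity(mod, term1_F = t1, term5 = term5, p = 1)
  expect_equal(as.vector(sens), 0)
})

test_that("finite differences are second-order accurate", {
  f <- function(th) th[1]^3 + 2 * th[1]
  d1 <- finite_difference(f, 1, h = 1e-2)[1, 1]
  d2 <- finite_difference(f, 1, h = 5e-3)[1, 1]
  # error ratio ~ 4 under step halving (Richardson)
  expect_equal((d1 - 5) / (d2 - 5), 4, tolerance = 0.05)
  expect_error(suppressWarnings(finite_difference(function(th) log(th), 0)),
               "non-finite")
})
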