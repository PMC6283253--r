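test_that("projection reduces to cohort dynamics without fertility and to A otherwise", {
  t2 <- toy_fixture("T2")    # no reproduction
  n0 <- c(0.3, 0.7, 0, 0)
  pr <- project(t2$model, n0, 5)
  pc <- project_cohort(t2$model, n0, 5)
  expect_equal(pr$n, pc$n)

  t1 <- toy_fixture("T1")
  one <- project(t1$model, c(1, 0), 1)
  expect_equal(one$n[, 2], t1$model$A[, 1])
})

test_that("growth increments converge to the dominant eigenvalue", {
  # primitive toy: fertility in two consecutive age classes
  sch <- make_schedules(U = list(matrix(0.5), matrix(0.4), matrix(0)),
                        F = list(matrix(0), matrix(1.5), matrix(2)))
  mod <- assemble_model(sch)
  st <- stable_analysis(mod)
  pr <- project(mod, c(1, 0, 0), 1000, normalize = TRUE)
  expect_equal(pr$growth[1000], st$lam, tolerance = 1e-8)
})

test_that("stable analysis solves the 2x2 toy eigenproblem by hand", {
  t1 <- toy_fixture("T1", m = 2)
  st <- stable_analysis(t1$model)
  expect_equal(st$lam, 1)
  expect_equal(st$w, c(2, 1) / 3)
  # v proportional to (1, 2), scaled so sum(v * w) = 1
  expect_equal(st$v / st$v[1], c(1, 2))
  expect_equal(sum(st$v * st$w), 1)
  expect_equal(st$w_age, c(2, 1) / 3)
  expect_equal(st$w_stage, 1)
  # reference-state rescaling
  st2 <- stable_analysis(t1$model, reference_state = 2)
  expect_equal(st2$v_report[2], 1)
})

test_that("zero reproductive value flags diagnose non-ergodic subspaces", {
  # a terminal stage that never reproduces and leads nowhere fertile
  U1 <- rbind(c(0.2, 0, 0), c(0.3, 0.4, 0), c(0.2, 0.3, 0.5))
  F1 <- rbind(c(0, 2, 0), c(0, 0, 0), c(0, 0, 0))
  sch <- make_schedules(U = list(U1), F = list(F1))
  st <- stable_analysis(assemble_model(sch))
  expect_true(st$ergodic_flags[3])     # post-reproductive stage: v = 0
  expect_false(any(st$ergodic_flags[1:2]))
})

test_that("birth mixture extracts the age-class-1 block of w", {
  set.seed(101)
  sch <- random_schedules(3, 3)
  mod <- assemble_model(sch)
  st <- stable_analysis(mod)
  pi <- birth_mixture_from_stable(st, 3)
  expect_equal(pi, st$w[1:3] / sum(st$w[1:3]))
  expect_equal(sum(pi), 1)
  # single birth stage: point mass
  sch1 <- random_schedules(2, 3, single_offspring_type = TRUE)
  st1 <- stable_analysis(assemble_model(sch1))
  expect_equal(birth_mixture_from_stable(st1, 2), c(1, 0))
})

test_that("net reproductive rate comes from the birth-to-birth block", {
  t1 <- toy_fixture("T1", m = 2)
  N <- fundamental_matrix(t1$model)
  rp <- net_reproductive_rate(t1$model, N)
  expect_equal(rp$R0, 1)           # boundary case R0 = lambda = 1
  expect_equal(dim(rp$R11), c(1, 1))

  # no fertility: R0 = 0
  t2 <- toy_fixture("T2")
  rp2 <- net_reproductive_rate(t2$model, fundamental_matrix(t2$model))
  expect_equal(rp2$R0, 0)

  # R0 and lambda lie on the same side of 1 (growth indicator)
  set.seed(102)
  for (rep in 1:5) {
    sch <- random_schedules(sample(1:3, 1), sample(1:3, 1))
    mod <- assemble_model(sch)
    st <- stable_analysis(mod)
    rp <- net_reproductive_rate(mod, fundamental_matrix(mod))
    expect_true((st$lam - 1) * (rp$R0 - 1) >= -1e-10)
  }
})

test_that("s = 1 degenerates to the classic life-table net reproductive rate", {
  surv <- c(0.8, 0.7, 0.5, 0)
  fert <- c(0, 1, 2, 1.5)
  sch <- make_schedules(U = lapply(surv, matrix), F = lapply(fert, matrix))
  mod <- assemble_model(sch)
  N <- fundamental_matrix(mod)
  rp <- net_reproductive_rate(mod, N)
  ell <- c(1, cumprod(surv))[1:4]          # ell(0..3)
  expect_equal(rp$R0, sum(ell * fert), tolerance = 1e-10)
  # classic cohort generation time sum(x ell f) / sum(ell f), x from 0
  gt <- generation_times(mod, N, cohort_n0(mod, 1))
  x <- 0:3
  expect_equal(gt$Gamma, sum(x * ell * fert) / sum(ell * fert),
               tolerance = 1e-10)
})

test_that("lifetime reproduction aggregates the next-generation block", {
  R11 <- matrix(c(0.334, 0.014, 4.656, 1.087), 2, 2)
  lr <- lifetime_reproduction(R11, c = c(1, 1), pi = c(0.85, 0.15))
  expect_equal(lr$r_weighted, colSums(R11))
  expect_equal(lr$r_mixed, as.vector(R11 %*% c(0.85, 0.15)))
  expect_equal(lr$rho, sum(R11 %*% c(0.85, 0.15)))
  # single offspring type, single birth stage: rho = R0
  r <- 1.7
  lr2 <- lifetime_reproduction(matrix(c(r, 0, 0, 0), 2, 2),
                               c = c(1, 0), pi = c(1, 0))
  expect_equal(lr2$rho, r)
})

test_that("generation times follow the closed-form mean age of reproduction", {
  t14 <- toy_fixture("T1", m = 4)
  mod <- t14$model
  N <- fundamental_matrix(mod)
  gt <- generation_times(mod, N, cohort_n0(mod, 1))
  expect_equal(gt$T, 2)            # log R0 / log lambda = log 2 / log sqrt(2)
  expect_equal(gt$Gamma, 1)        # all reproduction one step after birth

  # reproduction only during the first step: mean age 0 by the
  # age-from-0 convention
  sch0 <- make_schedules(U = list(matrix(0), matrix(0)),
                         F = list(matrix(3), matrix(0)))
  mod0 <- assemble_model(sch0)
  gt0 <- generation_times(mod0, fundamental_matrix(mod0), c(1, 0))
  expect_equal(gt0$Gamma, 0)

  # lambda = R0 = 1: T is flagged undefined, not computed
  t12 <- toy_fixture("T1", m = 2)
  gt1 <- generation_times(t12$model, fundamental_matrix(t12$model),
                          cohort_n0(t12$model, 1))
  expect_true(is.na(gt1$T))

  # offspring types never produced get Gamma = 0
  set.seed(103)
  sch2 <- random_schedules(2, 3, single_offspring_type = TRUE)
  mod2 <- assemble_model(sch2)
  gt2 <- generation_times(mod2, fundamental_matrix(mod2), cohort_n0(mod2, c(1, 0)))
  expect_equal(gt2$phi_life[2], 0)
  expect_equal(gt2$Gamma[2], 0)
  expect_true(gt2$Gamma[1] > 0)

  # cohort preconditions
  expect_error(generation_times(mod2, fundamental_matrix(mod2),
                                c(0, 0, 1, 0, 0, 0)), "age class 1")
})

test_that("N U N equals the age-weighted sum of powers of U", {
  set.seed(104)
  for (rep in 1:3) {
    mod <- assemble_model(random_schedules(sample(1:3, 1), sample(1:3, 1)))
    N <- fundamental_matrix(mod)
    closed <- N %*% mod$U %*% N
    series <- matrix(0, nrow(N), ncol(N))
    P <- diag(nrow(N))
    for (x in 1:200) {
      P <- P %*% mod$U
      series <- series + x * P
    }
    expect_near(closed, series, 1e-8)
  }
})
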