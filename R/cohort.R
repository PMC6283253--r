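# Life-table functions for age x stage-classified cohorts: survivorship,
# mortality, intra-cohort selection, and the fertility aggregations.
#
# Age convention: x counts time steps since entering age class 1, so
# survivorship starts at ell(0) = 1. All downstream conventions (generation
# time, ages at death) inherit this choice.

#' Initial cohort vector from a stage mixing distribution
#'
#' Places the stage distribution `pi0` into age class 1 of the joint state
#' space: `n0 = e1 (x) pi0` under the stages-within-ages ordering.
#'
#' @param model An `agestage_model`.
#' @param pi0 Stage mixing distribution at birth (length `s`).
#' @return Joint vector of length `s * omega`.
#' @export
cohort_n0 <- function(model, pi0) {
  pi0 <- as_mixing(pi0, model$s)
  n0 <- numeric(model$s * model$omega)
  n0[seq_len(model$s)] <- pi0
  n0
}

#' Survivorship of an age x stage-classified cohort
#'
#' The joint survivorship vector at age `x` is the vector of column sums of
#' the `x`-step transition matrix, \eqn{\tilde\ell(x) = (1^\top \tilde U^x)^\top}:
#' entry `k` is the probability that an individual starting in joint state
#' `k` is still alive `x` steps later. The birth-stage survivorship
#' schedule `ell` extracts the age-class-1 block, and a mixed cohort's
#' scalar schedule is `ell_mix(x) = t(pi) %*% ell[, x]`.
#'
#' Survivorship is accumulated iteratively by vector-matrix products, so
#' the cost is linear in `x_max`. If a stage is impossible at age class 1
#' its survivorship is identically zero.
#'
#' @param model An `agestage_model`.
#' @param x_max Largest age (number of projection steps) to compute.
#' @param pi Optional stage mixing distribution over birth stages.
#' @return An object of class `agestage_survivorship`: list with
#'   `ell_tilde` (`s*omega x (x_max+1)` matrix, column `x+1` is age `x`),
#'   `ell` (`s x (x_max+1)`), and `ell_mix` (length `x_max+1`, `NULL` if
#'   `pi` not given), plus `pi`, `s`, `omega`, `x_max`.
#' @export
survivorship <- function(model, x_max, pi = NULL) {
  stopifnot(inherits(model, "agestage_model"), x_max >= 0)
  s <- model$s; omega <- model$omega
  n <- s * omega
  ell_tilde <- matrix(0, n, x_max + 1)
  row <- rep(1, n)                      # running 1' U^x
  ell_tilde[, 1] <- row
  ell_tilde[!model$possible, 1] <- 0    # masked states never exist
  if (x_max > 0) {
    for (x in seq_len(x_max)) {
      row <- as.vector(row %*% model$U)
      ell_tilde[, x + 1] <- row
    }
  }
  ell <- ell_tilde[seq_len(s), , drop = FALSE]  # (e1' (x) I_s) block
  ell_mix <- NULL
  if (!is.null(pi)) {
    pi <- as_mixing(pi, s)
    ell_mix <- as.vector(pi %*% ell)
  }
  structure(
    list(ell_tilde = ell_tilde, ell = ell, ell_mix = ell_mix, pi = pi,
         s = s, omega = omega, x_max = x_max),
    class = "agestage_survivorship"
  )
}

#' Age- and stage-specific mortality rates
#'
#' The discrete hazard by birth stage is the reversed slope of log
#' survivorship, \eqn{\mu(x) = -\log(\ell(x+1)/\ell(x))} elementwise.
#' Entries where the cohort is already extinct (`ell(x) = 0`), including
#' stages impossible at birth, are `NaN` (undefined); entries where the
#' cohort dies out exactly at `x+1` are `+Inf`. The distinction matters:
#' `NaN` marks a rate that never existed, `Inf` a certain death.
#'
#' The mixed-cohort schedule uses the scalar `ell_mix` ratios; it is
#' "apparent" in the sense that no individual experiences it -- it reflects
#' the changing stage composition of the mixture.
#'
#' @param surv An `agestage_survivorship` object (computed to at least the
#'   ages wanted plus one).
#' @return List with `mu` (`s x x_max` matrix, column `x+1` is age `x`
#'   running over `x = 0..x_max-1`) and `mu_mix` (length `x_max`, `NULL`
#'   unless the survivorship carried a mixing distribution).
#' @export
mortality_rates <- function(surv) {
  stopifnot(inherits(surv, "agestage_survivorship"))
  xm <- surv$x_max
  if (xm < 1) stop("survivorship must be computed to at least x_max = 1")
  ratio <- surv$ell[, 2:(xm + 1), drop = FALSE] / surv$ell[, 1:xm, drop = FALSE]
  mu <- -log(ratio)                      # 0/0 -> NaN, log(0) -> +Inf
  mu_mix <- NULL
  if (!is.null(surv$ell_mix)) {
    mu_mix <- -log(surv$ell_mix[2:(xm + 1)] / surv$ell_mix[1:xm])
  }
  list(mu = mu, mu_mix = mu_mix)
}

#' Project a cohort and track intra-cohort selection
#'
#' Projects `n0` through the transition matrix, `n(x) = U^x n0`, and
#' normalizes each surviving cohort vector to the joint age-stage frequency
#' distribution `m(x)`, with stage and age marginals. As the cohort ages,
#' stages with higher mortality or faster transit decline in frequency
#' (intra-cohort selection); `m(x)` converges to the normalized dominant
#' right eigenvector of `U`.
#'
#' @param model An `agestage_model`.
#' @param n0 Nonnegative, nonzero initial joint vector (see [cohort_n0()]).
#' @param x_max Number of steps to project.
#' @return List with `n` (`s*omega x (x_max+1)` abundances), `joint_dist`
#'   (same shape, columns normalized to 1), `m_stage` (`s x (x_max+1)`),
#'   `m_age` (`omega x (x_max+1)`), and logical `empty` flagging ages at
#'   which the cohort has no survivors (distributions there are `NA`, not
#'   0/0).
#' @export
project_cohort <- function(model, n0, x_max) {
  stopifnot(inherits(model, "agestage_model"), x_max >= 0)
  n0 <- as.numeric(n0)
  if (length(n0) != model$s * model$omega) stop("'n0' has the wrong length")
  if (any(n0 < 0) || sum(n0) == 0) stop("'n0' must be nonnegative and nonzero")
  s <- model$s; omega <- model$omega
  n <- matrix(0, s * omega, x_max + 1)
  n[, 1] <- n0
  if (x_max > 0) {
    for (x in seq_len(x_max)) n[, x + 1] <- as.vector(model$U %*% n[, x])
  }
  tot <- colSums(n)
  empty <- tot == 0
  joint <- sweep(n, 2, ifelse(empty, NA_real_, tot), "/")
  Sm <- stage_marginal_operator(s, omega)
  Am <- age_marginal_operator(s, omega)
  list(n = n, joint_dist = joint,
       m_stage = Sm %*% joint, m_age = Am %*% joint,
       empty = empty)
}

#' Fertility aggregations at one age
#'
#' The `s x s` fertility matrix `F_x` of age class `x` is summarized three
#' ways: weighted offspring production `f_weighted = t(t(c) %*% F_x)`
#' (offspring types combined with weights `c`, one entry per parent stage);
#' mixed offspring production `f_mixed = F_x %*% pi_x` (offspring of each
#' type from a parent cohort mixed according to `pi_x`); and the scalar
#' schedule `f_scalar = t(c) %*% F_x %*% pi_x`. The natural source for
#' `pi_x` is the cohort's own stage composition at age `x`
#' (`m_stage` from [project_cohort()]); any other mixture may be supplied.
#'
#' @param F_x Nonnegative `s x s` fertility matrix for one age class.
#' @param c Nonnegative offspring weight vector (length `s`).
#' @param pi_x Stage mixing distribution at age `x` (length `s`).
#' @return List with `f_weighted`, `f_mixed` (length-`s` vectors) and
#'   `f_scalar`.
#' @export
fertility_summary <- function(F_x, c, pi_x) {
  F_x <- as.matrix(F_x)
  s <- nrow(F_x)
  if (ncol(F_x) != s) stop("'F_x' must be square")
  c <- as.numeric(c)
  if (length(c) != s) stop("'c' must have length s = ", s)
  if (any(c < 0)) stop("'c' must be nonnegative")
  pi_x <- as_mixing(pi_x, s)
  list(f_weighted = as.vector(c %*% F_x),
       f_mixed = as.vector(F_x %*% pi_x),
       f_scalar = as.vector(c %*% F_x %*% pi_x))
}
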