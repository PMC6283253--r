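# Joint distribution of age and stage at death, its marginals and
# mixtures, and life disparity (mean years of life lost to mortality).
#
# Absorbing states are indexed identically to transient states: death
# during the transition out of age class x is attributed to the (age,
# stage) combination occupied when that transition was applied.

#' Stage-specific mortality vectors and the mortality matrix
#'
#' For each age class `i`, the death probabilities by stage are the
#' complements of the column sums of `U[[i]]`,
#' `q_i = 1 - colSums(U[[i]])`; stacking their diagonal matrices down the
#' block diagonal gives the `s*omega x s*omega` mortality matrix `M` of the
#' absorbing chain. Together the transient matrix and `M` form a
#' column-stochastic chain on the possible states.
#'
#' @param schedules An `agestage_schedules` object (masking is applied
#'   first, so masked states carry death probability 1 in `M`; they are
#'   unreachable and excluded from stochasticity checks).
#' @return List with `q_list` (length-`omega` list of length-`s` vectors)
#'   and `M` (block-diagonal mortality matrix).
#' @export
mortality_operator <- function(schedules) {
  stopifnot(inherits(schedules, "agestage_schedules"))
  schedules <- apply_impossible_mask(schedules)
  validate_schedules(schedules)
  q_list <- lapply(schedules$U, function(Uj) pmin(pmax(1 - colSums(Uj), 0), 1))
  M <- block_diagonal(lapply(q_list, function(q) diag(q, nrow = length(q))))
  list(q_list = q_list, M = M)
}

#' Joint distribution of age and stage at death
#'
#' Multiplying the mortality matrix by the fundamental matrix gives
#' `B = M %*% N_fund`; column `k` of `B` is the probability distribution of
#' the (age, stage) combination at death for an individual currently in
#' joint state `k`. Because absorption is certain, every column over a
#' possible state sums to 1. Marginals sum the joint distribution over
#' stages within ages (`B_age`, `omega x s*omega`) or ages within stages
#' (`B_stage`, `s x s*omega`).
#'
#' @param M Mortality matrix from [mortality_operator()].
#' @param N_fund Fundamental matrix.
#' @param s,omega Model dimensions.
#' @return List with `B`, `B_age`, `B_stage`.
#' @export
death_distribution <- function(M, N_fund, s, omega) {
  B <- M %*% N_fund
  list(B = B,
       B_age = age_marginal_operator(s, omega) %*% B,
       B_stage = stage_marginal_operator(s, omega) %*% B)
}

#' Death distribution of a mixed cohort
#'
#' Averages the columns of the joint (or marginal) death distribution over
#' a mixing distribution on the joint state space: `B %*% pi`.
#'
#' @param B Joint or marginal death distribution matrix with `s*omega`
#'   columns.
#' @param pi Mixing distribution over joint states (length `s*omega`).
#' @param possible Optional logical vector marking possible states; `pi`
#'   must place no mass on impossible ones.
#' @return The mixed distribution vector (sums to 1).
#' @export
death_mixture <- function(B, pi, possible = NULL) {
  B <- as.matrix(B)
  pi <- as_mixing(pi, ncol(B))
  if (!is.null(possible) && any(pi[!possible] > 0)) {
    stop("mixing distribution places mass on an impossible state")
  }
  as.vector(B %*% pi)
}

#' Life disparity: mean years of life lost to mortality
#'
#' An individual dying in joint state `k` loses, in expectation, the mean
#' remaining longevity of state `k`. Integrating over the distribution of
#' state at death gives the life-disparity vector
#' `eta_dagger = t(B) %*% eta1`, one entry per starting state, and the
#' scalar `t(pi) %*% eta_dagger` for a mixed cohort.
#'
#' Under the discrete longevity convention (minimum longevity 1) the value
#' for a deterministic single-state death is 1, not the 0 of the
#' continuous-time limit; set `continuous = TRUE` to subtract 1 and
#' approximate that convention. The default reports the discrete
#' computation unchanged.
#'
#' @param eta1 Mean-longevity vector over joint states.
#' @param B Joint death distribution matrix.
#' @param pi Optional mixing distribution over joint states.
#' @param continuous If `TRUE`, subtract 1 to approximate the
#'   continuous-time convention. Default `FALSE`.
#' @return List with `eta_dagger` (vector over joint states) and
#'   `eta_dagger_mix` (scalar or `NULL`).
#' @export
life_disparity <- function(eta1, B, pi = NULL, continuous = FALSE) {
  B <- as.matrix(B)
  eta_dagger <- as.vector(eta1 %*% B)
  if (continuous) eta_dagger <- eta_dagger - 1
  out <- list(eta_dagger = eta_dagger, eta_dagger_mix = NULL)
  if (!is.null(pi)) {
    pi <- as_mixing(pi, length(eta_dagger))
    out$eta_dagger_mix <- sum(pi * eta_dagger)
  }
  out
}
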