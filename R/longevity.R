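# Absorbing-Markov-chain statistics of longevity: the fundamental matrix,
# moments and variance of time to death, age-conditional slices, the
# within/between-stage variance decomposition, and survivorship recovered
# from the fundamental matrix.
#
# Longevity counts the time step currently being lived, so its minimum is
# 1: an individual that dies during its first projection interval lived
# one step. Continuous-time life expectancy conventions differ by about
# one half.

#' Fundamental matrix of the mortality chain
#'
#' Treats the joint transition matrix `U` as the transient part of an
#' absorbing Markov chain and solves `(I - U) N = I` for the fundamental
#' matrix `N`, whose (i, j) entry is the expected number of time steps
#' spent in joint state `i` by an individual starting in state `j`. A
#' single LU factorization of `I - U` serves all right-hand sides.
#'
#' Absorption must be certain: if the spectral radius of `U` is within
#' `1e-12` of 1 (for example, an open-ended final age class with survival
#' exactly 1), the chain is immortal and an error is raised.
#'
#' @param model An `agestage_model`.
#' @return The `s*omega x s*omega` fundamental matrix.
#' @export
fundamental_matrix <- function(model) {
  stopifnot(inherits(model, "agestage_model"))
  U <- model$U
  rho <- max(Mod(eigen(U, only.values = TRUE)$values), 0)
  if (rho >= 1 - 1e-12) {
    stop("immortal chain: spectral radius of U is ", format(rho),
         "; death is not certain from every state")
  }
  n <- nrow(U)
  solve(diag(n) - U, diag(n))
}

#' Moments and variance of longevity
#'
#' From the fundamental matrix, the mean remaining longevity of every joint
#' state is `eta1 = t(colSums(N))`, the second moments satisfy
#' `t(eta2) = t(eta1) %*% (2 N - I)`, and the variance is
#' `V = eta2 - eta1^2`. Variances that come out very slightly negative
#' (>= -1e-9) from floating cancellation are clamped to zero; anything more
#' negative raises an internal-consistency error.
#'
#' @param N_fund Fundamental matrix from [fundamental_matrix()].
#' @return An object of class `agestage_longevity`: list with `N_fund`,
#'   `eta1`, `eta2`, `var` (each a vector over joint states).
#' @export
longevity_stats <- function(N_fund) {
  N_fund <- as.matrix(N_fund)
  n <- nrow(N_fund)
  eta1 <- colSums(N_fund)
  eta2 <- as.vector(eta1 %*% (2 * N_fund - diag(n)))
  v <- eta2 - eta1^2
  if (any(v < -1e-9)) {
    stop("internal inconsistency: variance of longevity below -1e-9 (",
         format(min(v)), ")")
  }
  v[v < 0] <- 0
  structure(list(N_fund = N_fund, eta1 = eta1, eta2 = eta2, var = v),
            class = "agestage_longevity")
}

#' Extract the stage vectors of longevity statistics at one age class
#'
#' Applies the unit-vector Kronecker selector `(t(e_x) (x) I_s)` to the
#' joint mean and variance vectors, returning the `s`-vectors of mean and
#' variance of remaining longevity for individuals of age class `x`.
#'
#' @param stats An `agestage_longevity` object.
#' @param x Age class, `1 <= x <= omega`.
#' @param s Number of stages.
#' @return List with `mean_by_stage` and `var_by_stage` (length-`s`
#'   vectors).
#' @export
age_slice <- function(stats, x, s) {
  stopifnot(inherits(stats, "agestage_longevity"))
  omega <- length(stats$eta1) / s
  if (x < 1 || x > omega || x != round(x)) {
    stop("age class 'x' must be an integer in 1..", omega)
  }
  idx <- (x - 1) * s + seq_len(s)
  list(mean_by_stage = stats$eta1[idx], var_by_stage = stats$var[idx])
}

#' Within/between-stage decomposition of the variance in longevity
#'
#' For a cohort of age `x` mixed over stages according to `pi_x`, the law
#' of total variance splits the variance in remaining longevity into a
#' within-stage component (individual stochasticity),
#' `V_within = t(pi) %*% var_by_stage`, and a between-stage component
#' (heterogeneity), `V_between = t(pi) %*% mean^2 - (t(pi) %*% mean)^2`.
#' The two add exactly to the mixture variance, and the percentage
#' attributable to heterogeneity is reported.
#'
#' @param mean_by_stage,var_by_stage Length-`s` vectors, e.g. from
#'   [age_slice()].
#' @param pi_x Stage mixing distribution; must place zero mass on any
#'   masked stage (indices in `masked`).
#' @param masked Optional integer vector of masked stage indices.
#' @return An object of class `agestage_vardecomp`: list with
#'   `mixture_mean`, `v_within`, `v_between`, `v_total`, `pct_between`
#'   (0 when the total variance is 0), and `pi_x`.
#' @export
variance_decomposition <- function(mean_by_stage, var_by_stage, pi_x,
                                   masked = NULL) {
  s <- length(mean_by_stage)
  stopifnot(length(var_by_stage) == s)
  pi_x <- as_mixing(pi_x, s)
  if (!is.null(masked) && any(pi_x[masked] > 0)) {
    stop("mixing distribution places positive mass on a masked stage")
  }
  m <- sum(pi_x * mean_by_stage)
  v_within <- sum(pi_x * var_by_stage)
  v_between <- sum(pi_x * mean_by_stage^2) - m^2
  if (v_between < -1e-9) {
    stop("internal inconsistency: between-stage variance is ", format(v_between))
  }
  v_between <- max(v_between, 0)  # floating cancellation only
  v_total <- v_within + v_between
  structure(
    list(mixture_mean = m, v_within = v_within, v_between = v_between,
         v_total = v_total,
         pct_between = if (v_total > 0) 100 * v_between / v_total else 0,
         pi_x = pi_x),
    class = "agestage_vardecomp"
  )
}

#' @export
print.agestage_vardecomp <- function(x, ...) {
  cat("Variance in longevity, mixture decomposition\n")
  cat(sprintf("  mixture mean      %.4f\n", x$mixture_mean))
  cat(sprintf("  within (stochasticity)   %.4f\n", x$v_within))
  cat(sprintf("  between (heterogeneity)  %.4f  (%.1f%%)\n",
              x$v_between, x$pct_between))
  invisible(x)
}

#' Survivorship recovered from the fundamental matrix
#'
#' An age class can be visited at most once, so the expected number of
#' visits to it equals the probability of ever reaching it -- which is the
#' survivorship. Aggregating the rows of the fundamental matrix over stages
#' within age classes and keeping the columns of the first age class gives
#' \deqn{L = (I_\omega \otimes 1_s^\top)\, \tilde N\, (e_1 \otimes I_s),}
#' an `omega x s` matrix whose column `i` is the survivorship schedule of
#' an individual born in stage `i` (row `x` is survival to age `x - 1`,
#' matching the age-from-0 convention of [survivorship()]).
#'
#' @param model An `agestage_model`.
#' @param N_fund Fundamental matrix.
#' @param pi Optional birth-stage mixing distribution; if given, the mixed
#'   schedule `L %*% pi` is also returned.
#' @return List with `L` (`omega x s`) and `ell_mix` (length `omega` or
#'   `NULL`).
#' @export
survivorship_from_fundamental <- function(model, N_fund, pi = NULL) {
  stopifnot(inherits(model, "agestage_model"))
  s <- model$s; omega <- model$omega
  Am <- age_marginal_operator(s, omega)          # I_omega (x) 1_s'
  L <- (Am %*% N_fund)[, seq_len(s), drop = FALSE]  # columns of age class 1
  ell_mix <- NULL
  if (!is.null(pi)) {
    pi <- as_mixing(pi, s)
    ell_mix <- as.vector(L %*% pi)
  }
  list(L = L, ell_mix = ell_mix)
}
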