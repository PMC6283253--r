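# Population dynamics: projection, stable structure and reproductive
# value, ergodicity diagnostics, the next-generation-matrix net
# reproductive rate, lifetime reproduction, and generation times.

#' Project a population
#'
#' Iterates `n(t+1) = A %*% n(t)` from `n0`. With `normalize = TRUE` each
#' step is rescaled to sum 1 and the per-step growth increments
#' `||n(t+1)|| / ||n(t)||` are returned; for a primitive model these
#' converge to the dominant eigenvalue.
#'
#' @param model An `agestage_model`.
#' @param n0 Nonnegative, nonzero initial joint vector.
#' @param t_max Number of projection steps.
#' @param normalize Rescale each step and record growth increments.
#' @return List with `n` (`s*omega x (t_max+1)` matrix) and `growth`
#'   (length `t_max`, `NULL` unless `normalize`).
#' @export
project <- function(model, n0, t_max, normalize = FALSE) {
  stopifnot(inherits(model, "agestage_model"), t_max >= 0)
  n0 <- as.numeric(n0)
  if (any(n0 < 0) || sum(n0) == 0) stop("'n0' must be nonnegative and nonzero")
  nmat <- matrix(0, length(n0), t_max + 1)
  growth <- if (normalize) numeric(t_max) else NULL
  cur <- n0
  if (normalize) cur <- cur / sum(cur)
  nmat[, 1] <- cur
  for (t in seq_len(t_max)) {
    nxt <- as.vector(model$A %*% cur)
    if (normalize) {
      growth[t] <- sum(nxt) / sum(cur)
      nxt <- nxt / sum(nxt)
    }
    nmat[, t + 1] <- nxt
    cur <- nxt
  }
  list(n = nmat, growth = growth)
}

#' Stable population structure, growth rate, and reproductive value
#'
#' Computes the dominant eigenvalue `lambda` (the eigenvalue of maximal
#' modulus admitting a nonnegative right eigenvector), the stable joint
#' age x stage distribution `w` (normalized to sum 1 over possible
#' states), its age and stage marginals, and the reproductive value vector
#' `v`, scaled internally so that `sum(v * w) = 1` (the scaling required
#' by the eigenvalue sensitivity formula) and additionally reported
#' relative to a reference state if one is given.
#'
#' Among eigenvalues numerically tied in modulus (relative 1e-10), the one
#' with a nonnegative right eigenvector is chosen; if several *distinct*
#' tied eigenvalues admit nonnegative eigenvectors the structure is
#' ambiguous and an error names them. Reducibility introduced by
#' impossible-state masking is handled by restricting checks to possible
#' states.
#'
#' Ergodicity diagnostic: `ergodic_flags` marks possible states whose
#' reproductive value is (numerically) zero. If any are flagged, an
#' initial population confined to those states would not converge to `w`;
#' post-reproductive subspaces are the classic example.
#'
#' @param model An `agestage_model`.
#' @param reference_state Optional joint state index; `v_report` is `v`
#'   rescaled so that this state has reproductive value 1.
#' @return An object of class `agestage_stable`: list with `lam`, `w`,
#'   `v`, `w_age`, `w_stage`, `v_report`, `ergodic_flags`.
#' @export
stable_analysis <- function(model, reference_state = NULL) {
  stopifnot(inherits(model, "agestage_model"))
  A <- model$A
  if (all(A == 0)) stop("projection matrix is identically zero")
  n <- nrow(A)
  eA <- eigen(A)
  mods <- Mod(eA$values)
  lam_mod <- max(mods)
  cand <- which(mods >= lam_mod * (1 - 1e-10))
  ok <- logical(length(cand))
  for (k in seq_along(cand)) {
    wv <- eA$vectors[, cand[k]]
    if (max(abs(Im(wv))) < 1e-8 * max(abs(wv))) {
      wr <- Re(wv)
      wr <- wr * sign(sum(wr))
      ok[k] <- all(wr >= -1e-8 * max(abs(wr)))
    }
  }
  if (!any(ok)) stop("no candidate dominant eigenvalue has a nonnegative eigenvector")
  vals <- Re(eA$values[cand[ok]])
  if (length(unique(round(vals, 10))) > 1) {
    stop("ambiguous dominant eigenvalue: distinct eigenvalues of equal ",
         "modulus with nonnegative eigenvectors: ",
         paste(format(unique(round(vals, 10))), collapse = ", "))
  }
  pick <- cand[ok][1]
  lam <- Re(eA$values[pick])
  w <- Re(eA$vectors[, pick])
  w <- w * sign(sum(w))
  w[!model$possible] <- 0
  w[w < 0] <- 0
  w <- w / sum(w)
  # left eigenvector of A = right eigenvector of t(A) for the same lambda
  eAt <- eigen(t(A))
  pickv <- which.min(abs(eAt$values - lam))
  v <- Re(eAt$vectors[, pickv])
  v <- v * sign(sum(v * w))
  v <- v / sum(v * w)
  s <- model$s; omega <- model$omega
  v_report <- NULL
  if (!is.null(reference_state)) {
    if (v[reference_state] == 0) {
      stop("reference state has zero reproductive value; cannot rescale")
    }
    v_report <- v / v[reference_state]
  }
  tolv <- 1e-10 * max(abs(v))
  structure(
    list(lam = lam, w = w, v = v,
         w_age = as.vector(age_marginal_operator(s, omega) %*% w),
         w_stage = as.vector(stage_marginal_operator(s, omega) %*% w),
         v_report = v_report,
         ergodic_flags = model$possible & (abs(v) <= tolv)),
    class = "agestage_stable"
  )
}

#' @export
print.agestage_stable <- function(x, ...) {
  cat(sprintf("Stable population: lambda = %.6f\n", x$lam))
  cat("Stage marginal of w:", paste(sprintf("%.4f", x$w_stage), collapse = " "), "\n")
  if (any(x$ergodic_flags)) {
    cat("Warning:", sum(x$ergodic_flags),
        "possible state(s) have zero reproductive value (reducible dynamics)\n")
  }
  invisible(x)
}

#' Birth mixing distribution from the stable structure
#'
#' Extracts the age-class-1 block of the stable joint distribution and
#' normalizes it to sum 1: the stage distribution of newborns in the
#' stable population, the natural mixing distribution for cohort analyses.
#'
#' @param structure An `agestage_stable` object.
#' @param s Number of stages.
#' @return Length-`s` probability vector.
#' @export
birth_mixture_from_stable <- function(structure, s) {
  stopifnot(inherits(structure, "agestage_stable"))
  w1 <- structure$w[seq_len(s)]
  tot <- sum(w1)
  if (tot <= 0) stop("no mass in age class 1 of the stable structure: no births")
  w1 / tot
}

#' Net reproductive rate via the next-generation matrix
#'
#' The next-generation matrix `R = F %*% N_fund` maps births to births of
#' the next generation. Under the stages-within-ages ordering only its
#' first block row is nonzero, so `R` is block upper-triangular and its
#' dominant eigenvalue equals that of the `s x s` birth-to-birth block
#' `R11` (extracted with the selector `Z = [I_s | 0]`): the net
#' reproductive rate `R0`, the per-generation growth rate. The (i, j)
#' entry of `R11` is the expected lifetime production of stage-`i`
#' offspring by an individual born in stage `j`.
#'
#' @param model An `agestage_model`.
#' @param N_fund Fundamental matrix.
#' @return An object of class `agestage_repro`: list with `R_ngm`
#'   (`s*omega x s*omega`), `R11` (`s x s`), and `R0`. The equality of the
#'   dominant eigenvalues of `R11` and the full matrix is verified to
#'   1e-10 (relative).
#' @export
net_reproductive_rate <- function(model, N_fund) {
  stopifnot(inherits(model, "agestage_model"))
  s <- model$s
  R_ngm <- model$F %*% N_fund
  R11 <- R_ngm[seq_len(s), seq_len(s), drop = FALSE]
  R0 <- max(Mod(eigen(R11, only.values = TRUE)$values), 0)
  R0_full <- max(Mod(eigen(R_ngm, only.values = TRUE)$values), 0)
  if (abs(R0 - R0_full) > 1e-10 * max(1, R0)) {
    stop("internal inconsistency: eigenvalues of R11 and the full ",
         "next-generation matrix disagree")
  }
  structure(list(R_ngm = R_ngm, R11 = R11, R0 = R0),
            class = "agestage_repro")
}

#' Aggregations of lifetime reproduction
#'
#' Summarizes the birth-to-birth block `R11` the same three ways as the
#' age-specific fertility matrices: `r_weighted = t(t(c) %*% R11)` (mean
#' weighted lifetime reproduction by an individual born in each stage),
#' `r_mixed = R11 %*% pi` (mean lifetime production of each offspring type
#' by a mixed cohort), and the scalar `rho = t(c) %*% R11 %*% pi`. When a
#' single offspring type is produced, `rho` with the indicator weight and
#' point-mass mixture reduces to `R0`.
#'
#' @param R11 The `s x s` birth-to-birth next-generation block.
#' @param c Offspring weight vector (length `s`).
#' @param pi Birth-stage mixing distribution (length `s`).
#' @return List with `r_weighted`, `r_mixed`, `rho`.
#' @export
lifetime_reproduction <- function(R11, c, pi) {
  R11 <- as.matrix(R11)
  s <- nrow(R11)
  c <- as.numeric(c)
  if (length(c) != s) stop("'c' must have length ", s)
  pi <- as_mixing(pi, s)
  list(r_weighted = as.vector(c %*% R11),
       r_mixed = as.vector(R11 %*% pi),
       rho = as.vector(c %*% R11 %*% pi))
}

#' Generation times
#'
#' Two measures. The growth-rate generation time `T = log(R0) / log(lambda)`
#' is the time needed for the population to grow by a factor of its
#' per-generation growth rate; it is undefined (`NA`) when `lambda = 1`.
#' The cohort generation time `Gamma` is the vector of mean ages at which
#' a cohort produces offspring of each type, computed from the exact
#' closed form
#' \deqn{\Gamma = D(\phi_{life})^{-1} (e_1^\top \otimes I_s)
#'       \tilde F \tilde N \tilde U \tilde N \tilde n_0,}
#' where `phi_life` is the vector of expected lifetime offspring by type
#' and the identity \eqn{\sum_x x \tilde U^x = \tilde N \tilde U \tilde N}
#' replaces the infinite series. Age is counted from `x = 0` at entry into
#' age class 1 (reproduction during the first projection interval happens
#' at age 0). Offspring types never produced get `Gamma = 0`.
#'
#' @param model An `agestage_model`.
#' @param N_fund Fundamental matrix.
#' @param n0 Cohort joint vector: unit 1-norm, mass only in age class 1.
#' @param lam,R0 Optional growth rate and net reproductive rate for `T`;
#'   computed from the model if omitted.
#' @return An object of class `agestage_gentime`: list with `T` (scalar or
#'   `NA`), `Gamma` (length-`s` vector), `phi_life` (length-`s` vector).
#' @export
generation_times <- function(model, N_fund, n0, lam = NULL, R0 = NULL) {
  stopifnot(inherits(model, "agestage_model"))
  s <- model$s; omega <- model$omega
  n0 <- as.numeric(n0)
  if (length(n0) != s * omega) stop("'n0' has the wrong length")
  if (any(n0 < 0)) stop("'n0' must be nonnegative")
  if (omega > 1 && any(n0[-seq_len(s)] != 0)) {
    stop("'n0' must be a cohort: mass only in age class 1")
  }
  if (abs(sum(n0) - 1) > 1e-8) stop("'n0' must have unit 1-norm")
  n0 <- n0 / sum(n0)
  if (is.null(lam)) lam <- stable_analysis(model)$lam
  if (is.null(R0)) R0 <- net_reproductive_rate(model, N_fund)$R0
  T_gen <- if (R0 > 0 && abs(lam - 1) > 1e-12) log(R0) / log(lam) else NA_real_
  sel <- seq_len(s)                                # (e1' (x) I_s) rows
  FN <- model$F %*% N_fund
  phi_life <- as.vector(FN %*% n0)[sel]
  num <- as.vector(FN %*% (model$U %*% (N_fund %*% n0)))[sel]
  Gamma <- numeric(s)
  pos <- phi_life > 0
  Gamma[pos] <- num[pos] / phi_life[pos]   # never-produced types stay 0
  structure(list(T = T_gen, Gamma = Gamma, phi_life = phi_life),
            class = "agestage_gentime")
}
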