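# Matrix-calculus sensitivity analysis. The derivative of any output xi
# with respect to any parameter vector theta factors into five terms:
#
#   d xi / d theta' =
#     (d xi / d vec' Utilde) (I (x) K'DK) sum_i (Qi' (x) Pi) (d vec Ui / d theta')
#   + (d xi / d vec' Ftilde) (I (x) K'HK) sum_i (Qi' (x) Pi) (d vec Fi / d theta')
#
# Only the first factor depends on the output; only the last on the
# parameters. The middle factors are 0-1 structural matrices fixed by
# (s, omega, D, H, K). They are never materialized in the assembled
# product: the Kronecker identities vec(M X) = (I (x) M) vec(X) and
# vec(P X Q) = (Q' (x) P) vec(X) reduce every product to reshapes and
# small matrix multiplications, so the cost is O(p * (s*omega)^2) for p
# parameters.

#' Sensitivity of the population growth rate to the projection matrix
#'
#' The classic eigenvalue perturbation result: with right and left
#' eigenvectors scaled so that `sum(v * w) = 1`,
#' `d lambda / d vec'(A) = t(w) (x) t(v)`; the entry for `A[i, j]` is
#' `v[i] * w[j]`. The scaling is enforced here, not trusted from the
#' caller.
#'
#' @param structure An `agestage_stable` object.
#' @return Row vector (1 x (s*omega)^2) over `vec(A)`.
#' @export
dlambda_dA <- function(structure) {
  stopifnot(inherits(structure, "agestage_stable"))
  w <- structure$w
  v <- structure$v
  vw <- sum(v * w)
  if (abs(vw) < 1e-300) stop("degenerate eigenvector scaling: sum(v * w) = 0")
  v <- v / vw
  matrix(w, nrow = 1) %x% matrix(v, nrow = 1)
}

#' Elasticity matrix of the population growth rate
#'
#' `e[i, j] = (A[i, j] / lambda) * d lambda / d A[i, j]`; the entries sum
#' to 1.
#'
#' @param model An `agestage_model`.
#' @param structure An `agestage_stable` object for the same model.
#' @return Matrix of elasticities, same shape as `A`.
#' @export
elasticity_lambda <- function(model, structure) {
  sens <- matrix(dlambda_dA(structure), nrow(model$A), ncol(model$A))
  model$A * sens / structure$lam
}

#' Sensitivity of the net reproductive rate to the model matrices
#'
#' Differentiating `R = F %*% N` with `N = solve(I - U)` and applying the
#' eigenvalue perturbation result to `R` gives, with `y`/`x` the
#' right/left eigenvectors of the next-generation matrix scaled so that
#' `sum(y * x) = 1`:
#' * with respect to `vec(F)`: `t(N %*% y) (x) t(x)`
#' * with respect to `vec(U)`: `t(N %*% y) (x) t(t(R) %*% x)`
#'
#' If `R0 = 0` (no reproduction) both derivatives are flagged zero.
#'
#' @param model An `agestage_model`.
#' @param N_fund Fundamental matrix.
#' @param repro An `agestage_repro` object from [net_reproductive_rate()].
#' @return List with row vectors `dF` (over `vec(Ftilde)`) and `dU` (over
#'   `vec(Utilde)`), and logical `zero` (TRUE when `R0 = 0`).
#' @export
dR0_dA <- function(model, N_fund, repro) {
  stopifnot(inherits(model, "agestage_model"), inherits(repro, "agestage_repro"))
  n <- nrow(model$A)
  if (repro$R0 <= 0) {
    z <- matrix(0, 1, n * n)
    return(list(dF = z, dU = z, zero = TRUE))
  }
  R <- repro$R_ngm
  eR <- eigen(R)
  py <- which.min(abs(eR$values - repro$R0))
  y <- Re(eR$vectors[, py])
  eRt <- eigen(t(R))
  px <- which.min(abs(eRt$values - repro$R0))
  x <- Re(eRt$vectors[, px])
  x <- x / sum(y * x)                       # enforce y' x = 1
  Ny <- as.vector(N_fund %*% y)
  Rx <- as.vector(x %*% R)                  # t(R) %*% x as a row
  list(dF = matrix(Ny, nrow = 1) %x% matrix(x, nrow = 1),
       dU = matrix(Ny, nrow = 1) %x% matrix(Rx, nrow = 1),
       zero = FALSE)
}

#' Structural Jacobians of the vec-permutation construction
#'
#' The middle terms of the sensitivity chain depend only on the dimensions
#' and the age operators, never on the output or the parameters. They are
#' returned in structured form: `M_U = K'DK` and `M_F = K'HK` (each
#' `s*omega x s*omega`), with the understanding that
#' `d vec(Utilde) / d vec'(U) = I (x) M_U` (and similarly for F), and
#' that `d vec(U) / d vec'(U_i) = t(Q_i) (x) P_i`, whose action is to
#' place `vec(U_i)` into diagonal block `i` of `vec(U)`.
#'
#' With `dense = TRUE` (only for `s*omega <= 40`) the full 0-1 matrices
#' are also materialized: `term2_U`, `term2_F` (`(s*omega)^2` square) and
#' the list `term3` of `(s*omega)^2 x s^2` block-placement matrices.
#'
#' @param model An `agestage_model`.
#' @param dense Materialize the full Kronecker matrices (small models
#'   only).
#' @return List with `M_U`, `M_F`, and (if `dense`) `term2_U`, `term2_F`,
#'   `term3`.
#' @export
structural_jacobians <- function(model, dense = FALSE) {
  stopifnot(inherits(model, "agestage_model"))
  s <- model$s; omega <- model$omega
  n <- s * omega
  p <- model$perm; ip <- order(p)
  DD <- block_diagonal(model$schedules$D)
  HH <- block_diagonal(model$schedules$H)
  M_U <- DD[ip, ip, drop = FALSE]           # K' D K
  M_F <- HH[ip, ip, drop = FALSE]
  out <- list(M_U = M_U, M_F = M_F)
  if (dense) {
    if (n > 40) stop("refusing to materialize (s*omega)^2-square matrices for s*omega > 40")
    out$term2_U <- diag(n) %x% M_U
    out$term2_F <- diag(n) %x% M_F
    out$term3 <- lapply(seq_len(omega), function(i) {
      Pi <- matrix(0, n, s); Pi[(i - 1) * s + seq_len(s), ] <- diag(s)
      Qi <- matrix(0, s, n); Qi[, (i - 1) * s + seq_len(s)] <- diag(s)
      t(Qi) %x% Pi
    })
  }
  out
}

#' Survival/transition decomposition of a stage matrix
#'
#' Factors `U_i = G_i %*% diag(sigma_i)` where `sigma_i` holds the
#' stage-specific survival probabilities (column sums of `U_i`) and `G_i`
#' contains the transition probabilities conditional on survival (columns
#' summing to 1 wherever `sigma > 0`; columns with `sigma = 0` are left
#' zero, where the factorization is arbitrary).
#'
#' @param U_i An `s x s` stage transition/survival matrix.
#' @return List with `G`, `sigma`, reproducing `U_i` to 1e-12.
#' @export
survival_decomposition <- function(U_i) {
  U_i <- as.matrix(U_i)
  sigma <- colSums(U_i)
  G <- U_i
  posv <- sigma > 0
  G[, posv] <- sweep(U_i[, posv, drop = FALSE], 2, sigma[posv], "/")
  G[, !posv] <- 0
  if (max(abs(G %*% diag(sigma, nrow = length(sigma)) - U_i)) > 1e-12) {
    stop("survival decomposition failed to reproduce U_i")
  }
  list(G = G, sigma = sigma)
}

#' Parameter Jacobian for multiplicative survival perturbations
#'
#' For the parameterization `sigma_i = sigma_hat_i * theta` (elementwise)
#' with `U_i = G_i %*% diag(sigma_i)`, the Jacobian of `vec(U_i)` with
#' respect to `theta` is
#' `(I_s (x) G_i) diag(vec(I_s)) (I_s (x) 1_s) diag(sigma_hat_i)`,
#' an `s^2 x s` matrix. Because the perturbation touches survival only,
#' the fertility counterpart of this term is zero.
#'
#' @param G Conditional transition matrix from [survival_decomposition()];
#'   columns must sum to 1 wherever the baseline survival is positive.
#' @param sigma_hat Baseline stage-specific survival vector.
#' @return The `s^2 x s` Jacobian `d vec(U_i) / d theta'`.
#' @export
survival_parameter_jacobian <- function(G, sigma_hat) {
  G <- as.matrix(G)
  s <- nrow(G)
  stopifnot(ncol(G) == s, length(sigma_hat) == s)
  csum <- colSums(G)
  if (any(sigma_hat > 0 & abs(csum - 1) > 1e-8)) {
    stop("columns of G must sum to 1 where baseline survival is positive")
  }
  J <- (diag(s) %x% G) %*% diag(as.vector(diag(s))) %*% (diag(s) %x% matrix(1, s, 1))
  J %*% diag(sigma_hat, nrow = s)
}

#' Assemble the full sensitivity chain
#'
#' Combines an output derivative (`term1_U`, `term1_F`: rows over
#' `vec(Utilde)` and `vec(Ftilde)`, e.g. from [dlambda_dA()] -- where the
#' two coincide -- or [dR0_dA()]) with per-age parameter Jacobians
#' (`term4`, `term5`: lists over age classes of `s^2 x p` matrices, `NULL`
#' entries meaning zero). The structural middle terms are applied through
#' Kronecker identities, so no `(s*omega)^2`-square matrix is ever formed.
#'
#' @param model An `agestage_model`.
#' @param term1_U,term1_F Row vectors of length `(s*omega)^2` (either may
#'   be `NULL` for zero).
#' @param term4,term5 Lists of length `omega` with `s^2 x p` Jacobians of
#'   `vec(U_i)` and `vec(F_i)` with respect to the parameters (`NULL`
#'   entries are zero).
#' @param p Number of parameters (inferred from the first non-`NULL`
#'   Jacobian if omitted).
#' @return Row vector `d xi / d theta'` of length `p`.
#' @export
assemble_sensitivity <- function(model, term1_U = NULL, term1_F = NULL,
                                 term4 = NULL, term5 = NULL, p = NULL) {
  stopifnot(inherits(model, "agestage_model"))
  s <- model$s; omega <- model$omega
  n <- s * omega
  if (is.null(p)) {
    for (lst in list(term4, term5)) {
      if (!is.null(lst)) {
        for (J in lst) if (!is.null(J)) { p <- ncol(J); break }
      }
      if (!is.null(p)) break
    }
    if (is.null(p)) stop("no parameter Jacobians supplied")
  }
  sj <- structural_jacobians(model)
  out <- numeric(p)
  one_side <- function(term1, M, terms) {
    if (is.null(term1) || is.null(terms)) return(numeric(p))
    if (length(term1) != n * n) {
      stop("conformability: term1 has length ", length(term1),
           ", expected ", n * n)
    }
    T1 <- matrix(as.vector(term1), n, n)       # reshape row over vec(Xtilde)
    A_blk <- crossprod(M, T1)                   # row * (I (x) M) reshaped
    acc <- numeric(p)
    for (i in seq_len(omega)) {
      J <- terms[[i]]
      if (is.null(J)) next
      if (nrow(J) != s * s || ncol(J) != p) {
        stop("conformability: parameter Jacobian for age class ", i,
             " is ", nrow(J), " x ", ncol(J), ", expected ", s * s, " x ", p)
      }
      idx <- (i - 1) * s + seq_len(s)
      blk <- A_blk[idx, idx, drop = FALSE]      # row * (Qi' (x) Pi) reshaped
      acc <- acc + as.vector(matrix(as.vector(blk), nrow = 1) %*% J)
    }
    acc
  }
  out <- one_side(term1_U, sj$M_U, term4) + one_side(term1_F, sj$M_F, term5)
  matrix(out, nrow = 1)
}

#' Sensitivity of lambda or R0 to survival perturbations at chosen ages
#'
#' Convenience wrapper for the full chain with the multiplicative survival
#' parameterization: `theta` is an `s`-vector of survival multipliers
#' (baseline 1) applied at the age classes in `ages`. Returns both the
#' analytic sensitivities by stage and (optionally) the elasticities.
#'
#' @param model An `agestage_model`.
#' @param output `"lambda"` or `"R0"`.
#' @param ages Integer vector of age classes whose survival is perturbed.
#' @return Row vector of length `s`: `d output / d theta'` at the
#'   baseline.
#' @export
sensitivity_survival <- function(model, output = c("lambda", "R0"),
                                 ages = seq_len(model$omega)) {
  output <- match.arg(output)
  s <- model$s
  if (output == "lambda") {
    t1 <- dlambda_dA(stable_analysis(model))
    term1_U <- t1; term1_F <- t1
  } else {
    N <- fundamental_matrix(model)
    d <- dR0_dA(model, N, net_reproductive_rate(model, N))
    term1_U <- d$dU; term1_F <- d$dF
  }
  term4 <- vector("list", model$omega)
  for (i in ages) {
    dec <- survival_decomposition(model$schedules$U[[i]])
    term4[[i]] <- survival_parameter_jacobian(dec$G, dec$sigma)
  }
  assemble_sensitivity(model, term1_U = term1_U, term1_F = term1_F,
                       term4 = term4, term5 = NULL, p = s)
}

#' Central finite differences
#'
#' Second-order-accurate validator for the analytic sensitivities:
#' `(f(theta + h e_k) - f(theta - h e_k)) / (2 h)` for each parameter.
#'
#' @param f Function from a parameter vector to a (scalar or vector)
#'   output; must be deterministic.
#' @param theta Point of evaluation.
#' @param h Step size (default 1e-6).
#' @return Matrix `length(f) x length(theta)` of derivatives.
#' @export
finite_difference <- function(f, theta, h = 1e-6) {
  theta <- as.numeric(theta)
  f0 <- f(theta)
  out <- matrix(NA_real_, length(f0), length(theta))
  for (k in seq_along(theta)) {
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    fu <- f(up); fd <- f(dn)
    if (any(!is.finite(fu)) || any(!is.finite(fd))) {
      stop("non-finite output at perturbed parameter ", k)
    }
    out[, k] <- (fu - fd) / (2 * h)
  }
  out
}
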