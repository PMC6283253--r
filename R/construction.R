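# Model construction: vec-permutation block assembly of age x stage
# projection matrices.
#
# Index convention used throughout the package: the joint state vector
# groups stages within age classes, so joint index k = (age - 1) * s + stage
# (1-based). This is the vec of the s x omega array N whose rows are stages
# and columns are age classes, and it gives the assembled projection matrix
# its block-Leslie form (fertility blocks across the first block row,
# transition blocks on the block subdiagonal).

#' Vec-permutation matrix
#'
#' Returns the permutation matrix \eqn{K_{m,n}} connecting the vec operator
#' and the matrix transpose: \eqn{K_{m,n} \mathrm{vec}(X) = \mathrm{vec}(X^\top)}
#' for every \eqn{m \times n} matrix \eqn{X}. In an age x stage model with
#' `m = s` stages and `n = omega` age classes, \eqn{K_{s,\omega}} swaps the
#' stages-within-ages and ages-within-stages orderings of the joint state
#' vector.
#'
#' Internally the permutation is carried as an index map (see
#' [vec_perm_indices()]); this function materializes it as a dense 0-1
#' matrix.
#'
#' @param m Number of rows of the matrices to be vec'd (stages), >= 1.
#' @param n Number of columns (age classes), >= 1.
#' @return An `mn x mn` permutation matrix.
#' @seealso [vec_perm_indices()] for the index-map form.
#' @export
#' @examples
#' K <- vec_perm_matrix(3, 5)
#' X <- matrix(rnorm(15), 3, 5)
#' all.equal(as.vector(K %*% as.vector(X)), as.vector(t(X)))
vec_perm_matrix <- function(m, n) {
  p <- vec_perm_indices(m, n)
  K <- matrix(0, m * n, m * n)
  K[cbind(seq_along(p), p)] <- 1
  K
}

#' Vec-permutation index map
#'
#' The permutation `p` such that `x[p]` equals `K_{m,n} %*% x`; applying
#' the vec-permutation matrix never requires more than indexing one joint
#' vector.
#'
#' @inheritParams vec_perm_matrix
#' @return Integer vector of length `m * n`.
#' @export
vec_perm_indices <- function(m, n) {
  stopifnot(is.numeric(m), is.numeric(n), length(m) == 1, length(n) == 1)
  if (m < 1 || n < 1 || m != round(m) || n != round(n)) {
    stop("dimensions 'm' and 'n' must be positive integers")
  }
  # row (i-1)*n + j of K picks entry (j-1)*m + i of vec(X)
  i <- rep(seq_len(m), each = n)
  j <- rep(seq_len(n), times = m)
  as.integer((j - 1L) * m + i)
}

#' Default age-advance and age-assignment operators
#'
#' The age-advance matrix `D` has ones on the subdiagonal, moving surviving
#' individuals to the next age class; its (omega, omega) corner defaults to
#' 1, which makes the final age class an open-ended category (setting
#' `final_survival = 0` instead kills all individuals reaching age omega).
#' The age-assignment matrix `H` has ones across row 1: all newborns enter
#' age class 1 regardless of parental age.
#'
#' One copy of each is returned per stage; age-advance mortality can be
#' introduced by supplying custom column-substochastic `D` matrices to
#' [make_schedules()], but the default builder never generates it.
#'
#' @param s Number of stages.
#' @param omega Number of age classes.
#' @param final_survival Entry placed in the (omega, omega) corner of each
#'   `D`; default 1 (open-ended final age class).
#' @return A list with components `D` and `H`, each a list of `s` matrices
#'   of dimension `omega x omega`.
#' @export
default_age_operators <- function(s, omega, final_survival = 1) {
  stopifnot(s >= 1, omega >= 1, final_survival >= 0, final_survival <= 1)
  D <- matrix(0, omega, omega)
  if (omega > 1) D[cbind(2:omega, 1:(omega - 1))] <- 1
  D[omega, omega] <- final_survival
  H <- matrix(0, omega, omega)
  H[1, ] <- 1
  list(D = rep(list(D), s), H = rep(list(H), s))
}

#' Bundle per-age-class vital rate matrices into a schedule set
#'
#' A schedule set holds the biological content of an age x stage model:
#' stage transition/survival matrices `U[[j]]` and fertility matrices
#' `F[[j]]` (both `s x s`) for each age class `j = 1..omega`, the age
#' operators `D[[i]]` and `H[[i]]` (both `omega x omega`) for each stage
#' `i = 1..s`, and an optional mask of impossible (stage, age) combinations
#' whose rows and columns are zeroed before assembly.
#'
#' @param U List of `omega` nonnegative `s x s` matrices; every column sum
#'   must lie in `[0, 1 + tol]`.
#' @param F List of `omega` nonnegative `s x s` fertility matrices.
#' @param D Optional list of `s` column-substochastic `omega x omega`
#'   age-advance matrices; defaults from [default_age_operators()].
#' @param H Optional list of `s` column-stochastic `omega x omega`
#'   age-assignment matrices; defaults assign all newborns to age class 1.
#' @param impossible Optional two-column matrix (or data.frame) of
#'   impossible (stage, age) index pairs.
#' @param final_survival Passed to [default_age_operators()] when `D` is
#'   not supplied.
#' @param tol Tolerance for the substochasticity check (default 1e-10).
#'   Violations are errors, not warnings: silently allowing column sums
#'   above one corrupts every downstream Markov chain result.
#' @return An object of class `agestage_schedules`.
#' @export
make_schedules <- function(U, F, D = NULL, H = NULL, impossible = NULL,
                           final_survival = 1, tol = 1e-10) {
  if (!is.list(U) || !length(U)) stop("'U' must be a non-empty list of s x s matrices")
  if (!is.list(F) || length(F) != length(U)) {
    stop("'F' must be a list of the same length (omega) as 'U'")
  }
  U <- lapply(U, as.matrix)
  F <- lapply(F, as.matrix)
  s <- nrow(U[[1]])
  omega <- length(U)
  for (j in seq_len(omega)) {
    if (!all(dim(U[[j]]) == c(s, s))) stop("'U[[", j, "]]' is not ", s, " x ", s)
    if (!all(dim(F[[j]]) == c(s, s))) stop("'F[[", j, "]]' is not ", s, " x ", s)
  }
  if (is.null(D) || is.null(H)) {
    defaults <- default_age_operators(s, omega, final_survival)
    if (is.null(D)) D <- defaults$D
    if (is.null(H)) H <- defaults$H
  }
  D <- lapply(D, as.matrix)
  H <- lapply(H, as.matrix)
  if (length(D) != s || length(H) != s) {
    stop("'D' and 'H' must each contain one omega x omega matrix per stage")
  }
  if (!is.null(impossible)) {
    impossible <- as.matrix(impossible)
    if (ncol(impossible) != 2) stop("'impossible' needs two columns: stage, age")
    storage.mode(impossible) <- "integer"
    colnames(impossible) <- c("stage", "age")
  } else {
    impossible <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("stage", "age")))
  }
  out <- structure(
    list(s = s, omega = omega, U = U, F = F, D = D, H = H,
         impossible = impossible, tol = tol),
    class = "agestage_schedules"
  )
  validate_schedules(out)
  out
}

#' Validate a schedule set
#'
#' Checks nonnegativity, column substochasticity of every `U[[j]]` and
#' `D[[i]]`, and column stochasticity of every `H[[i]]`. Errors name the
#' offending age class and stage.
#'
#' @param schedules An `agestage_schedules` object.
#' @param tol Substochasticity tolerance; defaults to the value stored at
#'   construction.
#' @return `schedules`, invisibly.
#' @export
validate_schedules <- function(schedules, tol = schedules$tol) {
  s <- schedules$s; omega <- schedules$omega
  for (j in seq_len(omega)) {
    Uj <- schedules$U[[j]]
    if (any(Uj < 0)) stop("negative entry in U for age class ", j)
    if (any(schedules$F[[j]] < 0)) stop("negative entry in F for age class ", j)
    cs <- colSums(Uj)
    bad <- which(cs > 1 + tol)
    if (length(bad)) {
      stop("column sum of U exceeds 1 for age class ", j,
           ", stage ", bad[1], " (sum = ", format(cs[bad[1]]), ")")
    }
  }
  for (i in seq_len(s)) {
    Di <- schedules$D[[i]]; Hi <- schedules$H[[i]]
    if (!all(dim(Di) == c(omega, omega))) stop("D for stage ", i, " is not omega x omega")
    if (!all(dim(Hi) == c(omega, omega))) stop("H for stage ", i, " is not omega x omega")
    if (any(Di < 0) || any(colSums(Di) > 1 + tol)) {
      stop("D for stage ", i, " must be nonnegative with column sums <= 1")
    }
    if (any(Hi < 0) || any(abs(colSums(Hi) - 1) > 1e-8)) {
      stop("H for stage ", i, " must be column-stochastic")
    }
  }
  imp <- schedules$impossible
  if (nrow(imp)) {
    if (any(imp[, 1] < 1 | imp[, 1] > s)) stop("impossible-mask stage index out of range")
    if (any(imp[, 2] < 1 | imp[, 2] > omega)) stop("impossible-mask age index out of range")
  }
  invisible(schedules)
}

#' Zero out impossible age x stage combinations
#'
#' For each masked pair (stage `i`, age `j`), row `i` and column `i` of
#' `U[[j]]` and `F[[j]]` are set to zero: no individual can enter, leave, or
#' reproduce from an impossible state. All other entries are unchanged.
#'
#' @param schedules An `agestage_schedules` object with a non-empty
#'   `impossible` component (an empty mask returns the schedules unchanged).
#' @return The masked `agestage_schedules` object.
#' @export
apply_impossible_mask <- function(schedules) {
  stopifnot(inherits(schedules, "agestage_schedules"))
  imp <- schedules$impossible
  if (!nrow(imp)) return(schedules)
  validate_schedules(schedules)
  for (k in seq_len(nrow(imp))) {
    i <- imp[k, 1]; j <- imp[k, 2]
    schedules$U[[j]][i, ] <- 0; schedules$U[[j]][, i] <- 0
    schedules$F[[j]][i, ] <- 0; schedules$F[[j]][, i] <- 0
  }
  schedules
}

#' Direct sum of square matrices
#'
#' Places the given blocks down the diagonal of an otherwise-zero matrix,
#' as in the block-diagonal matrices of the vec-permutation construction.
#'
#' @param blocks List of square matrices, all of the same order.
#' @return The dense block-diagonal matrix.
#' @export
block_diagonal <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  d <- unique(vapply(blocks, function(b) {
    b <- as.matrix(b)
    if (nrow(b) != ncol(b)) stop("all blocks must be square")
    nrow(b)
  }, integer(1)))
  if (length(d) != 1) stop("all blocks must have the same size")
  as.matrix(Matrix::bdiag(blocks))
}

#' Logical vector of possible joint states
#'
#' @param s,omega Dimensions.
#' @param impossible Two-column (stage, age) mask matrix.
#' @return Logical vector of length `s * omega`, `FALSE` at masked states.
#' @keywords internal
possible_states <- function(s, omega, impossible) {
  ok <- rep(TRUE, s * omega)
  if (nrow(impossible)) {
    ok[(impossible[, 2] - 1L) * s + impossible[, 1]] <- FALSE
  }
  ok
}

#' Assemble the age x stage projection matrices
#'
#' Builds the joint transition matrix `U`, fertility matrix `F`, and
#' projection matrix `A = U + F` (all `s*omega x s*omega`) from a schedule
#' set by the vec-permutation algorithm:
#' \deqn{\tilde U = K^\top \mathbb{D} K \mathbb{U}, \qquad
#'       \tilde F = K^\top \mathbb{H} K \mathbb{F},}
#' where the blackboard matrices are block diagonals of the per-age
#' (`U`, `F`) and per-stage (`D`, `H`) schedules and `K` is the
#' vec-permutation matrix. Reading right to left: individuals move among
#' stages within their age class, the ordering is flipped to ages within
#' stages, ages advance (or newborns are assigned to age class 1), and the
#' ordering is flipped back. With the default age operators the result has
#' block-Leslie form: fertility blocks across the first block row,
#' transition blocks on the block subdiagonal, and `U[[omega]]` in the
#' open-ended corner.
#'
#' The impossible-state mask is applied before assembly and recorded in the
#' model so downstream normalization checks can exclude masked states.
#'
#' @param schedules An `agestage_schedules` object.
#' @return An object of class `agestage_model` with components `s`, `omega`,
#'   `U`, `F`, `A`, `perm` (the vec-permutation index map), `convention`
#'   (`"stage_within_age"`), `impossible`, `possible` (logical vector over
#'   joint states) and `schedules`.
#' @export
#' @examples
#' ops <- default_age_operators(1, 3)
#' sch <- make_schedules(U = list(0.5, 0.8, 0), F = list(0, 1.2, 2))
#' m <- assemble_model(sch)
#' m$A  # classic 3x3 Leslie matrix
assemble_model <- function(schedules) {
  stopifnot(inherits(schedules, "agestage_schedules"))
  schedules <- apply_impossible_mask(schedules)
  validate_schedules(schedules)
  s <- schedules$s; omega <- schedules$omega
  p <- vec_perm_indices(s, omega)
  ip <- order(p)                        # inverse permutation: K^T rows
  UU <- block_diagonal(schedules$U)     # stages within ages
  FF <- block_diagonal(schedules$F)
  DD <- block_diagonal(schedules$D)     # ages within stages
  HH <- block_diagonal(schedules$H)
  # K M = M[p, ]; K^T M = M[ip, ]
  Ut <- (DD %*% UU[p, , drop = FALSE])[ip, , drop = FALSE]
  Ft <- (HH %*% FF[p, , drop = FALSE])[ip, , drop = FALSE]
  structure(
    list(s = s, omega = omega, U = Ut, F = Ft, A = Ut + Ft, perm = p,
         convention = "stage_within_age", impossible = schedules$impossible,
         possible = possible_states(s, omega, schedules$impossible),
         schedules = schedules),
    class = "agestage_model"
  )
}

#' @export
print.agestage_model <- function(x, ...) {
  cat("Age x stage-classified model:", x$s, "stage(s) x", x$omega,
      "age class(es) =", x$s * x$omega, "joint states\n")
  cat("Index convention:", x$convention, "\n")
  if (nrow(x$impossible)) {
    cat("Masked impossible (stage, age) pairs:", nrow(x$impossible), "\n")
  }
  invisible(x)
}

#' Switch to the age-primary (ages-within-stages) ordering
#'
#' Conjugates the model matrices by the vec-permutation matrix,
#' `A' = K A K^T`, flipping the index convention so that age becomes the
#' primary classification and stage the secondary one. This is a similarity
#' transform, so all eigenvalues are unchanged; applying the function twice
#' returns the original model.
#'
#' @param model An `agestage_model`.
#' @return The reordered `agestage_model`.
#' @export
reorder_age_primary <- function(model) {
  stopifnot(inherits(model, "agestage_model"))
  p <- model$perm
  flip <- function(M) M[p, p, drop = FALSE]
  unflip <- function(M) {
    ip <- order(p)
    M[ip, ip, drop = FALSE]
  }
  f <- if (model$convention == "stage_within_age") flip else unflip
  model$U <- f(model$U); model$F <- f(model$F); model$A <- f(model$A)
  if (model$convention == "stage_within_age") {
    model$possible <- model$possible[order(p)]
    model$convention <- "age_within_stage"
  } else {
    model$possible <- model$possible[p]
    model$convention <- "stage_within_age"
  }
  model
}

#' Marginal and mixture operators on joint age x stage vectors
#'
#' Any linear combination of stages (a matrix `R` with `s` columns) and of
#' ages (a matrix `C` with `omega` rows) acting on the underlying
#' stage-by-age array `N` as `R N C` is realized on vec-ordered joint
#' vectors by the Kronecker operator \eqn{C^\top \otimes R}. The common
#' special cases have shortcuts:
#' * stage marginal (sum over ages): `stage_marginal_operator()`,
#'   \eqn{1_\omega^\top \otimes I_s};
#' * age marginal (sum over stages): `age_marginal_operator()`,
#'   \eqn{I_\omega \otimes 1_s^\top};
#' * age-class-1 mixture with stage weights `pi`:
#'   `age1_mixture_operator()`, \eqn{e_1^\top \otimes \pi^\top}.
#'
#' @param row_combine Matrix with `s` columns combining stages.
#' @param col_combine Matrix with `omega` rows combining ages.
#' @return The operator matrix `t(col_combine) %x% row_combine`.
#' @export
marginal_operator <- function(row_combine, col_combine) {
  row_combine <- as.matrix(row_combine)
  col_combine <- as.matrix(col_combine)
  t(col_combine) %x% row_combine
}

#' @rdname marginal_operator
#' @param s,omega Model dimensions.
#' @export
stage_marginal_operator <- function(s, omega) {
  marginal_operator(diag(s), matrix(1, omega, 1))
}

#' @rdname marginal_operator
#' @export
age_marginal_operator <- function(s, omega) {
  marginal_operator(matrix(1, 1, s), diag(omega))
}

#' @rdname marginal_operator
#' @param pi Stage mixing distribution (length `s`).
#' @export
age1_mixture_operator <- function(pi, omega) {
  e1 <- matrix(0, omega, 1); e1[1] <- 1
  marginal_operator(matrix(pi, 1), e1)
}

#' Normalize and validate a mixing distribution
#'
#' Mixing vectors must be nonnegative and sum to 1; deviations of at most
#' `1e-8` are renormalized silently, larger ones are errors.
#'
#' @param pi Numeric vector of mixture weights.
#' @param n Required length (optional).
#' @return The validated (renormalized) probability vector.
#' @export
as_mixing <- function(pi, n = NULL) {
  pi <- as.numeric(pi)
  if (!is.null(n) && length(pi) != n) {
    stop("mixing distribution has length ", length(pi), ", expected ", n)
  }
  if (any(pi < 0)) stop("mixing distribution has negative entries")
  s <- sum(pi)
  if (abs(s - 1) > 1e-8) stop("mixing distribution sums to ", format(s), ", not 1")
  pi / s
}
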