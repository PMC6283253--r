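# Model bundle serialization: the assembled matrices as CSV plus a JSON
# metadata file. Numbers are written with 17 significant digits so a
# write/read round trip reproduces the model to machine precision.

#' Write and read model bundles
#'
#' A bundle is a directory holding `U.csv`, `F.csv` (the assembled joint
#' matrices), `D.csv`, `H.csv` (the stacked per-stage age operators,
#' needed to rebuild the structural sensitivity terms), and
#' `metadata.json` (`s`, `omega`, index convention, impossible-state
#' mask). Reading reassembles the per-age schedules from the block
#' structure of the joint matrices, verifies the dimensions and the
#' convention against the metadata, and returns the model; a tampered or
#' inconsistent bundle is rejected.
#'
#' @param model An `agestage_model` in the stages-within-ages convention.
#' @param dir Directory to create/fill.
#' @return `write_model_bundle()` returns `dir` invisibly;
#'   `read_model_bundle()` returns the `agestage_model`.
#' @export
write_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "agestage_model"))
  if (model$convention != "stage_within_age") {
    stop("bundles store the stages-within-ages convention; reorder first")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(M, f) {
    utils::write.table(format(M, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(dir, f), sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  wr(model$U, "U.csv")
  wr(model$F, "F.csv")
  wr(do.call(rbind, model$schedules$D), "D.csv")
  wr(do.call(rbind, model$schedules$H), "H.csv")
  meta <- list(s = model$s, omega = model$omega,
               convention = model$convention,
               impossible = if (nrow(model$impossible)) {
                 unname(apply(model$impossible, 1, as.list))
               } else list())
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  s <- as.integer(meta$s); omega <- as.integer(meta$omega)
  rd <- function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  }
  Ut <- unname(rd("U.csv")); Ft <- unname(rd("F.csv"))
  Ds <- unname(rd("D.csv")); Hs <- unname(rd("H.csv"))
  n <- s * omega
  if (!all(dim(Ut) == n) || !all(dim(Ft) == n)) {
    stop("bundle integrity error: matrix dimensions do not match metadata ",
         "(s = ", s, ", omega = ", omega, ")")
  }
  if (!identical(meta$convention, "stage_within_age")) {
    stop("bundle integrity error: unknown index convention '",
         meta$convention, "'")
  }
  if (nrow(Ds) != s * omega || ncol(Ds) != omega ||
      nrow(Hs) != s * omega || ncol(Hs) != omega) {
    stop("bundle integrity error: age-operator dimensions do not match metadata")
  }
  imp <- if (length(meta$impossible)) {
    do.call(rbind, lapply(meta$impossible, function(x) {
      as.integer(unlist(x))
    }))
  } else NULL
  D <- lapply(seq_len(s), function(i) Ds[(i - 1) * omega + seq_len(omega), , drop = FALSE])
  H <- lapply(seq_len(s), function(i) Hs[(i - 1) * omega + seq_len(omega), , drop = FALSE])
  # recover per-age schedules from the block-Leslie layout; each joint
  # entry is D_i'(a', a) * U_a(i', i) (resp. H for F), so divide out the
  # age-operator weight where it is positive (where it is zero the joint
  # matrix carries no information and zero is as good a reconstruction)
  blk <- function(M, i, j) M[(i - 1) * s + seq_len(s), (j - 1) * s + seq_len(s), drop = FALSE]
  recover <- function(Mt, OP, a_to, a_from) {
    B <- blk(Mt, a_to, a_from)
    wt <- vapply(seq_len(s), function(i) OP[[i]][a_to, a_from], numeric(1))
    sweep(B, 1, ifelse(wt > 0, wt, 1), "/")
  }
  U <- vector("list", omega); F <- vector("list", omega)
  for (j in seq_len(omega)) F[[j]] <- recover(Ft, H, 1, j)
  if (omega > 1) for (j in seq_len(omega - 1)) U[[j]] <- recover(Ut, D, j + 1, j)
  U[[omega]] <- recover(Ut, D, omega, omega)
  sch <- make_schedules(U = U, F = F, D = D, H = H, impossible = imp)
  model <- assemble_model(sch)
  if (max(abs(model$U - Ut)) > 1e-12 || max(abs(model$F - Ft)) > 1e-12) {
    stop("bundle integrity error: stored joint matrices are not consistent ",
         "with a block-Leslie model built from their own blocks")
  }
  model
}
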