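# Thin R wrappers around the compiled ILU(0)-Krylov backend.

# Build a cached solver (CSR + ILU(0) factor) from a Matrix::dgCMatrix.
sparse_solver <- function(A, milu = FALSE) {
  A <- methods::as(A, "CsparseMatrix")
  stopifnot(nrow(A) == ncol(A))
  cpp_make_solver(A@p, A@i, A@x, nrow(A), milu)
}

# Solve with the cached solver.  method "cg" requires an SPD matrix.
krylov_solve <- function(solver, b, x0 = NULL, tol = 1e-10, maxit = 20000L,
                         method = c("cg", "bicgstab"), context = "linear solve",
                         must_converge = TRUE) {
  method <- match.arg(method)
  if (is.null(x0)) x0 <- numeric(length(b))
  res <- cpp_solve(solver, as.numeric(b), as.numeric(x0), tol,
                   as.integer(maxit), method)
  if (must_converge && !res$converged) {
    stop(sprintf("%s: Krylov solver (%s) failed to converge: relres = %.3g after %d iterations",
                 context, method, res$relres, res$iters))
  }
  res
}
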