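# Internal numerical helpers. All posterior algebra funnels through these so
# that ill-conditioned systems are flagged in one place.

# Inverse of a symmetric positive-definite matrix via Cholesky.
# Warns when the condition number exceeds ~1e10 (results still returned).
spd_inv <- function(M, label = "matrix") {
  M <- symmetrize(M)
  if (nrow(M) == 0L) return(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ns <- null_space_direction(M)
    stop(sprintf("%s is not positive definite; null-space direction ~ (%s)",
                 label, paste(signif(ns, 3), collapse = ", ")), call. = FALSE)
  }
  d <- diag(ch)^2
  if (max(d) / min(d) > 1e10)
    warning(sprintf("%s is ill conditioned (condition number > 1e10); results may be inaccurate",
                    label), call. = FALSE)
  symmetrize(chol2inv(ch))
}

symmetrize <- function(M) (M + t(M)) / 2

# Approximate direction along which a symmetric matrix is (near) singular,
# used only to make singular-system errors actionable.
null_space_direction <- function(M) {
  e <- eigen(symmetrize(M), symmetric = TRUE)
  v <- e$vectors[, which.min(e$values)]
  v / max(abs(v))
}

is_spd <- function(M, tol = 1e-10) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) return(FALSE)
  ev <- eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

# Block-diagonal assembly from a list of matrices (scalars allowed).
block_diag <- function(blocks) {
  blocks <- lapply(blocks, as.matrix)
  sizes <- vapply(blocks, nrow, integer(1))
  n <- sum(sizes)
  out <- matrix(0, n, n)
  at <- 0L
  for (B in blocks) {
    idx <- at + seq_len(nrow(B))
    out[idx, idx] <- B
    at <- at + nrow(B)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
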