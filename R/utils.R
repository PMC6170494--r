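# Internal numerical helpers shared across modules.

#' Largest singular value by power iteration
#'
#' Estimates \eqn{\sigma_{max}(X)} for a square symmetric positive
#' semidefinite matrix (the solver only needs spectral norms of Gram
#' matrices and graph Laplacians, which are all symmetric PSD).
#'
#' @param X symmetric PSD matrix (dense or \code{Matrix} sparse).
#' @param n_iter maximum power iterations.
#' @param tol relative change tolerance on the Rayleigh quotient.
#' @return non-negative scalar estimate of the top eigenvalue.
#' @keywords internal
#' @noRd
power_sigma_max <- function(X, n_iter = 50L, tol = 1e-6) {
  n <- nrow(X)
  if (n == 0L) return(0)
  # deterministic generic start vector (no RNG state consumed; an all-ones
  # start can be exactly orthogonal to the dominant eigenvector)
  v <- sin(seq_len(n))
  v <- v / sqrt(sum(v^2))
  sigma <- 0
  for (it in seq_len(n_iter)) {
    w <- as.numeric(X %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)
    v <- w / nw
    sigma_new <- as.numeric(crossprod(v, as.numeric(X %*% v)))
    if (it > 1L && abs(sigma_new - sigma) <= tol * max(1, abs(sigma_new))) {
      sigma <- sigma_new
      break
    }
    sigma <- sigma_new
  }
  max(sigma, 0)
}

# Counter-based sub-seed derivation: every stochastic replicate gets an
# independently reproducible seed below 2^31 derived from one master seed.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 8191) %% 2147483647)
}

# Evaluate expr with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}

# Minimum-norm least squares solve argmin_x ||A x - b||_2 via SVD,
# robust to rank deficiency (duplicate TF activity rows must not crash).
lstsq_min_norm <- function(A, b, rcond = 1e-10) {
  if (NCOL(A) == 0L) return(numeric(0))
  sv <- svd(A)
  d <- sv$d
  keep <- d > rcond * max(d, 0)
  if (!any(keep)) return(numeric(NCOL(A)))
  di <- ifelse(keep, 1 / d, 0)
  as.numeric(sv$v %*% (di * crossprod(sv$u, b)))
}

# Moore-Penrose pseudoinverse applied to a matrix RHS: X = pinv(A) %*% B.
pinv_solve <- function(A, B, rcond = 1e-10) {
  sv <- svd(A)
  d <- sv$d
  keep <- d > rcond * max(d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), ncol(B)))
  di <- ifelse(keep, 1 / d, 0)
  sv$v %*% (di * crossprod(sv$u, B))
}
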