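# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation; kept below 2^31 so set.seed() is safe.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 65011 + 1) * 32401 + index * 7919) %% 2147483587L
}

# x must be a non-negative multiple of `unit` (up to float tolerance)
is_multiple_of <- function(x, unit, tol = 1e-9) {
  abs(x / unit - round(x / unit)) < tol
}

stop_config <- function(...) stop(..., call. = FALSE)

# 4D array <-> scans x voxels matrix
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
}

set_run_matrix <- function(run, M) {
  d <- dim(run$data)
  stopifnot(nrow(M) == d[4], ncol(M) == prod(d[1:3]))
  run$data <- array(t(M), dim = d)
  run
}

# Residualize the columns of Y against the column space of X.
# Rank deficiency is tolerated (pivoted QR); a warning is emitted because it
# usually signals duplicated regressors.
residualize <- function(Y, X, warn_rank = TRUE) {
  qx <- qr(X)
  if (warn_rank && qx$rank < ncol(X)) {
    warning("regressor matrix is rank deficient (rank ", qx$rank, " < ",
            ncol(X), " columns); residualizing on its column space",
            call. = FALSE)
  }
  qr.resid(qx, Y)
}
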