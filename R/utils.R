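#' @importFrom methods as is
#' @importFrom stats aggregate cor loess median pchisq pnorm pt predict
#'   prcomp quantile rbinom rexp rgamma rlnorm rmultinom rnbinom rnorm runif
#'   sd setNames var
#' @importFrom utils combn head read.delim write.table
NULL

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Dirichlet draw via normalized gamma variates.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x <- rep(1, length(alpha))
  x / sum(x)
}

# All permutations of 1..n as an n! x n integer matrix (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, k] <- n
    blk[, -k] <- sub
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

# Column-wise means and detection fractions of a sparse genes x cells matrix,
# restricted to a set of columns.
sparse_row_stats <- function(m, cols) {
  sub <- m[, cols, drop = FALSE]
  n <- ncol(sub)
  list(
    mean = Matrix::rowSums(sub) / n,
    mean_expm1 = Matrix::rowSums(expm1(sub)) / n,
    frac = Matrix::rowSums(sub > 0) / n,
    n = n
  )
}
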