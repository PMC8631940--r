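# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so seeded package functions never disturb user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # force initialization so we have something to restore
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed. Kept below
# .Machine$integer.max so it is always a valid set.seed() argument.
child_seed <- function(seed, offset) {
  (as.integer(seed) * 48271L + as.integer(offset)) %% 2147483587L
}

# Column-standardize a matrix; zero-variance columns map to all-zero
# columns rather than NaN. Returns the matrix with center/scale records.
std_cols <- function(M) {
  M <- as.matrix(M)
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr, "-")
  # sample sd per column
  sds <- sqrt(colSums(Mc^2) / max(1L, nrow(M) - 1L))
  ok <- sds > 0
  Ms <- Mc
  Ms[, ok] <- sweep(Mc[, ok, drop = FALSE], 2L, sds[ok], "/")
  Ms[, !ok] <- 0
  list(X = Ms, center = ctr, scale = ifelse(ok, sds, 1), constant = !ok)
}

# Per-column variance of a matrix (denominator n - 1).
col_vars <- function(M) {
  n <- nrow(M)
  if (n < 2L) return(rep(0, ncol(M)))
  Mc <- sweep(M, 2L, colMeans(M), "-")
  colSums(Mc^2) / (n - 1L)
}

stop_mgp <- function(..., class = "mgp_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
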