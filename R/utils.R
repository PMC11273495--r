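# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Canonical identifier form: trimmed, lowercased (HMDD-style files vary in
# casing; matching is case-insensitive by normalising both sides).
.normalizeId <- function(x) tolower(trimws(x))

.pairMatrix <- function(i, j) {
  m <- cbind(i = as.integer(i), j = as.integer(j))
  if (!nrow(m)) m <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  m
}

.emptyPairs <- function() .pairMatrix(integer(0), integer(0))

.assertSquare <- function(A, what = "matrix") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(what, " must be a square matrix")
  invisible(A)
}

.assertSymmetric <- function(A, tol = 1e-8, what = "matrix") {
  .assertSquare(A, what)
  if (nrow(A) && max(abs(A - t(A))) > tol)
    stop(what, " must be symmetric")
  invisible(A)
}
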