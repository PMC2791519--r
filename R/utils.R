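# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL uses (and advances) the
# current RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-voxel seed from a base seed and a voxel linear index,
# kept inside the 32-bit integer range.
voxelSeed <- function(seed, voxel) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(voxel)) %% 2147483647)
}

assertSimplex <- function(r, what = "r") {
  if (!is.numeric(r) || length(r) < 2L || any(!is.finite(r)) ||
      any(r < 0) || abs(sum(r) - 1) > 1e-8) {
    stop(sprintf(
      "'%s' must be a probability vector of length >= 2 (non-negative, summing to 1)",
      what
    ), call. = FALSE)
  }
  invisible(TRUE)
}

assertPositive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("all elements of '%s' must be finite and > 0", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Coerce a LogEvidenceMatrix or bare numeric matrix to the validated class.
asLogEvidence <- function(x) {
  if (is(x, "LogEvidenceMatrix")) return(x)
  if (is.matrix(x) && is.numeric(x)) return(LogEvidenceMatrix(x))
  stop("expected a LogEvidenceMatrix or a numeric matrix", call. = FALSE)
}
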