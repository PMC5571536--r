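#' @keywords internal
"_PACKAGE"

# Evaluate `expr` with the global RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.  Every stochastic function in the package routes its
# randomness through this helper so that no call leaks random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation from one master seed.  Offsets are
# small fixed integers per stage name so derived seeds stay far below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, gene_sets = 23L, deg = 37L, som = 53L,
               enrichment = 71L, pipeline = 89L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer(seed) + off
}

# Replace characters unsafe in file names (group labels contain "/" and "+").
sanitize_filename <- function(x) {
  gsub("^[.-]+|[.-]+$", "", gsub("[^A-Za-z0-9._-]+", "-", x))
}

abort_config <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
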