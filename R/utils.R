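# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_if_not_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", name, min), call. = FALSE)
  invisible(x)
}

# coerce a character vector / DNAStringSet to a named DNAStringSet
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  stop("reference must be a named character vector or a DNAStringSet", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
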