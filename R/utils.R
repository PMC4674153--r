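`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private RNG stream; the caller's stream is untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

SUBSET_LEVELS <- c("classical", "intermediate", "non_classical")

.check_subsets <- function(subset) {
  bad <- setdiff(unique(as.character(subset)), SUBSET_LEVELS)
  .assert(length(bad) == 0L,
          "unknown subset label(s): ", paste(bad, collapse = ", "),
          " (expected ", paste(SUBSET_LEVELS, collapse = "/"), ")")
  factor(as.character(subset), levels = SUBSET_LEVELS)
}
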