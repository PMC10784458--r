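`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can distinguish failure modes programmatically
gpcr_abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "gpcrstates_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

gpcr_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "gpcrstates_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# run `expr` with a private RNG stream; restores the caller's .Random.seed
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
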