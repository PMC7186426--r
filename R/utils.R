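#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All user-facing randomness funnels through this so
# that a single integer seed makes any run reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dfhm <- function(..., class = "dfhm_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
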