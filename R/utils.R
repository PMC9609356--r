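# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from one top-level seed so that stages draw from
# independent streams; kept within 32-bit integer range.
derive_seed <- function(seed, stage_index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 99991L * as.integer(stage_index)) %% 2147483647L
}

stop_memfluor <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "memfluor_error")))
}

warn_memfluor <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "memfluor_warning")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

fmt_sci <- function(x, digits = 3) formatC(x, format = "e", digits = digits)
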