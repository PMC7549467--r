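# Internal helpers: classed errors and seeded RNG scoping.

ai_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "actimage_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_invalid <- function(message) ai_stop(message, "actimage_invalid_argument")
stop_format <- function(message) ai_stop(message, "actimage_format_error")
stop_io <- function(message) ai_stop(message, "actimage_io_error")
stop_detection <- function(message) ai_stop(message, "actimage_detection_failure")
stop_split <- function(message) ai_stop(message, "actimage_split_error")
stop_build <- function(message) ai_stop(message, "actimage_build_error")

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
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
    set.seed(seed)
  }
  expr
}

# Derive `n` well-separated child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
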