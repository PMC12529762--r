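#' Derive a child seed from a master seed and a tag
#'
#' All randomness in pcmaudit flows from a single master seed. Components
#' derive their own seeds from the master seed plus a string tag so that any
#' component can be regenerated independently and deterministically.
#'
#' @param seed integer master seed.
#' @param ... character tags (coerced with `as.character` and concatenated).
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 17
  for (x in utf8ToInt(tag)) h <- (h * 31 + x) %% 2147483647
  as.integer(((seed %% 50021) * 69621 + h) %% 2147483647)
}

# internal: stop with a classed condition so callers can test error classes
pcm_stop <- function(msg, class) {
  stop(structure(class = c(class, "pcm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
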