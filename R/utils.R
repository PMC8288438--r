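#' Stable string hash for seed derivation
#'
#' Deterministic 31-bit hash of an arbitrary sequence of values, used to derive
#' per-cell seeds from a master seed so that screen results are reproducible
#' independently of execution order. Not cryptographic.
#'
#' @param ... values (coerced to character) that identify the stream, e.g.
#'   `stable_hash(seed, clade, class)`.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' stable_hash(42, "rosids", "alkaloids")
stable_hash <- function(...) {
  parts <- vapply(list(...), function(p) paste(format(p, digits = 15), collapse = ","),
                  character(1))
  s <- paste(parts, collapse = "\x1f")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h) + 1L
}

# round-half-up, used for retained-presence counts and prevalence -> k
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
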