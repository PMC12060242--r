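## Small shared helpers. Nothing here is exported.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable 31-bit string hash
#'
#' Deterministic seed derivation for experiment cells: a polynomial rolling
#' hash over the UTF-8 bytes of the pasted arguments, reduced mod 2^31 - 1.
#' Pure double arithmetic (products stay below 2^53), so identical on every
#' platform and R version.
#'
#' @param ... atomic values identifying the cell (pasted with "/").
#' @return integer in [1, 2^31 - 2], usable with [set.seed()].
#' @export
stable_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "/")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

## run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lower), format(upper))
  invisible(x)
}
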