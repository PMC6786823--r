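#' Derive a child seed from a root seed and a named stream
#'
#' All randomness in the package flows from a single root seed; each pipeline
#' stage draws from its own named stream so stages can be re-run independently
#' without perturbing one another.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. `"design"`, `"behavior"`).
#' @return An integer seed, guaranteed < 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 2654435761) %% 1e9
  as.integer((abs(seed) * 31 + h) %% .Machine$integer.max)
}

# run expr with a local RNG state seeded from `seed`; restores global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ld <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# probability in [0,1] check used by config validators
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_ld("`%s` must be a probability in [0, 1], got %s", name,
            paste(format(x), collapse = ", "))
  invisible(x)
}
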