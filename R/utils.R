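# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mix arbitrary identifiers into a 32-bit seed
#'
#' All randomness in the package flows from one root integer seed; substreams
#' for stages, participants and trials are derived by mixing identifiers into
#' the root with a small multiplicative hash. Changing the cohort size
#' therefore does not reshuffle the substreams of existing trials.
#'
#' @param ... integers and/or character scalars/vectors to mix.
#' @return a single integer in 0..(2^31 - 2), usable with [set.seed()].
#' @keywords internal
hash_mix <- function(...) {
  parts <- list(...)
  m <- 2147483647
  h <- 104729
  for (p in parts) {
    if (is.character(p)) p <- vapply(p, function(s) sum(utf8ToInt(s)), numeric(1))
    for (v in as.numeric(p)) {
      v <- abs(v) %% m
      h <- (h * 69069 + v * 40503 + 12345) %% m
    }
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stop with a consistent prefix identifying which contract was violated.
stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
stop_data <- function(...) stop("data error: ", ..., call. = FALSE)

# Fixed-precision numeric formatting used by all table writers (6 significant
# digits) so that pipeline outputs are byte-stable and diffable.
format_num <- function(x) {
  if (is.double(x)) signif(x, 6) else x
}
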