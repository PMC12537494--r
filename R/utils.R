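#' @useDynLib vegsyntax, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif rnorm rnbinom setNames
#' @importFrom utils head tail
NULL

# Deterministic 31-bit sub-seed from a base seed plus arbitrary string/integer
# context (epoch number, plot id, ...). FNV-1a over the concatenated text,
# folded into [0, 2^31 - 2] so it is always a valid set.seed() argument.
derive_seed <- function(seed, ...) {
  txt <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "\r")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == floor(x)
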