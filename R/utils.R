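#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
#' @useDynLib megrsa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# argument checks -------------------------------------------------------------

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "megrsa_invalid_argument")
}

check_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  lo <- if (allow_zero) min else min + .Machine$double.eps
  if (x < lo) stop_invalid("`%s` must be >= %s", name, format(min))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

# seeding ---------------------------------------------------------------------

#' Derive a child seed from a master seed and a stream key
#'
#' A single pipeline seed fans out to per-subject and per-stage streams by a
#' stable keyed hash, so results do not depend on the order in which stages or
#' subjects are processed. The derived seed is always in `[0, 2^31 - 2]`.
#'
#' @param seed Master integer seed.
#' @param ... Character or integer stream keys (e.g. `"subject"`, `3`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, "subject", 3)
derive_seed <- function(seed, ...) {
  check_count(seed, "seed", min = 0L)
  keys <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(keys)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# balanced splits -------------------------------------------------------------

# n items into k near-equal contiguous blocks; larger blocks first.
balanced_block_sizes <- function(n, k) {
  q <- n %/% k
  r <- n %% k
  c(rep(q + 1L, r), rep(q, k - r))
}
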