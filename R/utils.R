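#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All stochastic operations in the package take an
# explicit integer seed and funnel through here (no hidden global state).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Truncate a number toward zero at a given number of decimals
#'
#' Decoy-set reports print GF scores and percentages truncated (not rounded)
#' to two decimals; this helper makes that convention explicit and reusable.
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept (default 2).
#' @return numeric vector truncated toward zero.
#' @examples
#' trunc_dec(0.75929)   # 0.75
#' trunc_dec(-1.239, 2) # -1.23
#' @export
trunc_dec <- function(x, digits = 2) {
  f <- 10^digits
  trunc(x * f) / f
}

# Euclidean distance matrix of an n x 3 coordinate matrix.
coord_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

vnorm <- function(v) sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_pharm <- function(msg, class) {
  stop(structure(class = c(class, "pharmscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
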