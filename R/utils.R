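#' Derive a child seed from a root seed and a stream name
#'
#' All randomness in the package flows from a single root seed through named
#' child streams, so that each pipeline stage is reproducible in isolation.
#' The derivation is a small deterministic hash kept below 2^31 so the result
#' is always a valid R integer seed.
#'
#' @param root integer root seed.
#' @param name character stream name, e.g. `"sumstats"` or `"sumstats/GWAS_3"`.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(root %% m)
  for (cp in utf8ToInt(name)) {
    h <- (h * 69069 + cp) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a named child RNG stream
#'
#' Sets the RNG to a seed derived from `root` and `name`, evaluates `expr`,
#' and restores the previous RNG state afterwards.
#'
#' @param root integer root seed.
#' @param name character stream name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(root, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(root, name))
  expr
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p,
       lower = max(0, centre - half),
       upper = min(1, centre + half))
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# min-max scale a numeric vector to [0, 1]; constant vectors return NULL
# (caller drops the covariate with a warning)
minmax_scale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) return(NULL)
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic variant id dialect: chr_pos_ref_alt, 1-based positions
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
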