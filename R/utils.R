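# Internal helpers: seeding, truncated normal draws, small assertions.

#' The 39-arm vocabulary
#'
#' Chromosome arms used for FSD and arm-level CNV summaries: all autosomal
#' arms except the acrocentric p arms (13p, 14p, 15p, 21p, 22p), following
#' the DELFI convention.
#'
#' @return Character vector of 39 arm names in genomic order.
#' @export
#' @examples
#' armVocabulary()
armVocabulary <- function() {
  c("1p", "1q", "2p", "2q", "3p", "3q", "4p", "4q", "5p", "5q",
    "6p", "6q", "7p", "7q", "8p", "8q", "9p", "9q", "10p", "10q",
    "11p", "11q", "12p", "12q", "13q", "14q", "15q", "16p", "16q",
    "17p", "17q", "18p", "18q", "19p", "19q", "20p", "20q", "21q", "22q")
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and an index
#'
#' Splittable counter-based scheme: child seeds for per-sample / per-candidate
#' randomness are derived as `(master * 48271 + index * 16807) mod (2^31 - 1)`
#' (Lehmer multipliers over the Mersenne prime modulus), so a cohort replays
#' identically from its master seed regardless of generation order.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(7, 1:3)
deriveSeed <- function(master, index) {
  m <- 2147483647
  s <- (as.double(master) %% m * 48271 + as.double(index) * 16807) %% m
  as.integer(ifelse(s < 1, s + 1, s))
}

# Vectorized truncated-normal integer lengths on [lo, hi] via inverse CDF.
rtrunc_norm_int <- function(n, mean, sd, lo = 100L, hi = 220L) {
  if (n == 0L) return(integer(0))
  plo <- pnorm(lo - 0.5, mean, sd)
  phi <- pnorm(hi + 0.5, mean, sd)
  u <- runif(n)
  x <- qnorm(plo + u * (phi - plo), mean, sd)
  pmin.int(hi, pmax.int(lo, as.integer(round(x))))
}

pmin.int <- function(a, b) as.integer(pmin(a, b))
pmax.int <- function(a, b) as.integer(pmax(a, b))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Population z-score of a numeric vector; degenerate (SD 0) maps to all 0.
# NAs are excluded from mean/SD and preserved in the output.
pop_zscore <- function(x) {
  ok <- !is.na(x)
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  z <- x
  z[ok] <- if (s > 0) (x[ok] - m) / s else 0
  z
}
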