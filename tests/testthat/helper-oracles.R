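# Independent oracles (brute force / enumeration / Monte-Carlo), kept
# free of the implementation paths they check.

# AUC as the raw fraction of concordant positive-negative pairs.
bruteForceAUC <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Maximum-probability state path by exhaustive enumeration (<= 8 bins).
bruteForceViterbi <- function(l, mu, sigma, stay) {
  states <- c("loss", "neutral", "gain")
  means <- c(-mu, 0, mu)
  n <- length(l)
  stopifnot(n <= 8)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- apply(paths, 1, function(pp) {
    s <- log(1 / 3) + dnorm(l[1], means[pp[1]], sigma, log = TRUE)
    if (n > 1) for (t in 2:n) {
      s <- s + log(if (pp[t] == pp[t - 1]) stay else (1 - stay) / 2) +
        dnorm(l[t], means[pp[t]], sigma, log = TRUE)
    }
    s
  })
  states[paths[which.max(lp), ]]
}

# Largest threshold meeting the sensitivity target, by brute force over
# every observed score.
bruteForceCutoff <- function(scores, labels, target) {
  y <- as.integer(as.logical(labels))
  ok <- Filter(function(t) mean(scores[y == 1] >= t) >= target,
               sort(unique(scores)))
  max(unlist(ok))
}

# Monte-Carlo estimate of P(all five ratios exceed 1 + k), shared
# k ~ Gamma(shape, rate).
mcMarginProbability <- function(E, controls, shape = 0.5, rate = 1,
                                n_mc = 1e6, seed = 42) {
  k <- withr::with_seed(seed, rgamma(n_mc, shape = shape, rate = rate))
  vapply(E, function(e) mean(min(e / controls) > 1 + k), numeric(1))
}
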