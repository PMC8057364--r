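## Independent brute-force implementation of the CHE chain, used as the
## oracle for equivalence tests.  Percentiles by explicit sort-and-rank
## (nearest rank, inclusive bounds); every quantity computed with plain
## arithmetic, no calls into the package.

oracle_nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

oracle_poverty_line <- function(the, food, size, beta = 0.56,
                                window = c(45, 55)) {
  share <- food / the
  lo <- oracle_nearest_rank(share, window[1])
  hi <- oracle_nearest_rank(share, window[2])
  sel <- share >= lo & share <= hi
  per_eq <- food[sel] / size[sel]^beta
  sum(per_eq) / length(per_eq)
}

## Full chain: poverty line -> SE -> PC (with substitution) -> flags
oracle_chain <- function(the, food, size, oop, beta = 0.56,
                         window = c(45, 55),
                         thresholds = c(0.10, 0.20, 0.30, 0.40)) {
  pl <- oracle_poverty_line(the, food, size, beta, window)
  se <- pl * size^beta
  raw_pc <- the - se
  substituted <- raw_pc < 0
  pc <- ifelse(substituted, the - food, raw_pc)
  flags <- lapply(thresholds, function(z) {
    ifelse(pc > 0, as.integer(oop / pc >= z), as.integer(oop > 0))
  })
  names(flags) <- sprintf("flag_%g", round(thresholds * 100))
  list(pl = pl, se = se, pc = pc, substituted = substituted,
       flags = flags)
}

## Logistic DGP at the design-matrix level, for operating-characteristic
## studies of the selection and fitting machinery.
logistic_design <- function(n, beta, n_null = 0, intercept = -0.5) {
  k <- length(beta) + n_null
  X <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  eta <- intercept + drop(X[, seq_along(beta), drop = FALSE] %*% beta)
  dm <- data.frame(che = stats::rbinom(n, 1, stats::plogis(eta)), X)
  attr(dm, "threshold") <- 0.30
  class(dm) <- c("che_design", "data.frame")
  dm
}
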