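# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All user-facing simulators funnel through this so that identical
# (config, seed) pairs give byte-identical output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

# Deterministic apportionment of `n` items over fractions summing to 1:
# floor each share, then hand out the remainder by largest fractional part
# (ties resolved in the order the fractions are given).
apportion <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop2("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  }
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# counts / size factors, then log2(x + 1); the standard variance-stabilising
# transform used before correlation-based analyses in this package.
normalize_log2 <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  log2(sweep(counts, 2L, factors, "/") + 1)
}

check_group_sizes <- function(samples, groups, min_n = 2L) {
  for (g in groups) {
    n <- sum(samples$group == g)
    if (n < min_n) {
      stop2("group '", g, "' has ", n, " sample(s); at least ", min_n,
            " are required")
    }
  }
  invisible(TRUE)
}

random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}
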