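# Independent oracles and small fixtures shared across test files.

# Brute-force inheritance-bin evaluator, written from the verbal pattern
# definitions (independently of the package's lookup table):
#   overdominance: F significantly above both parents, or below both;
#   additivity:    parents differ and F is significantly between them;
#   dominance:     parents differ, F matches one parent and differs from the
#                  other in the direction of that parent's partner.
oracle_bin <- function(c1, c2, c3) {
  if (c2 == "up" && c3 == "up") {
    return(switch(c1, ns = "I", up = "II", down = "XII"))
  }
  if (c2 == "down" && c3 == "down") {
    return(switch(c1, ns = "VII", up = "VI", down = "VIII"))
  }
  if (c1 == "up") {
    if (c2 == "up" && c3 == "down") return("IV")
    if (c2 == "up" && c3 == "ns") return("III")
    if (c2 == "ns" && c3 == "down") return("V")
  }
  if (c1 == "down") {
    if (c2 == "down" && c3 == "up") return("X")
    if (c2 == "down" && c3 == "ns") return("IX")
    if (c2 == "ns" && c3 == "up") return("XI")
  }
  if (c1 == "ns" && c2 == "ns" && c3 == "ns") return("conserved")
  "ambiguous"
}

oracle_pattern <- function(bin) {
  if (bin %in% c("IV", "X")) "additive"
  else if (bin %in% c("III", "V", "IX", "XI")) "dominant"
  else if (bin %in% c("I", "II", "VI", "VII", "VIII", "XII")) "overdominant"
  else bin
}

# Brute-force O(m^2) BH step-up straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(p[rk >= rk[i]] * m / rk[rk >= rk[i]]))
  }
  q
}

all_calls <- c("up", "down", "ns")
call_grid <- expand.grid(c1 = all_calls, c2 = all_calls, c3 = all_calls,
                         stringsAsFactors = FALSE)

# Minimal contrast table for driving classify_all directly.
fake_contrast <- function(ids, call, contrast) {
  lfc <- ifelse(call == "up", 2, ifelse(call == "down", -2, 0))
  data.frame(feature_id = ids, contrast = contrast,
             log2fc = lfc, padj = ifelse(call == "ns", 1, 0.001),
             call = call, stringsAsFactors = FALSE)
}
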