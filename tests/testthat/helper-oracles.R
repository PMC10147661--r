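# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (string surgery, distance
# matrices, union-find, dense enumeration) rather than calling the package's
# own neighborhood or graph code.

# all 1-Hamming neighbors of a genotype by exhaustive single-token
# substitution on the encoded string
oracle_neighbors <- function(enc, parts = parts_library()) {
  halves <- strsplit(enc, "|", fixed = TRUE)[[1]]
  etok <- strsplit(halves[1], "-", fixed = TRUE)[[1]]
  ptok <- strsplit(halves[2], "-", fixed = TRUE)[[1]]
  n_edges <- sum(etok != "0")
  out <- character(0)
  for (i in 1:6) {
    for (v in 0:parts$s) {
      tv <- as.character(v)
      if (tv == etok[i]) next
      cand <- etok
      cand[i] <- tv
      ne <- sum(cand != "0")
      if (ne < 3 || ne > 6) next
      out <- c(out, paste0(paste(cand, collapse = "-"), "|", paste(ptok, collapse = "-")))
    }
  }
  ptoks <- names(parts$promoters)
  ptoks[ptoks == "ZERO"] <- "0"
  for (i in 1:2) {
    for (tv in ptoks) {
      if (tv == ptok[i]) next
      cand <- ptok
      cand[i] <- tv
      out <- c(out, paste0(halves[1], "|", paste(cand, collapse = "-")))
    }
  }
  unique(out)
}

# Hamming distance over the 8 token slots of two encoded genotypes
oracle_hamming <- function(a, b) {
  ta <- unlist(strsplit(gsub("\\|", "-", a), "-", fixed = FALSE))
  tb <- unlist(strsplit(gsub("\\|", "-", b), "-", fixed = FALSE))
  sum(ta != tb)
}

# connected components by union-find on the pairwise Hamming-distance
# matrix restricted to same-label genotypes
oracle_components <- function(genotypes, labels) {
  n <- length(genotypes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j] && oracle_hamming(genotypes[i], genotypes[j]) == 1) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(genotypes, paste(labels, roots))
}

# exact absorption-time distribution of a random walk whose per-step
# phenotype-change probability and edge-count transitions depend only on
# the current number of edges E. Returns P(absorbed at step k), k = 1..kmax,
# for the promoter-B labeling rule (2 of the neighbors change the label).
oracle_walk_distribution <- function(E0, kmax) {
  # per-E neighbor structure of the default space: (total, absorb, to E-1, to E+1)
  tab <- list(
    `3` = c(n = 39, abs = 2, down = 0, up = 18),
    `4` = c(n = 42, abs = 2, down = 4, up = 12),
    `5` = c(n = 42, abs = 2, down = 5, up = 6),
    `6` = c(n = 42, abs = 2, down = 6, up = 0)
  )
  p <- c(`3` = 0, `4` = 0, `5` = 0, `6` = 0)
  p[as.character(E0)] <- 1
  out <- numeric(kmax)
  for (k in seq_len(kmax)) {
    absorbed <- 0
    q <- c(`3` = 0, `4` = 0, `5` = 0, `6` = 0)
    for (E in 3:6) {
      key <- as.character(E)
      t <- tab[[key]]
      mass <- p[key]
      if (mass == 0) next
      absorbed <- absorbed + mass * t["abs"] / t["n"]
      stay <- (t["n"] - t["abs"] - t["down"] - t["up"]) / t["n"]
      q[key] <- q[key] + mass * stay
      if (t["down"] > 0) q[as.character(E - 1)] <- q[as.character(E - 1)] + mass * t["down"] / t["n"]
      if (t["up"] > 0) q[as.character(E + 1)] <- q[as.character(E + 1)] + mass * t["up"] / t["n"]
    }
    out[k] <- absorbed
    p <- q
  }
  out
}

# median of a discrete distribution given P(X = k), censoring mass at kmax
oracle_distribution_median <- function(pk) {
  pk[length(pk)] <- pk[length(pk)] + (1 - sum(pk))
  cum <- cumsum(pk)
  which(cum >= 0.5)[1]
}

# a small parameter set whose E-keyed tables are flat, for model-reduction
# tests where circuits with different edge counts must be comparable
flat_key_parameters <- function() {
  th <- default_parameters()
  th$d_rna[] <- 0.2
  th$dcas_total[] <- 200
  th
}

# dose-response tibble from per-node readout vectors (9 doses)
make_dr <- function(A, B, C, doses = default_doses()) {
  tibble::tibble(
    genotype = "toy",
    ara = rep(doses, 3),
    node = rep(c("A", "B", "C"), each = length(doses)),
    reporter = rep(c("mKO2", "mKate2", "sfGFP"), each = length(doses)),
    value = c(A, B, C)
  )
}
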