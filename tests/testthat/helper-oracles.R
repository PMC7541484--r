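# Independent oracles used to validate the package's own implementations.

# Isotope pattern by per-atom sequential convolution (no exponentiation
# tricks): multiply the abundance polynomial in one atom at a time.
iso_pattern_oracle <- function(comp, n_peaks) {
  abund <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
  poly_mul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) for (j in seq_along(b))
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    out
  }
  p <- 1
  for (el in names(comp)) {
    for (k in seq_len(comp[[el]])) p <- poly_mul(p, abund[[el]])
  }
  length(p) <- max(length(p), n_peaks)
  p[is.na(p)] <- 0
  head(p, n_peaks) / sum(head(p, n_peaks))
}

# Fitch length by brute-force minimization over all internal-state
# assignments, restricted to the states observed at each site (an optimal
# assignment never needs an unobserved state). Matrices must be free of
# missing symbols.
fitch_oracle <- function(tree, matrix) {
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):max(tree$edge)
  mat <- matrix[tree$tip.label, , drop = FALSE]
  total <- 0L
  for (site in seq_len(ncol(mat))) {
    leaf_states <- mat[, site]
    states <- unique(leaf_states)
    grid <- as.matrix(expand.grid(rep(list(states), length(internals)),
                                  stringsAsFactors = FALSE))
    changes <- numeric(nrow(grid))
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      sa <- if (a <= n_tip) rep(leaf_states[a], nrow(grid))
            else grid[, match(a, internals)]
      sb <- if (b <= n_tip) rep(leaf_states[b], nrow(grid))
            else grid[, match(b, internals)]
      changes <- changes + (sa != sb)
    }
    total <- total + min(changes)
  }
  total
}

# Random character matrix over a reduced alphabet (no missing symbols).
random_aa_matrix <- function(n_taxa, n_sites, n_states = 4L, seed = 1L) {
  set.seed(seed)
  states <- c("G", "A", "R", "D", "K", "F")[seq_len(n_states)]
  mat <- matrix(sample(states, n_taxa * n_sites, replace = TRUE),
                n_taxa, n_sites)
  rownames(mat) <- paste0("t", seq_len(n_taxa))
  mat
}

# Canonical split-set signature of an unrooted topology, for set comparison.
topo_signature <- function(tree) {
  paste(sort(tree_splits(tree)), collapse = ";")
}

# The standard ZooMS marker peptide at nominal m/z 1105.
marker_p1105 <- function() {
  peptide("GVQGPPGPAGPR",
          modifications = data.frame(type = "hydroxylation_PK", position = 6L))
}
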