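# Maximum-parsimony phylogenetics on amino-acid character matrices.
#
# States are encoded as 20-bit masks; X, '-' and '?' are fully missing (the
# complete state set). Fitch small-parsimony counts are computed by set
# intersection/union sweeps vectorized over site patterns (identical columns
# are collapsed with weights). The tree search is exact: full enumeration of
# unrooted binary topologies by stepwise leaf addition, optionally pruned by
# the partial-tree Fitch length, which is a valid lower bound because adding
# leaves never decreases the parsimony score.

.AA_STATES <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
                "K", "E", "M", "H", "F", "R", "Y", "W")
.MISSING_MASK <- bitwShiftL(1L, 20L) - 1L  # 2^20 - 1

# Encode a character matrix into per-pattern bitmask columns with weights.
.encode_alignment <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  codes <- matrix(0L, nrow(mat), ncol(mat))
  for (i in seq_along(.AA_STATES))
    codes[mat == .AA_STATES[i]] <- bitwShiftL(1L, i - 1L)
  codes[mat %in% c("X", "-", "?")] <- .MISSING_MASK
  if (any(codes == 0L))
    stop("unknown state symbol(s): ",
         paste(unique(mat[codes == 0L]), collapse = ", "))
  keys <- apply(codes, 2, paste, collapse = ",")
  uniq <- !duplicated(keys)
  idx <- match(keys, keys[uniq])
  list(codes = codes[, uniq, drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(uniq))),
       pattern_index = idx, n_sites = ncol(mat), taxa = rownames(mat))
}

# Fitch length of a tree given as an edge matrix. Tips are node ids
# 1..n_tip; the sweep is rooted at tip `root_tip` (score is rooting
# invariant). Sequential pairwise combination handles the degree-3 node of
# an unrooted binary tree exactly.
.fitch_edges <- function(edge, codes, weights, n_tip, root_tip = 1L) {
  nnodes <- max(edge)
  adj <- vector("list", nnodes)
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(nnodes)
  order <- integer(0)
  stack <- root_tip
  parent[root_tip] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) if (u != parent[v]) { parent[u] <- v; stack <- c(stack, u) }
  }
  sets <- vector("list", nnodes)
  npat <- ncol(codes)
  changes <- numeric(npat)
  for (v in rev(order)) {
    if (v == root_tip) {
      child <- adj[[v]][adj[[v]] != parent[v]][1]
      inter <- bitwAnd(codes[v, ], sets[[child]])
      changes <- changes + (inter == 0L)
    } else if (v <= n_tip) {
      sets[[v]] <- codes[v, ]
    } else {
      ch <- adj[[v]][adj[[v]] != parent[v]]
      s <- sets[[ch[1]]]
      for (cc in ch[-1]) {
        inter <- bitwAnd(s, sets[[cc]])
        emp <- inter == 0L
        changes <- changes + emp
        if (any(emp)) {
          un <- bitwOr(s, sets[[cc]])
          inter[emp] <- un[emp]
        }
        s <- inter
      }
      sets[[v]] <- s
    }
  }
  sum(changes * weights)
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of character-state changes over the tree, summed over
#' sites; `X`, `-` and `?` contribute the full state set. Invariant to leaf
#' order and rooting.
#'
#' @param tree An `ape::phylo` (unrooted or rooted binary) whose tip labels
#'   equal the matrix taxa.
#' @param matrix Character matrix, taxa x sites.
#' @return Number of changes (>= 0).
#' @export
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, rownames(matrix)))
    stop("tree leaves and matrix taxa differ")
  deg <- tabulate(c(tree$edge), max(tree$edge))
  if (any(deg[-seq_len(length(tree$tip.label))] > 3L))
    stop("polytomies are not supported")
  enc <- .encode_alignment(matrix[tree$tip.label, , drop = FALSE])
  .fitch_edges(tree$edge, enc$codes, enc$weights,
               n_tip = length(tree$tip.label))
}

# Newick string for an edge-matrix tree, rooted for display at the internal
# node adjacent to tip 1 (standard unrooted trifurcation).
.newick_from_edges <- function(edge, labels) {
  n_tip <- length(labels)
  nnodes <- max(edge)
  adj <- vector("list", nnodes)
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  sub <- function(v, par) {
    if (v <= n_tip) return(labels[v])
    ch <- adj[[v]][adj[[v]] != par]
    paste0("(", paste(vapply(ch, sub, "", par = v), collapse = ","), ")")
  }
  r <- adj[[1]][1]
  ch <- adj[[r]]
  paste0("(", paste(vapply(ch, sub, "", par = r), collapse = ","), ");")
}

# Insert leaf `leaf` on edge row `e`, creating internal node `newnode`.
.insert_leaf <- function(edge, e, leaf, newnode) {
  u <- edge[e, 1]; v <- edge[e, 2]
  edge[e, ] <- c(u, newnode)
  rbind(edge, c(newnode, v), c(newnode, leaf))
}

#' Exact search for maximum-parsimony trees
#'
#' Enumerates unrooted binary topologies by stepwise leaf addition and
#' returns every topology attaining the minimum Fitch length. Branch-and-
#' bound prunes subtrees whose partial-tree length already exceeds the best
#' complete tree (adding taxa never decreases parsimony length), and returns
#' the identical set as full enumeration.
#'
#' @param matrix Character matrix, taxa x sites, 4 to 12 taxa.
#' @param mode `"branch_and_bound"` (default) or `"exhaustive"`.
#' @return List with `trees` (an `ape::multiPhylo` of the minimal
#'   topologies), `score` (minimum Fitch length) and `n_evaluated`
#'   (complete topologies scored).
#' @export
search_mp_trees <- function(matrix, mode = c("branch_and_bound", "exhaustive")) {
  mode <- match.arg(mode)
  n <- nrow(matrix)
  if (n < 4L || n > 12L) stop("supported taxon range is 4 to 12")
  enc <- .encode_alignment(matrix)
  codes <- enc$codes; w <- enc$weights
  bb <- mode == "branch_and_bound"
  state <- new.env(parent = emptyenv())
  state$best <- Inf
  state$trees <- list()
  state$n_eval <- 0L
  start <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  rec <- function(edge, k) {
    if (k > n) {
      sc <- .fitch_edges(edge, codes, w, n)
      state$n_eval <- state$n_eval + 1L
      if (sc < state$best) {
        state$best <- sc
        state$trees <- list(edge)
      } else if (sc == state$best) {
        state$trees[[length(state$trees) + 1L]] <- edge
      }
      return(invisible())
    }
    newnode <- n + k - 2L
    for (e in seq_len(nrow(edge))) {
      cand <- .insert_leaf(edge, e, k, newnode)
      if (bb && .fitch_edges(cand, codes, w, n) > state$best) next
      rec(cand, k + 1L)
    }
  }
  rec(start, 4L)
  labels <- rownames(matrix)
  trees <- lapply(state$trees, function(ed)
    ape::read.tree(text = .newick_from_edges(ed, labels)))
  class(trees) <- "multiPhylo"
  list(trees = trees, score = state$best, n_evaluated = state$n_eval)
}

#' Non-trivial splits of an unrooted tree
#'
#' Each internal edge's bipartition, oriented to the side not containing the
#' reference taxon and keyed as the sorted taxon labels joined by `|`.
#'
#' @param tree An `ape::phylo`.
#' @param ref_taxon Orientation taxon (default: alphabetically first label).
#' @return Character vector of split keys.
#' @export
tree_splits <- function(tree, ref_taxon = NULL) {
  taxa <- sort(tree$tip.label)
  if (is.null(ref_taxon)) ref_taxon <- taxa[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (ref_taxon %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2L || length(side) > length(taxa) - 2L)
      return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

# Build a (possibly multifurcating) tree from a laminar family of splits,
# with per-split support labels. Splits are taxon-label sets not containing
# `taxa[1]`.
.tree_from_splits <- function(taxa, splits, supports) {
  if (length(splits)) {
    members <- lapply(splits, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
    ord <- order(-lengths(members))
    members <- members[ord]; supports <- supports[ord]
  } else members <- list()
  nsp <- length(members)
  parent <- integer(nsp)  # 0 = root
  for (i in seq_len(nsp)) {
    parent[i] <- 0L
    if (i > 1L) for (j in (i - 1L):1L) {
      if (all(members[[i]] %in% members[[j]])) { parent[i] <- j; break }
    }
  }
  # deepest (smallest) split containing each leaf; members sorted by size
  # descending so later assignments win
  leaf_parent <- setNames(rep(0L, length(taxa)), taxa)
  for (i in seq_len(nsp)) leaf_parent[members[[i]]] <- i
  write_node <- function(id) {
    kids_sp <- which(parent == id)
    kids_lf <- names(leaf_parent)[leaf_parent == id]
    parts <- c(vapply(kids_sp, function(s)
      paste0(write_node(s), sprintf("%g", supports[s])), ""),
      kids_lf)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(write_node(0L), ";")
  ape::read.tree(text = txt)
}

#' Majority-rule consensus tree
#'
#' Contains exactly the splits occurring in more than `threshold` of the
#' input trees (default 50 percent); may be multifurcating. Split
#' frequencies (percent) are attached as internal node labels.
#'
#' @param trees List / `multiPhylo` of trees on identical leaf sets.
#' @param threshold Fraction in \[0.5, 1\) (default 0.5).
#' @return An `ape::phylo` with `node.label` supports.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees) if (!setequal(tr$tip.label, taxa))
    stop("leaf-set mismatch between input trees")
  counts <- table(unlist(lapply(trees, tree_splits, ref_taxon = taxa[1])))
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > threshold
  .tree_from_splits(taxa, names(counts)[keep], round(100 * freq[keep], 1))
}

#' Bootstrap support by site resampling
#'
#' Resamples alignment columns with replacement, finds all maximum-parsimony
#' trees per replicate (tied trees contribute fractionally to their splits),
#' and returns the majority-rule consensus with split supports in percent of
#' replicates.
#'
#' @param matrix Character matrix, taxa x sites.
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @param mode Search mode, see [search_mp_trees()].
#' @param threshold Consensus threshold (default 0.5).
#' @return An `ape::phylo` with `node.label` supports (percent); the full
#'   split-frequency table is attached as attribute `split_freq`.
#' @export
bootstrap_support <- function(matrix, n_replicates = 1000L, seed = 1L,
                              mode = "branch_and_bound", threshold = 0.5) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  taxa <- sort(rownames(matrix))
  counts <- new.env(parent = emptyenv())
  .with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(ncol(matrix), replace = TRUE)
      res <- search_mp_trees(matrix[, idx, drop = FALSE], mode = mode)
      k <- length(res$trees)
      for (tr in res$trees) {
        for (key in tree_splits(tr, ref_taxon = taxa[1])) {
          counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) +
            1 / k
        }
      }
    }
  })
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 0) / n_replicates
  keep <- freq > threshold
  cons <- .tree_from_splits(taxa, keys[keep], round(100 * freq[keep], 1))
  attr(cons, "split_freq") <- data.frame(split = keys,
                                         support = round(100 * freq, 1),
                                         row.names = NULL)
  cons
}

#' Write a character matrix and partitions as NEXUS
#'
#' Minimal protein NEXUS export (data block plus a sets block with one
#' charset per partition) consumable by external Bayesian phylogenetics
#' tools.
#'
#' @param alignment A `concat_alignment` or character matrix.
#' @param path Output path.
#' @export
write_nexus <- function(alignment, path) {
  if (inherits(alignment, "concat_alignment")) {
    seqs <- alignment$sequences
    parts <- alignment$partitions
  } else {
    mat <- alignment
    seqs <- apply(mat, 1, paste, collapse = "")
    parts <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  nchar1 <- nchar(seqs[1])
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs), nchar1),
               "  FORMAT DATATYPE=PROTEIN MISSING=X GAP=-;",
               "  MATRIX"), con)
  for (nm in names(seqs))
    writeLines(sprintf("    %-12s %s", nm, seqs[[nm]]), con)
  writeLines(c("  ;", "END;"), con)
  if (!is.null(parts)) {
    writeLines(c("", "BEGIN SETS;"), con)
    for (i in seq_len(nrow(parts)))
      writeLines(sprintf("  CHARSET %s = %d-%d;", parts$protein[i],
                         parts$start[i], parts$end[i]), con)
    writeLines("END;", con)
  }
  invisible(path)
}
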