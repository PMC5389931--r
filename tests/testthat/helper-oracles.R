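# Independent brute-force oracles used across test files. These deliberately
# recompute quantities by direct O(n^2) enumeration, never through the
# package's linear-time recurrences.

# per-node cross-pair statistics by enumerating every leaf pair at its MRCA
brute_node_stats <- function(tree) {
  n <- length(tree$tip.label)
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  M <- ape::mrca(tree)
  nodes <- sort(unique(as.vector(M[upper.tri(M)])))
  res <- data.frame(node = nodes, cross_pair_count = NA_real_,
                    cross_pair_mean = NA_real_)
  for (k in seq_along(nodes)) {
    sel <- M == nodes[k] & upper.tri(M)
    res$cross_pair_count[k] <- sum(sel)
    res$cross_pair_mean[k] <- mean(D[sel])
  }
  res
}

# the whole-tree percentile by expanding the weighted multiset into a flat
# vector (one entry per leaf pair) and taking the standard type-7 quantile
brute_threshold <- function(tree, p) {
  st <- brute_node_stats(tree)
  flat <- rep(st$cross_pair_mean, st$cross_pair_count)
  unname(stats::quantile(flat, p, type = 7))
}

# tree diameter from the all-pairs patristic distance matrix
brute_diameter <- function(tree) {
  max(ape::cophenetic.phylo(tree))
}

# maximal root-to-leaf distance of a rooted tree
max_root_depth <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    depth[pre$edge[i, 2]] <- depth[pre$edge[i, 1]] + pre$edge.length[i]
  }
  max(depth[seq_len(n)])
}

# naive position-by-position motif matcher over expanded character classes
naive_motif_scan <- function(seq, motif = "GX5EX7REUXEEXGU",
                             u_set = c("L", "I", "V")) {
  toks <- regmatches(motif, gregexpr("X[0-9]+|X|U|[A-Z]", motif))[[1L]]
  classes <- list()
  for (t in toks) {
    if (t == "X") {
      classes[length(classes) + 1L] <- list(NULL)  # NULL = any residue
    } else if (grepl("^X[0-9]+$", t)) {
      for (i in seq_len(as.integer(substring(t, 2L)))) {
        classes[length(classes) + 1L] <- list(NULL)
      }
    } else if (t == "U") {
      classes[[length(classes) + 1L]] <- u_set
    } else {
      classes[[length(classes) + 1L]] <- t
    }
  }
  w <- length(classes)
  chars <- strsplit(seq, "")[[1L]]
  starts <- integer(0)
  if (length(chars) >= w) {
    for (s in seq_len(length(chars) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        cls <- classes[[j]]
        if (!is.null(cls) && !(chars[s + j - 1L] %in% cls)) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, s)
    }
  }
  starts
}

# small random tree with exponential branch lengths, deterministic per call
# site through the caller's RNG state
random_test_tree <- function(n, scale = 1) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / scale)
  tr
}
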