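#' Per-node patristic distance statistics
#'
#' For every node of a rooted tree, computes in one post-order pass:
#' `n_leaves`, the number of descendant leaves; `leaf_path_sum`, the sum of
#' patristic distances from the node to each descendant leaf;
#' `cross_pair_count`, the number of leaf pairs whose lowest common ancestor
#' is the node (`sum over child pairs of n_i * n_j`); and `cross_pair_mean`,
#' the exact mean patristic distance over those pairs. Every leaf pair of
#' the tree is separated at exactly one node, so the weighted multiset of
#' `(cross_pair_mean, cross_pair_count)` over internal nodes summarises the
#' whole-tree pairwise distance distribution in linear time.
#'
#' Polytomies and zero-length branches are supported (zero-length branches
#' contribute 0 to path sums).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return A data frame with one row per node (in ape node numbering:
#'   tips `1..n`, then internal nodes), columns `node`, `is_leaf`,
#'   `n_leaves`, `leaf_path_sum`, `cross_pair_count`, `cross_pair_mean`
#'   (`NA` for leaves).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2);")
#' compute_node_stats(tr)  # root: mean 3, one pair
compute_node_stats <- function(tree) {
  check_phylo(tree)
  n_tip <- length(tree$tip.label)
  n_tot <- n_tip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length

  n_leaves <- integer(n_tot)
  n_leaves[seq_len(n_tip)] <- 1L
  path_sum <- numeric(n_tot)
  cross_count <- numeric(n_tot)
  cross_mean <- rep(NA_real_, n_tot)

  kids <- split(seq_len(nrow(edge)), edge[, 1])
  post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (v in post) {
    ke <- kids[[as.character(v)]]
    ch <- edge[ke, 2]
    # distance mass from v into each child subtree
    a <- path_sum[ch] + n_leaves[ch] * elen[ke]
    nc <- n_leaves[ch]
    n_leaves[v] <- sum(nc)
    path_sum[v] <- sum(a)
    cross_count[v] <- (sum(nc)^2 - sum(nc^2)) / 2
    if (cross_count[v] > 0) {
      cross_sum <- sum(a * (n_leaves[v] - nc))
      cross_mean[v] <- cross_sum / cross_count[v]
    }
  }
  data.frame(node = seq_len(n_tot),
             is_leaf = seq_len(n_tot) <= n_tip,
             n_leaves = n_leaves,
             leaf_path_sum = path_sum,
             cross_pair_count = cross_count,
             cross_pair_mean = cross_mean)
}

check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an ape 'phylo' tree")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  invisible(tree)
}

#' Whole-tree percentile distance threshold
#'
#' Builds the weighted multiset `{(cross_pair_mean(v), cross_pair_count(v))}`
#' over internal nodes — each of the `n(n-1)/2` leaf pairs contributing once,
#' at the mean of the node where the pair splits — and returns its weighted
#' p-th percentile, with linear interpolation between adjacent weighted
#' order statistics (equivalent to `stats::quantile(type = 7)` on the
#' expanded multiset).
#'
#' @param stats Output of [compute_node_stats()] (or a `phylo` tree, which
#'   is converted).
#' @param percentile Probability in (0, 1\]; the partitioner default is
#'   0.05.
#' @return The distance threshold (numeric scalar).
#' @export
whole_tree_threshold <- function(stats, percentile = 0.05) {
  if (inherits(stats, "phylo")) stats <- compute_node_stats(stats)
  if (percentile <= 0 || percentile > 1) stop("percentile must be in (0, 1]")
  keep <- stats$cross_pair_count > 0
  if (!any(keep)) stop("tree must have at least 2 leaves")
  m <- stats$cross_pair_mean[keep]
  w <- stats$cross_pair_count[keep]
  ord <- order(m)
  m <- m[ord]
  w <- w[ord]
  weighted_quantile_type7(m, w, percentile)
}

# type-7 quantile on the multiset where value m[i] is repeated w[i] times
weighted_quantile_type7 <- function(m, w, p) {
  n_pairs <- sum(w)
  h <- (n_pairs - 1) * p + 1
  cw <- cumsum(w)
  at <- function(k) m[which(cw >= k)[1L]]
  lo <- floor(h)
  frac <- h - lo
  v1 <- at(lo)
  if (frac == 0) return(v1)
  v1 + frac * (at(lo + 1) - v1)
}

#' Maximal tight clades below a distance threshold
#'
#' Pre-order descent from the root: an internal node qualifies when its
#' mean cross-pair patristic distance is strictly below the threshold; the
#' descent does not enter a qualifying clade, so the returned nodes are the
#' root-most (maximal) qualifying clades. Leaves not under any qualifying
#' node remain unclustered.
#'
#' @param tree A rooted `phylo` tree.
#' @param threshold Distance threshold (see [whole_tree_threshold()]).
#' @param stats Optional precomputed [compute_node_stats()] output.
#' @return Integer vector of qualifying node numbers (possibly empty), in
#'   pre-order.
#' @export
initial_clusters <- function(tree, threshold, stats = NULL) {
  check_phylo(tree)
  if (is.null(stats)) stats <- compute_node_stats(tree)
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- n_tip + 1L
  out <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v > n_tip && !is.na(stats$cross_pair_mean[v]) &&
        stats$cross_pair_mean[v] < threshold) {
      out <- c(out, v)
    } else if (v > n_tip) {
      stack <- c(kids[[as.character(v)]], stack)  # preserve pre-order
    }
  }
  out
}

#' Partition configuration
#'
#' @param percentile Whole-tree distribution percentile in (0, 1); default
#'   0.05.
#' @param min_size,max_size Inclusive clade size bounds; defaults 400 and
#'   4000 (the production setting for trees of tens of thousands of leaves;
#'   scale down proportionally for smaller trees).
#' @return A `partition_config` list.
#' @export
partition_config <- function(percentile = 0.05, min_size = 400L,
                             max_size = 4000L) {
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0, 1)")
  if (max_size < 1L) stop("max_size must be >= 1")
  if (min_size > max_size) stop("min_size must be <= max_size")
  structure(list(percentile = percentile, min_size = as.integer(min_size),
                 max_size = as.integer(max_size)),
            class = "partition_config")
}

clade_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  sort(ape::extract.clade(tree, node)$tip.label, method = "radix")
}

#' Enforce clade-size bounds on a set of clades
#'
#' Oversized clades (more leaves than `max_size`) are split at their root
#' into their child subtrees, recursively, until every piece fits (a
#' polytomous root splits into all of its children). Undersized clades
#' (fewer leaves than `min_size`) are merged with their adjacent clade —
#' the nearest other clade by patristic distance between clade roots,
#' preferring siblings, ties broken by smaller clade then lexicographically
#' smallest leaf label — but only when the merged clade would not exceed
#' `max_size`; a small clade with no permissible merge has its leaves moved
#' to the unclustered leftover pool. Small clades are processed smallest
#' first (ties by smallest leaf label).
#'
#' @param tree A rooted `phylo` tree.
#' @param clusters Integer vector of clade root nodes (e.g. from
#'   [initial_clusters()]).
#' @param config A [partition_config()].
#' @return A `partition` object: list with `clades` (list of sorted
#'   leaf-label vectors, each within the size bounds) and `leftover`
#'   (sorted leaf labels not covered by any clade).
#' @export
enforce_size_bounds <- function(tree, clusters, config = partition_config()) {
  check_phylo(tree)
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nl <- compute_node_stats(tree)$n_leaves

  # 1. split oversized clades at their root, recursively
  queue <- as.integer(clusters)
  roots <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    if (nl[v] > config$max_size) {
      queue <- c(queue, kids[[as.character(v)]])
    } else {
      roots <- c(roots, v)
    }
  }

  clades <- lapply(roots, function(v) clade_leaves(tree, v))
  croot <- roots
  leftover <- character(0)

  # 2. merge undersized clades with their adjacent clade
  if (length(croot) > 0L) {
    dn <- ape::dist.nodes(tree)
    repeat {
      sizes <- lengths(clades)
      small <- which(sizes < config$min_size)
      if (length(small) == 0L) break
      first_leaf <- vapply(clades, `[`, character(1), 1L)
      small <- small[order(sizes[small], first_leaf[small], method = "radix")]
      i <- small[[1L]]
      cand <- setdiff(seq_along(clades), i)
      cand <- cand[sizes[cand] + sizes[i] <= config$max_size]
      if (length(cand) == 0L) {
        leftover <- c(leftover, clades[[i]])
        clades <- clades[-i]
        croot <- croot[-i]
        next
      }
      d <- dn[croot[i], croot[cand]]
      sib <- parent[croot[cand]] == parent[croot[i]]
      pick <- cand[order(d, !sib, sizes[cand], first_leaf[cand],
                         method = "radix")[1L]]
      merged <- sort(c(clades[[i]], clades[[pick]]), method = "radix")
      mroot <- ape::getMRCA(tree, c(clades[[i]][1L], clades[[pick]][1L]))
      keep <- setdiff(seq_along(clades), c(i, pick))
      clades <- c(clades[keep], list(merged))
      croot <- c(croot[keep], mroot)
    }
  }

  # clades emitted in pre-order of their roots
  if (length(clades) > 0L) {
    pre <- preorder_rank(tree)
    ord <- order(pre[croot], method = "radix")
    clades <- clades[ord]
    croot <- croot[ord]
  }
  structure(list(clades = clades,
                 clade_roots = croot,
                 leftover = sort(leftover, method = "radix")),
            class = "partition")
}

preorder_rank <- function(tree) {
  n_tot <- length(tree$tip.label) + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rank <- integer(n_tot)
  stack <- length(tree$tip.label) + 1L
  k <- 0L
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    k <- k + 1L
    rank[v] <- k
    kv <- kids[[as.character(v)]]
    if (!is.null(kv)) stack <- c(kv, stack)
  }
  rank
}

#' Partition a tree into size-bounded tight clades
#'
#' The full partitioner used to divide a very large family into subgroups
#' for divide-and-conquer alignment: computes exact per-clade mean patristic
#' distances ([compute_node_stats()]), derives the whole-tree percentile
#' threshold ([whole_tree_threshold()]), takes the maximal clades whose mean
#' is below it ([initial_clusters()]), and enforces the size bounds
#' ([enforce_size_bounds()]). Leaves never clustered — under no qualifying
#' clade, or in small clades that could not be merged — are pooled into one
#' leftover group, to be treated as a single subgroup downstream.
#'
#' If the tree has fewer than `min_size` leaves, everything goes to the
#' pooled leftover group.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param config A [partition_config()].
#' @return A `partition` object (see [enforce_size_bounds()]).
#' @export
#' @examples
#' tr <- ape::rtree(60)
#' p <- partition_tree(tr, partition_config(0.5, min_size = 4, max_size = 40))
#' lengths(p$clades)
partition_tree <- function(tree, config = partition_config()) {
  check_phylo(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < config$min_size) {
    return(structure(list(clades = list(), clade_roots = integer(0),
                          leftover = sort(tree$tip.label, method = "radix")),
                     class = "partition"))
  }
  stats <- compute_node_stats(tree)
  thr <- whole_tree_threshold(stats, config$percentile)
  cl <- initial_clusters(tree, thr, stats)
  part <- enforce_size_bounds(tree, cl, config)
  covered <- c(unlist(part$clades), part$leftover)
  part$leftover <- sort(c(part$leftover, setdiff(tree$tip.label, covered)),
                        method = "radix")
  part
}

#' @export
print.partition <- function(x, ...) {
  cat("Tree partition: ", length(x$clades), " clade(s), ",
      length(x$leftover), " leftover leaf/leaves\n", sep = "")
  if (length(x$clades) > 0L) {
    cat("  clade sizes: ", paste(lengths(x$clades), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write a partition to TSV files
#'
#' Writes `<prefix>_members.tsv` mapping each leaf label to a group id
#' (`G001`, `G002`, ... in clade order; `UNCLUSTERED_POOL` for the leftover
#' group) and `<prefix>_summary.tsv` with per-group size and, where the
#' group is a single clade of the tree, its mean within-clade patristic
#' distance.
#'
#' @param partition A `partition` object.
#' @param tree The tree it was computed from.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_partition_tsv <- function(partition, tree, prefix) {
  ids <- sprintf("G%03d", seq_along(partition$clades))
  members <- data.frame(
    leaf_label = c(unlist(partition$clades), partition$leftover),
    group_id = c(rep(ids, lengths(partition$clades)),
                 rep("UNCLUSTERED_POOL", length(partition$leftover))),
    stringsAsFactors = FALSE)
  mean_within <- vapply(partition$clades, function(lv) {
    if (length(lv) < 2L) return(NA_real_)
    sub <- ape::keep.tip(tree, lv)
    d <- ape::cophenetic.phylo(sub)
    mean(d[upper.tri(d)])
  }, numeric(1))
  summary <- data.frame(
    group_id = c(ids, if (length(partition$leftover) > 0) "UNCLUSTERED_POOL"),
    n_leaves = c(lengths(partition$clades),
                 if (length(partition$leftover) > 0) length(partition$leftover)),
    mean_within_distance = c(round(mean_within, 6),
                             if (length(partition$leftover) > 0) NA_real_),
    stringsAsFactors = FALSE)
  p1 <- paste0(prefix, "_members.tsv")
  p2 <- paste0(prefix, "_summary.tsv")
  utils::write.table(members, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(members = p1, summary = p2))
}
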