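#' Midpoint root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (the tree diameter), so that the two deepest root-to-leaf distances are
#' equal. When several leaf pairs tie for the diameter, the path whose
#' lexicographically smallest leaf label is smallest (then the smaller
#' second label) is chosen, making the result deterministic. A tree whose
#' branch lengths are all zero has no defined midpoint and raises an error.
#' An already-midpoint-rooted tree is returned unchanged.
#'
#' @param tree A `phylo` tree with branch lengths (rooted or unrooted;
#'   unrooted trees are handled through their internal representation).
#' @return A rooted `phylo` tree whose two maximal root-to-leaf distances
#'   agree within 1e-9.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:3);")
#' midpoint_root(tr)  # root 2 from each leaf
midpoint_root <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an ape 'phylo' tree")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (all(tree$edge.length == 0)) {
    stop("all branch lengths are zero: midpoint undefined")
  }
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("midpoint rooting requires at least 2 leaves")

  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]  # fixed label order
  diam <- max(d)
  hits <- which(d == diam, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  lab <- tree$tip.label
  a <- pmin(lab[hits[, 1]], lab[hits[, 2]])
  b <- pmax(lab[hits[, 1]], lab[hits[, 2]])
  pick <- order(a, b, method = "radix")[1L]
  t1 <- match(a[pick], lab)
  t2 <- match(b[pick], lab)

  # walk the t1 -> t2 path; the midpoint lies diam/2 from t1
  path <- ape::nodepath(tree, t1, t2)
  target <- diam / 2
  if (is_midpoint_rooted(tree, tol = 1e-9)) return(tree)
  cum <- 0
  for (i in seq_len(length(path) - 1L)) {
    e <- which((tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1L]) |
               (tree$edge[, 1] == path[i + 1L] & tree$edge[, 2] == path[i]))
    len <- tree$edge.length[e]
    if (cum + len >= target - 1e-12) {
      # midpoint sits on this edge; child = endpoint farther from the root
      child <- if (tree$edge[e, 2] %in% c(path[i], path[i + 1L])) {
        tree$edge[e, 2]
      } else stop("inconsistent edge orientation")
      # walking up (child -> parent): midpoint is target-cum above the child;
      # walking down (parent -> child): it is cum+len-target above the child
      from_child <- if (child == path[i]) target - cum else cum + len - target
      return(root_on_edge(tree, e, from_child))
    }
    cum <- cum + len
  }
  stop("midpoint not found on diameter path")  # should not happen
}

is_midpoint_rooted <- function(tree, tol = 1e-9) {
  n_tip <- length(tree$tip.label)
  if (!ape::is.rooted(tree)) return(FALSE)
  kids <- tree$edge[tree$edge[, 1] == n_tip + 1L, 2]
  if (length(kids) != 2L) return(FALSE)
  depth <- node_depths(tree)
  d <- ape::cophenetic.phylo(tree)
  diam <- max(d)
  abs(max(depth[seq_len(n_tip)]) - diam / 2) <= tol &&
    two_sided_depths_equal(tree, depth, tol)
}

two_sided_depths_equal <- function(tree, depth, tol) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  deep <- vapply(kids, function(k) {
    lv <- if (k <= n_tip) k else {
      which(tree$tip.label %in% ape::extract.clade(tree, k)$tip.label)
    }
    max(depth[lv])
  }, numeric(1))
  abs(max(deep) - min(deep)) <= tol
}

node_depths <- function(tree) {
  n_tot <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n_tot)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    depth[pre$edge[i, 2]] <- depth[pre$edge[i, 1]] + pre$edge.length[i]
  }
  depth
}

# re-root the tree on edge e, at distance from_child above the child node
root_on_edge <- function(tree, e, from_child) {
  child <- tree$edge[e, 2]
  len <- tree$edge.length[e]
  from_child <- min(max(from_child, 0), len)
  # graft a temporary tip at the midpoint, root there, then remove it
  tmp <- "..midpoint.."
  tip <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = tmp,
              edge.length = 0, Nnode = 1L)
  class(tip) <- "phylo"
  aug <- ape::bind.tree(tree, tip, where = child, position = from_child)
  aug <- ape::root(aug, outgroup = tmp, resolve.root = TRUE)
  out <- ape::drop.tip(aug, tmp, collapse.singles = FALSE)
  out <- collapse_root_singleton(out)
  out
}

# dropping the temporary outgroup can leave a degree-2 root; splice it out
# while keeping the true root binary
collapse_root_singleton <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  repeat {
    kids <- which(tree$edge[, 1] == root)
    if (length(kids) != 1L) break
    tree <- ape::collapse.singles(tree)
    root <- length(tree$tip.label) + 1L
  }
  tree
}

#' Leaf annotation table
#'
#' Validates a leaf-annotation table: one row per (leaf, function) with the
#' leaf's domain of life and the annotation's confidence score. A leaf with
#' no function rows (or `NA` function) is uncharacterized — as for
#' family-seed leaves with no experimental record.
#'
#' @param leaf_id,domain_of_life,function_id,confidence Column vectors;
#'   `domain_of_life` must be one of `bacteria`, `archaea`, `eukaryota`,
#'   `virus`.
#' @return A validated data frame.
#' @export
leaf_annotations <- function(leaf_id, domain_of_life,
                             function_id = NA_character_,
                             confidence = NA_real_) {
  df <- data.frame(leaf_id = as.character(leaf_id),
                   domain_of_life = as.character(domain_of_life),
                   function_id = as.character(function_id),
                   confidence = as.numeric(confidence),
                   stringsAsFactors = FALSE)
  bad <- !df$domain_of_life %in% c("bacteria", "archaea", "eukaryota", "virus")
  if (any(bad)) stop("unknown domain of life: ",
                     paste(unique(df$domain_of_life[bad]), collapse = ", "))
  if (any(!is.na(df$confidence) & (df$confidence < 0 | df$confidence > 1))) {
    stop("confidence scores must lie in [0, 1]")
  }
  df
}

#' Read / write leaf annotations as TSV
#'
#' Columns `leaf_id`, `domain_of_life`, `function_id`, `confidence`;
#' multiple rows per leaf allowed.
#'
#' @param path TSV path.
#' @return Annotation data frame.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""),
                          colClasses = c(leaf_id = "character",
                                         domain_of_life = "character",
                                         function_id = "character",
                                         confidence = "numeric"))
  leaf_annotations(df$leaf_id, df$domain_of_life, df$function_id,
                   df$confidence)
}

#' @rdname read_annotations_tsv
#' @param annotations Annotation data frame.
#' @export
write_annotations_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# per-leaf characterization state at a confidence threshold
leaf_states <- function(tree, annotations, min_confidence) {
  miss <- setdiff(unique(annotations$leaf_id), tree$tip.label)
  if (length(miss) > 0L) {
    stop("annotation(s) reference leaves absent from the tree: ",
         paste(miss, collapse = ", "))
  }
  keep <- !is.na(annotations$function_id) &
    !is.na(annotations$confidence) &
    annotations$confidence >= min_confidence
  ann <- annotations[keep, , drop = FALSE]
  funs_by_leaf <- split(ann$function_id, ann$leaf_id)
  dom <- annotations$domain_of_life[!duplicated(annotations$leaf_id)]
  names(dom) <- annotations$leaf_id[!duplicated(annotations$leaf_id)]
  list(funs = funs_by_leaf,
       characterized = names(funs_by_leaf),
       domain = dom)
}

# maximal clades (node numbers) whose characterized leaves carry function f
# at >= coherence_fraction; singleton carriers qualify as leaf "clades"
coherent_nodes_for_function <- function(tree, states, function_id,
                                        coherence_fraction = 1.0) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(v) {
    if (v <= n_tip) v else {
      which(tree$tip.label %in% ape::extract.clade(tree, v)$tip.label)
    }
  }
  is_char <- tree$tip.label %in% states$characterized
  carries <- vapply(tree$tip.label, function(l) {
    function_id %in% states$funs[[l]]
  }, logical(1))

  qualifies <- function(v) {
    tp <- tips_below(v)
    nc <- sum(is_char[tp])
    nf <- sum(carries[tp])
    nc >= 1L && nf >= 1L && nf / nc >= coherence_fraction
  }
  out <- integer(0)
  stack <- n_tip + 1L
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (qualifies(v)) {
      out <- c(out, v)
    } else if (v > n_tip) {
      stack <- c(kids[[as.character(v)]], stack)
    }
  }
  out
}

#' Find functionally coherent clades
#'
#' A leaf is "characterized" when it carries at least one function with
#' confidence at or above `min_confidence` (default 0.2, the cutoff below
#' which annotations are considered unlikely to reflect physiological
#' activity; 0.5 is a stricter preset). For each function, the maximal
#' clades are found in which at least `coherence_fraction` of the
#' characterized leaves carry that function; clades with at least two
#' characterized leaves are reported, each classified `multi_domain` when
#' its characterized leaves span at least two domains of life (viruses are
#' excluded from the domain count but flagged) or `single_domain`
#' otherwise. Multi-domain coherent clades are the operational signature of
#' candidate-ancestral functions.
#'
#' @param tree A rooted `phylo` tree.
#' @param annotations Leaf-annotation data frame ([leaf_annotations()]).
#' @param min_confidence Characterization threshold in \[0, 1\].
#' @param coherence_fraction Minimum fraction of characterized leaves in the
#'   clade that must share the function; default 1.0 (strict).
#' @return Data frame with one row per (clade, function): `clade_id` (the
#'   node number), `function_id`, `n_characterized`, `n_supporting`,
#'   `domains` (comma-joined, viruses excluded), `has_virus`,
#'   `classification`, `leaves` (comma-joined leaf labels).
#' @export
find_function_clades <- function(tree, annotations, min_confidence = 0.2,
                                 coherence_fraction = 1.0) {
  check_phylo(tree)
  states <- leaf_states(tree, annotations, min_confidence)
  if (length(states$characterized) == 0L) return(empty_clade_table())
  funs <- sort(unique(unlist(states$funs)), method = "radix")
  n_tip <- length(tree$tip.label)

  rows <- lapply(funs, function(f) {
    nodes <- coherent_nodes_for_function(tree, states, f, coherence_fraction)
    do.call(rbind, lapply(nodes, function(v) {
      tp <- if (v <= n_tip) v else {
        which(tree$tip.label %in% ape::extract.clade(tree, v)$tip.label)
      }
      labs <- tree$tip.label[tp]
      ch <- labs[labs %in% states$characterized]
      if (length(ch) < 2L) return(NULL)  # degenerate clades not reported
      supp <- sum(vapply(ch, function(l) f %in% states$funs[[l]], logical(1)))
      doms <- unique(states$domain[ch])
      doms <- doms[!is.na(doms)]
      has_virus <- "virus" %in% doms
      doms <- sort(setdiff(doms, "virus"), method = "radix")
      data.frame(clade_id = v, function_id = f,
                 n_characterized = length(ch), n_supporting = supp,
                 domains = paste(doms, collapse = ","),
                 has_virus = has_virus,
                 classification = if (length(doms) >= 2L) "multi_domain"
                                  else "single_domain",
                 leaves = paste(sort(labs, method = "radix"), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_clade_table())
  rownames(out) <- NULL
  out
}

empty_clade_table <- function() {
  data.frame(clade_id = integer(), function_id = character(),
             n_characterized = integer(), n_supporting = integer(),
             domains = character(), has_virus = logical(),
             classification = character(), leaves = character(),
             stringsAsFactors = FALSE)
}

#' Count independent clades carrying a function
#'
#' Counts the maximal function-coherent clades (as in
#' [find_function_clades()], but with singleton characterized carriers
#' counted as degenerate clades) that contain the function. A count of 1
#' indicates the characterized carriers are monophyletic; 2 or more
#' indicates homoplasy (independent origins) or loss.
#'
#' @inheritParams find_function_clades
#' @param function_id The function to count.
#' @return Integer count (0, with a warning, when no characterized leaf
#'   carries the function at the threshold).
#' @export
polyphyly_count <- function(tree, annotations, function_id,
                            min_confidence = 0.2, coherence_fraction = 1.0) {
  check_phylo(tree)
  states <- leaf_states(tree, annotations, min_confidence)
  known <- unique(unlist(states$funs))
  if (!function_id %in% known) {
    warning("no characterized leaf carries function ", function_id,
            " at confidence >= ", min_confidence)
    return(0L)
  }
  length(coherent_nodes_for_function(tree, states, function_id,
                                     coherence_fraction))
}

#' Per-function polyphyly summary
#'
#' @inheritParams find_function_clades
#' @return Data frame with `function_id`, `n_clades`, `monophyletic`.
#' @export
polyphyly_summary <- function(tree, annotations, min_confidence = 0.2,
                              coherence_fraction = 1.0) {
  states <- leaf_states(tree, annotations, min_confidence)
  funs <- sort(unique(unlist(states$funs)), method = "radix")
  n <- vapply(funs, function(f) {
    length(coherent_nodes_for_function(tree, states, f, coherence_fraction))
  }, integer(1))
  data.frame(function_id = funs, n_clades = n, monophyletic = n == 1L,
             stringsAsFactors = FALSE)
}
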