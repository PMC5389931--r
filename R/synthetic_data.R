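#' Simulation configuration
#'
#' Bundles the knobs of the seeded generators that produce trees, leaf
#' annotations and evidence tables with planted ground truth. A fixed seed
#' gives byte-identical outputs; the single seed fans out to an independent
#' substream per generator stage, so adding a stage never perturbs earlier
#' streams.
#'
#' Defaults describe the study conditions the generators emulate: trees of
#' 100 leaves with exponential branch lengths (mean 0.1 substitutions/site);
#' 4 functions planted on clades of 3-8 leaves with 1 independent origin
#' each; a domain-of-life mix dominated by bacteria with within-clade
#' correlation; kinetic screens in which true substrates have kcat/Km of
#' 10^6-10^7 M^-1 s^-1 (orders of magnitude above decoys at 10^3-10^4,
#' mirroring the >1000-fold kinetic separation seen between physiological
#' and non-physiological substrates), with lognormal noise of 0.3 log10
#' units; decoy evidence for half the proteins; and a genetic record for
#' 10% of proteins.
#'
#' @param seed Integer master seed.
#' @param n_leaves Number of tree leaves.
#' @param branch_length_scale Mean of the exponential branch lengths.
#' @param n_functions Number of planted functions.
#' @param origins_per_function Number of disjoint clades each function is
#'   planted on (1 = monophyletic truth; >= 2 = planted homoplasy).
#' @param clade_size_range Leaf-count range of candidate planted clades.
#' @param domain_mix Named probability vector over
#'   `bacteria`, `archaea`, `eukaryota`, `virus`.
#' @param domain_coherence Probability that a leaf inherits its clade's
#'   domain of life rather than redrawing from `domain_mix`.
#' @param background_rate Probability that a leaf outside every planted
#'   clade is characterized with a lineage-specific background function.
#' @param evidence_noise Lognormal spread (sd, log10 units) of simulated
#'   kcat/Km around the true-function value.
#' @param decoy_rate Probability that a protein also receives decoy
#'   kinetic evidence for a non-true function.
#' @param genetic_rate Probability that a protein receives a genetic
#'   (knockout) record for its true function in addition to kinetics.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_leaves = 100L,
                       branch_length_scale = 0.1,
                       n_functions = 4L,
                       origins_per_function = 1L,
                       clade_size_range = c(3L, 8L),
                       domain_mix = c(bacteria = 0.50, archaea = 0.15,
                                      eukaryota = 0.30, virus = 0.05),
                       domain_coherence = 0.9,
                       background_rate = 0.6,
                       evidence_noise = 0.3,
                       decoy_rate = 0.5,
                       genetic_rate = 0.1) {
  stopifnot(n_leaves >= 2L, branch_length_scale > 0, n_functions >= 1L,
            origins_per_function >= 1L, evidence_noise >= 0,
            decoy_rate >= 0, decoy_rate <= 1)
  if (abs(sum(domain_mix) - 1) > 1e-8) {
    stop("domain_mix probabilities must sum to 1")
  }
  structure(list(seed = as.integer(seed), n_leaves = as.integer(n_leaves),
                 branch_length_scale = branch_length_scale,
                 n_functions = as.integer(n_functions),
                 origins_per_function = as.integer(origins_per_function),
                 clade_size_range = as.integer(clade_size_range),
                 domain_mix = domain_mix,
                 domain_coherence = domain_coherence,
                 background_rate = background_rate,
                 evidence_noise = evidence_noise,
                 decoy_rate = decoy_rate,
                 genetic_rate = genetic_rate),
            class = "sim_config")
}

# independent substream per stage; keeps derived seeds under 2^31
stage_seed <- function(config, stage) {
  offset <- c(tree = 101L, annotations = 211L, evidence = 307L)[[stage]]
  (config$seed * 1009L + offset) %% 2147483587L
}

#' Simulate a random tree
#'
#' Random binary topology grown by uniform attachment (each new leaf is
#' attached at a uniformly chosen existing branch) with independent
#' exponential branch lengths at the configured scale. Leaf labels are
#' `L0001`, `L0002`, ... Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A rooted binary `phylo` tree.
#' @export
sim_tree <- function(config = sim_config()) {
  set.seed(stage_seed(config, "tree"))
  n <- config$n_leaves
  tree <- if (n == 2L) {
    ape::read.tree(text = "(t1:1,t2:1);")
  } else {
    # uniform attachment: grow by splitting a uniformly chosen branch
    grow_uniform_attachment(n)
  }
  tree$edge.length <- stats::rexp(nrow(tree$edge),
                                  rate = 1 / config$branch_length_scale)
  tree$tip.label <- sprintf("L%04d", seq_len(n))
  tree
}

grow_uniform_attachment <- function(n) {
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  for (k in 3:n) {
    e <- sample.int(nrow(tree$edge), 1L)
    target <- tree$edge[e, 2]
    tip <- list(edge = matrix(c(2L, 1L), 1L, 2L),
                tip.label = paste0("t", k), edge.length = 1, Nnode = 1L)
    class(tip) <- "phylo"
    pos <- tree$edge.length[e] / 2
    tree <- ape::bind.tree(tree, tip, where = target, position = pos)
  }
  tree
}

#' Simulate leaf annotations with planted functions
#'
#' Plants each of `n_functions` functions on `origins_per_function`
#' disjoint clades (drawn from internal nodes whose leaf count lies in
#' `clade_size_range`); leaves of a planted clade carry that function at
#' high confidence (0.7-0.99). Leaves outside every planted clade are
#' characterized with a lineage-specific background function (ids `BG...`)
#' at rate `background_rate` and confidence 0.3-0.9, emulating the dense
#' annotation of a curated reference phylogeny; remaining leaves are
#' uncharacterized. Domains of life are drawn per leaf from `domain_mix`
#' with within-clade correlation (`domain_coherence`).
#'
#' @param tree A tree from [sim_tree()].
#' @param config A [sim_config()].
#' @return List with `annotations` (a [leaf_annotations()] data frame) and
#'   `truth` (per planted function: its clades' leaf sets and the planted
#'   number of independent origins).
#' @export
sim_annotations <- function(tree, config = sim_config()) {
  set.seed(stage_seed(config, "annotations"))
  n_tip <- length(tree$tip.label)
  stats <- compute_node_stats(tree)
  cand <- which(!stats$is_leaf &
                stats$n_leaves >= config$clade_size_range[1L] &
                stats$n_leaves <= config$clade_size_range[2L])
  cand <- cand[sample.int(length(cand))]

  need <- config$n_functions * config$origins_per_function
  fun_ids <- sprintf("F%02d", seq_len(config$n_functions))
  # planting order F1,F1,...,F2,F2,...: slot i belongs to function fn_of(i)
  fn_of <- rep(fun_ids, each = config$origins_per_function)
  chosen <- integer(0)
  clade_lv <- list()
  used <- character(0)
  for (v in cand) {
    lv <- clade_leaves(tree, v)
    if (any(lv %in% used)) next
    # independent origins must stay separable: the MRCA with every
    # same-function clade already planted must contain a third-party leaf
    i <- length(chosen) + 1L
    same <- which(fn_of[seq_len(i - 1L)] == fn_of[i])
    separable <- all(vapply(same, function(j) {
      anc <- ape::getMRCA(tree, c(lv[1L], clade_lv[[j]][1L]))
      length(clade_leaves(tree, anc)) > length(lv) + length(clade_lv[[j]])
    }, logical(1)))
    if (!separable) next
    chosen <- c(chosen, v)
    clade_lv[[i]] <- lv
    used <- c(used, lv)
    if (length(chosen) == need) break
  }
  if (length(chosen) < need) {
    stop("cannot plant ", need, " disjoint clades on this tree; found only ",
         length(chosen))
  }
  assign_fun <- fn_of

  domains <- names(config$domain_mix)
  leaf_dom <- sample(domains, n_tip, replace = TRUE, prob = config$domain_mix)
  names(leaf_dom) <- tree$tip.label

  rows <- list()
  truth <- stats::setNames(vector("list", config$n_functions), fun_ids)
  for (i in seq_along(chosen)) {
    lv <- clade_leaves(tree, chosen[i])
    f <- assign_fun[i]
    truth[[f]]$clades <- c(truth[[f]]$clades, list(lv))
    # within-clade domain correlation: clade draws one domain, leaves
    # inherit it with probability domain_coherence
    clade_dom <- sample(domains, 1L, prob = config$domain_mix)
    inherit <- stats::runif(length(lv)) < config$domain_coherence
    leaf_dom[lv[inherit]] <- clade_dom
    rows[[length(rows) + 1L]] <- data.frame(
      leaf_id = lv, domain_of_life = leaf_dom[lv], function_id = f,
      confidence = stats::runif(length(lv), 0.7, 0.99),
      stringsAsFactors = FALSE)
  }
  for (f in fun_ids) truth[[f]]$origins <- config$origins_per_function

  outside <- setdiff(tree$tip.label, used)
  bg <- outside[stats::runif(length(outside)) < config$background_rate]
  # postcondition: planted origins are independent — every pair of
  # same-function clades must have a characterized non-carrier under its
  # MRCA; promote one unplanted leaf to background where none exists
  for (f in fun_ids) {
    idx <- which(assign_fun == f)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      anc <- ape::getMRCA(tree, c(clade_lv[[a]][1L], clade_lv[[b]][1L]))
      under <- clade_leaves(tree, anc)
      # a separator must not itself carry f: exclude every f-clade leaf
      others <- setdiff(under, unlist(clade_lv[idx]))
      if (!any(others %in% c(used, bg))) {
        free <- sort(setdiff(others, used), method = "radix")
        if (length(free) > 0L) bg <- c(bg, free[1L])
      }
    }
  }
  bg <- outside[outside %in% bg]  # restore deterministic order
  if (length(bg) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      leaf_id = bg, domain_of_life = leaf_dom[bg],
      function_id = sprintf("BG%04d", match(bg, tree$tip.label)),
      confidence = stats::runif(length(bg), 0.3, 0.9),
      stringsAsFactors = FALSE)
  }
  uncha <- setdiff(outside, bg)
  if (length(uncha) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      leaf_id = uncha, domain_of_life = leaf_dom[uncha],
      function_id = NA_character_, confidence = NA_real_,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann <- ann[order(ann$leaf_id, ann$function_id, method = "radix"), ]
  rownames(ann) <- NULL
  list(annotations = leaf_annotations(ann$leaf_id, ann$domain_of_life,
                                      ann$function_id, ann$confidence),
       truth = truth)
}

#' Simulate an evidence table from a true-function map
#'
#' For each protein, draws true-function kinetic evidence with log10
#' kcat/Km uniform on \[6, 7\] plus Gaussian noise of sd `evidence_noise`
#' (a lognormal kinetic model: the scoring model is linear in log10).
#' With probability `decoy_rate` the protein also receives decoy kinetic
#' evidence for a decoy function, log10 uniform on \[3, 4\] plus the same
#' noise. With probability `genetic_rate` a knockout record with the
#' predicted phenotype is added for the true function. Deterministic under
#' the config seed.
#'
#' @param true_function_map Named character vector: protein id -> true
#'   function id.
#' @param config A [sim_config()].
#' @return List with `records` (an evidence data frame) and `truth` (the
#'   input map).
#' @export
sim_evidence <- function(true_function_map, config = sim_config()) {
  set.seed(stage_seed(config, "evidence"))
  prot <- names(true_function_map)
  if (is.null(prot)) stop("true_function_map must be named by protein id")
  rows <- list()
  for (p in prot) {
    truef <- true_function_map[[p]]
    l10 <- stats::runif(1L, 6, 7) + stats::rnorm(1L, 0, config$evidence_noise)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = p, function_id = truef, category = "biochemical",
      subtype = "kcat_km", value = 10^l10, source_ref = "sim:true",
      stringsAsFactors = FALSE)
    if (stats::runif(1L) < config$decoy_rate) {
      l10d <- stats::runif(1L, 3, 4) + stats::rnorm(1L, 0, config$evidence_noise)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, function_id = paste0(truef, "_decoy"),
        category = "biochemical", subtype = "kcat_km", value = 10^l10d,
        source_ref = "sim:decoy", stringsAsFactors = FALSE)
    }
    if (stats::runif(1L) < config$genetic_rate) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, function_id = truef, category = "genetic",
        subtype = "knockout_predicted", value = NA_real_,
        source_ref = "sim:genetic", stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  list(records = rec, truth = true_function_map)
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper running [sim_tree()], [sim_annotations()] and
#' [sim_evidence()] (one protein per planted-clade leaf, its true function
#' being the planted one), returning every piece plus the ground truth
#' needed to compute recovery statistics.
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `annotations`, `truth`, `evidence` and
#'   `true_function_map`.
#' @export
sim_study <- function(config = sim_config()) {
  tree <- sim_tree(config)
  ann <- sim_annotations(tree, config)
  planted <- ann$annotations[grepl("^F", ann$annotations$function_id) &
                             !is.na(ann$annotations$function_id), ]
  map <- stats::setNames(planted$function_id, planted$leaf_id)
  ev <- sim_evidence(map, config)
  list(tree = tree, annotations = ann$annotations, truth = ann$truth,
       evidence = ev$records, true_function_map = map)
}
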