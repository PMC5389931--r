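test_that("midpoint rooting splits the two-leaf path evenly", {
  tr <- ape::read.tree(text = "(A:1,B:3);")
  mr <- midpoint_root(tr)
  d <- ape::cophenetic.phylo(mr)
  expect_equal(d["A", "B"], 4)
  depth <- numeric(2 + mr$Nnode)
  for (i in seq_len(nrow(mr$edge))) {
    depth[mr$edge[i, 2]] <- depth[mr$edge[i, 1]] + mr$edge.length[i]
  }
  expect_equal(unname(depth[1:2]), c(2, 2))
  expect_error(midpoint_root(ape::read.tree(text = "(A:0,B:0);")),
               "midpoint undefined")
})

test_that("midpoint rooting balances the deepest paths on random trees", {
  set.seed(909)
  for (i in 1:40) {
    tr <- random_test_tree(sample(5:20, 1))
    mr <- midpoint_root(tr)
    # same leaves, same pairwise distances
    expect_setequal(mr$tip.label, tr$tip.label)
    expect_equal(ape::cophenetic.phylo(mr)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-9)
    # the deepest leaf sits at half the brute-force diameter
    expect_equal(max_root_depth(mr), brute_diameter(tr) / 2,
                 tolerance = 1e-9)
    # and both root children reach that depth (equal-deepest-path property)
    expect_true(nudixevol:::is_midpoint_rooted(mr, tol = 1e-9))
  }
})

test_that("midpoint rooting agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(910)
  for (i in 1:10) {
    tr <- random_test_tree(sample(5:15, 1))
    mr <- midpoint_root(tr)
    ph <- phangorn::midpoint(tr)
    expect_equal(max_root_depth(mr), max_root_depth(ph), tolerance = 1e-9)
  }
})

test_that("midpoint rooting is idempotent", {
  set.seed(911)
  tr <- random_test_tree(12)
  mr <- midpoint_root(tr)
  again <- midpoint_root(mr)
  expect_identical(ape::write.tree(again), ape::write.tree(mr))
})

make_planted_tree <- function() {
  # clade P = (p1..p4) carries F; clade Q = (q1,q2) carries G; r1 unrelated
  ape::read.tree(text = paste0(
    "(((p1:1,p2:1):1,(p3:1,p4:1):1):2,((q1:1,q2:1):2,r1:3):1);"))
}

planted_annotations <- function() {
  leaf_annotations(
    leaf_id = c("p1", "p2", "p3", "p4", "q1", "q2", "r1"),
    domain_of_life = c("bacteria", "eukaryota", "bacteria", "archaea",
                       "bacteria", "bacteria", "virus"),
    function_id = c("F", "F", "F", "F", "G", "G", NA),
    confidence = c(0.9, 0.8, 0.7, 0.95, 0.6, 0.5, NA))
}

test_that("planted coherent clades are found, classified and maximal", {
  tr <- make_planted_tree()
  fc <- find_function_clades(tr, planted_annotations())
  expect_equal(sort(fc$function_id), c("F", "G"))
  frow <- fc[fc$function_id == "F", ]
  expect_equal(frow$n_characterized, 4)
  expect_equal(frow$n_supporting, 4)
  expect_equal(frow$leaves, "p1,p2,p3,p4")
  # bacteria + eukaryota + archaea present: a multi-domain (candidate
  # ancestral) clade
  expect_equal(frow$classification, "multi_domain")
  # the maximal G-coherent clade absorbs the uncharacterized neighbor r1
  grow <- fc[fc$function_id == "G", ]
  expect_equal(grow$leaves, "q1,q2,r1")
  expect_equal(grow$n_characterized, 2)
  expect_equal(grow$classification, "single_domain")
})

test_that("uncharacterized trees and confidence thresholds behave", {
  tr <- make_planted_tree()
  none <- leaf_annotations(tr$tip.label, rep("bacteria", 7))
  expect_equal(nrow(find_function_clades(tr, none)), 0)
  # raising the threshold above G's confidences removes that clade
  fc <- find_function_clades(tr, planted_annotations(), min_confidence = 0.65)
  expect_false("G" %in% fc$function_id)
  expect_error(
    find_function_clades(tr, leaf_annotations("zz", "bacteria", "F", 0.9)),
    "absent")
})

test_that("virus leaves are excluded from the domain count but flagged", {
  tr <- make_planted_tree()
  ann <- leaf_annotations(
    leaf_id = c("q1", "q2", "p1"),
    domain_of_life = c("bacteria", "virus", "bacteria"),
    function_id = c("G", "G", "H"),
    confidence = c(0.9, 0.9, 0.9))
  fc <- find_function_clades(tr, ann)
  grow <- fc[fc$function_id == "G", ]
  expect_equal(grow$classification, "single_domain")
  expect_equal(grow$domains, "bacteria")
  expect_true(grow$has_virus)
})

test_that("polyphyly counts planted origins and respects the threshold", {
  tr <- make_planted_tree()
  ann <- planted_annotations()
  expect_equal(polyphyly_count(tr, ann, "F"), 1L)  # monophyletic
  expect_equal(polyphyly_count(tr, ann, "G"), 1L)
  # plant F a second, disjoint time on q1: two independent origins
  ann2 <- rbind(ann, leaf_annotations("q1", "bacteria", "F", 0.9))
  expect_equal(polyphyly_count(tr, ann2, "F"), 2L)
  # scores below the threshold do not count as characterized
  low <- leaf_annotations(c("p1", "p2"), c("bacteria", "bacteria"),
                          c("F", "F"), c(0.1, 0.15))
  expect_warning(n <- polyphyly_count(tr, low, "F"), "no characterized")
  expect_equal(n, 0L)
  expect_warning(polyphyly_count(tr, ann, "nosuch"), "no characterized")
})

test_that("three planted origins yield a polyphyly count of three", {
  # F on three mutually non-nested clades, separated by other functions
  tr <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1):1,(x1:1,x2:1):1):1,",
    "((b1:1,b2:1):1,((y1:1,y2:1):1,(c1:1,c2:1):1):1):1);"))
  ann <- leaf_annotations(
    leaf_id = c("a1", "a2", "b1", "b2", "c1", "c2", "x1", "x2", "y1", "y2"),
    domain_of_life = rep("bacteria", 10),
    function_id = c(rep("F", 6), "X", "X", "Y", "Y"),
    confidence = rep(0.9, 10))
  expect_equal(polyphyly_count(tr, ann, "F"), 3L)
  cl <- find_function_clades(tr, ann)
  fcl <- cl[cl$function_id == "F", ]
  # mutually non-nested maximal clades
  leaf_sets <- strsplit(fcl$leaves, ",")
  for (i in seq_along(leaf_sets)) {
    for (j in seq_along(leaf_sets)) {
      if (i != j) expect_length(intersect(leaf_sets[[i]], leaf_sets[[j]]), 0)
    }
  }
})

test_that("loose coherence admits clades with a minority dissenter", {
  tr <- make_planted_tree()
  # p4 characterized with a different function; strict coherence splits the
  # P clade, 0.7 coherence keeps it whole
  ann <- leaf_annotations(
    leaf_id = c("p1", "p2", "p3", "p4"),
    domain_of_life = rep("bacteria", 4),
    function_id = c("F", "F", "F", "Z"),
    confidence = rep(0.9, 4))
  strict <- find_function_clades(tr, ann, coherence_fraction = 1.0)
  expect_equal(strict[strict$function_id == "F", "leaves"], "p1,p2")
  loose <- find_function_clades(tr, ann, coherence_fraction = 0.7)
  expect_equal(loose[loose$function_id == "F", "n_characterized"], 4)
  expect_equal(loose[loose$function_id == "F", "n_supporting"], 3)
})

test_that("lowering the threshold never shrinks a clade's characterized set", {
  set.seed(912)
  cfg <- sim_config(seed = 31, n_leaves = 60, n_functions = 3)
  tr <- sim_tree(cfg)
  ann <- sim_annotations(tr, cfg)$annotations
  hi <- find_function_clades(tr, ann, min_confidence = 0.5)
  lo <- find_function_clades(tr, ann, min_confidence = 0.2)
  for (f in intersect(hi$function_id, lo$function_id)) {
    expect_gte(max(lo$n_characterized[lo$function_id == f]),
               max(hi$n_characterized[hi$function_id == f]))
  }
})

test_that("annotation TSV round-trips", {
  ann <- planted_annotations()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_annotations_tsv(ann, tf)
  back <- read_annotations_tsv(tf)
  expect_equal(back, ann)
})
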