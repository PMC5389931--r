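test_that("kinetic scores reproduce the anchor table and log interpolation", {
  tab <- score_table()
  # anchors, exactly
  expect_equal(score_kinetic(1e3, tab), 0.1)
  expect_equal(score_kinetic(1e4, tab), 0.2)
  expect_equal(score_kinetic(1e5, tab), 0.5)
  expect_equal(score_kinetic(1e6, tab), 0.85)
  expect_equal(score_kinetic(1e7, tab), 0.99)
  expect_equal(score_kinetic(0, tab), 0.01)
  # the worked interpolation example: 5e6 between the 10^6 and 10^7 anchors
  expect_equal(score_kinetic(5e6, tab),
               (log10(5e6) - 6) * (0.99 - 0.85) + 0.85)
  expect_equal(round(score_kinetic(5e6, tab), 3), 0.948)
  # clamping outside the anchor range
  expect_equal(score_kinetic(1e9, tab), 0.99)
  expect_equal(score_kinetic(50, tab), 0.1)
  expect_error(score_kinetic(-1, tab), "non-negative")
})

test_that("pseudo-kinetic scores use the lower anchor set", {
  tab <- score_table()
  expect_equal(score_pseudo_kinetic(1e7, tab), 0.7)
  expect_equal(score_pseudo_kinetic(1e3, tab), 0.05)
  expect_equal(score_pseudo_kinetic(0, tab), 0.01)
  expect_equal(score_pseudo_kinetic(5e6, tab),
               (log10(5e6) - 6) * (0.7 - 0.5) + 0.5)
  expect_equal(round(score_pseudo_kinetic(5e6, tab), 3), 0.640)
})

test_that("kinetic scorers are non-decreasing in kcat/Km", {
  tab <- score_table()
  set.seed(42)
  for (i in 1:200) {
    v <- sort(10^stats::runif(2, -1, 9))
    expect_lte(score_kinetic(v[1], tab), score_kinetic(v[2], tab))
    expect_lte(score_pseudo_kinetic(v[1], tab), score_pseudo_kinetic(v[2], tab))
  }
  vals <- 10^stats::runif(100, -1, 9)
  expect_true(all(score_kinetic(vals, tab) >= 0 &
                  score_kinetic(vals, tab) <= 1))
})

test_that("pseudo-kcat/Km follows the squared activity ratio", {
  expect_equal(pseudo_kcat_km(100, 100, 1e6), 1e6)
  expect_equal(pseudo_kcat_km(0, 100, 1e6), 0)
  expect_equal(pseudo_kcat_km(50, 100, 1e6), 2.5e5)
  expect_error(pseudo_kcat_km(50, 0, 1e6), "> 0")
})

test_that("relative-activity scores are linear with a clamp above 100%", {
  tab <- score_table()
  expect_equal(score_relative_activity(100, tab), 0.1)
  expect_equal(score_relative_activity(0, tab), 0)
  expect_equal(score_relative_activity(50, tab), 0.05)
  expect_warning(s <- score_relative_activity(130, tab), "clamped")
  expect_equal(s, 0.1)
  expect_error(score_relative_activity(-5, tab), "non-negative")
})

test_that("category scores take the maximum over records", {
  tab <- score_table()
  gen <- evidence_records("p", "f", "genetic", "knockout_predicted")
  expect_equal(score_category(gen, tab), 0.99)
  bio <- evidence_records(c("p", "p"), c("f", "f"),
                          c("biochemical", "biochemical"),
                          c("kcat_km", "kcat_km"), c(1e3, 1e7))
  expect_equal(score_category(bio, tab), 0.99)
  gel <- evidence_records("p", "f", "biochemical", "gel_hplc_common")
  expect_equal(score_category(gel, tab), 0.05)
  mixed <- rbind(gen, gel)
  expect_error(score_category(mixed, tab), "one category")
})

test_that("qualitative and genetic lookups match the assignment table", {
  tab <- score_table()
  expect_equal(score_record("knockout_related", table = tab), 0.7)
  expect_equal(score_record("knockout_inexplicable", table = tab), 0.1)
  expect_equal(score_record("rescue", table = tab), 0.5)
  expect_equal(score_record("gel_rare_substrate", table = tab), 0.5)
  expect_equal(score_record("xray_binding", table = tab), 0.5)
  expect_equal(score_record("xray_substrate", table = tab), 0.01)
  expect_equal(score_record("positive_activity", table = tab), 0.01)
  # the stricter rescue reading remains configurable
  tab2 <- score_table(genetic_scores = c(rescue = 0.7))
  expect_equal(score_record("rescue", table = tab2), 0.7)
})

test_that("overall combination is a noisy OR", {
  expect_equal(combine_overall(0, 0), 0)
  expect_equal(combine_overall(0.7, 0.5), 0.85)
  set.seed(7)
  a <- stats::runif(100)
  b <- stats::runif(100)
  s <- combine_overall(a, b)
  expect_equal(s, 1 - (1 - a) * (1 - b))
  expect_true(all(s >= pmax(a, b)))
  expect_equal(combine_overall(a, 0), a)  # absent biochemical evidence
  expect_error(combine_overall(1.2, 0), "\\[0, 1\\]")
})

test_that("final-score adjustment matches the three-case Z formula", {
  # SD = 0 and single-annotation pass-throughs
  expect_equal(adjust_final(c(0.5, 0.5, 0.5))$s_final, c(0.5, 0.5, 0.5))
  expect_equal(adjust_final(0.8)$s_final, 0.8)
  expect_equal(adjust_final(0.8)$z_score, 0)
  # hand evaluation with population SD: scores (0.9, 0.1, 0.1, 0.1) have
  # mean 0.3 and SD sqrt(0.12), so Z = sqrt(3) for the outlier and
  # -1/sqrt(3) for the rest
  a <- adjust_final(c(0.9, 0.1, 0.1, 0.1))
  expect_equal(a$z_score, c(sqrt(3), -1 / sqrt(3), -1 / sqrt(3), -1 / sqrt(3)))
  expect_equal(a$s_final,
               c(1 - 0.1 / (1 + sqrt(3)), rep(0.1 / (1 + 1 / sqrt(3)), 3)))
  expect_gt(a$s_final[1], 0.9)         # outlier strictly increased
  expect_true(all(a$s_final[2:4] < 0.1))  # low elements strictly decreased
})

test_that("adjustment preserves rank order and moves scores with Z's sign", {
  set.seed(11)
  for (i in 1:100) {
    s <- stats::runif(sample(1:8, 1))
    a <- adjust_final(s)
    expect_equal(order(a$s_final), order(s))
    expect_true(all(a$s_final >= 0 & a$s_final <= 1))
    expect_true(all(a$s_final[a$z_score > 0] >= a$s_overall[a$z_score > 0]))
    expect_true(all(a$s_final[a$z_score < 0] <= a$s_overall[a$z_score < 0]))
    expect_equal(a$s_final[a$z_score == 0], a$s_overall[a$z_score == 0])
  }
})

test_that("score_dataset runs the full pipeline deterministically", {
  tab <- score_table()
  expect_equal(nrow(score_dataset(evidence_records(character(0), character(0),
                                                   character(0), character(0)),
                                  tab)), 0)
  one <- evidence_records("p1", "fA", "genetic", "knockout_predicted")
  res <- score_dataset(one, tab)
  expect_equal(res$s_final, 0.99)
  expect_equal(res$s_biochem, 0)
  expect_equal(res$z_score, 0)
  expect_equal(res$n_records, 1L)

  ev <- evidence_records(
    protein_id = c("p2", "p2", "p2", "p1"),
    function_id = c("fB", "fA", "fB", "fA"),
    category = c("biochemical", "biochemical", "genetic", "genetic"),
    subtype = c("kcat_km", "kcat_km", "knockout_related", "knockout_predicted"),
    value = c(1e7, 1e3, NA, NA))
  res <- score_dataset(ev, tab)
  expect_equal(res$protein_id, c("p1", "p2", "p2"))
  expect_equal(res$function_id, c("fA", "fA", "fB"))
  # p2/fB combines kcat/Km 1e7 (0.99) with knockout_related (0.7)
  expect_equal(res$s_overall[3], 1 - (1 - 0.7) * (1 - 0.99))
  expect_true(all(res$s_final >= 0 & res$s_final <= 1))

  # permuting the input rows yields identical output
  set.seed(3)
  perm <- ev[sample(nrow(ev)), ]
  expect_equal(score_dataset(perm, tab), res)
})

test_that("score_dataset reports and skips malformed rows", {
  ev <- data.frame(protein_id = c("p1", "p1"), function_id = c("fA", "fB"),
                   category = c("genetic", "mystery"),
                   subtype = c("knockout_predicted", "kcat_km"),
                   value = c(NA, 1e6), source_ref = NA,
                   stringsAsFactors = FALSE)
  expect_message(res <- score_dataset(ev), "skipping row 2")
  expect_equal(nrow(res), 1)
  expect_equal(res$function_id, "fA")
})

test_that("evidence TSV round-trips and scored TSV prints 4 decimals", {
  ev <- evidence_records(c("p1", "p1"), c("fA", "fB"),
                         c("genetic", "biochemical"),
                         c("knockout_predicted", "kcat_km"),
                         c(NA, 5e6), c("ref1", "ref2"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ev, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_evidence_tsv(tf)
  expect_equal(back$protein_id, ev$protein_id)
  expect_equal(back$value, ev$value)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(score_dataset(ev), out)
  txt <- readLines(out)
  expect_match(txt[1], "^protein_id\tfunction_id\ts_genetic")
  expect_match(txt[2], "0\\.9900")
})

test_that("score config YAML overrides merge into the defaults", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("genetic_scores:", "  rescue: 0.7",
               "relative_activity_max_score: 0.2"), tf)
  expect_message(tab <- read_score_config(tf), "override")
  expect_equal(unname(tab$genetic_scores["rescue"]), 0.7)
  expect_equal(unname(tab$genetic_scores["knockout_predicted"]), 0.99)
  expect_equal(tab$relative_activity_max_score, 0.2)
  expect_error(score_table(kinetic_anchors = c("3" = 0.9, "4" = 0.2)),
               "strictly increasing")
})
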