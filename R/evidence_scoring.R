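#' Score a kcat/Km measurement
#'
#' Maps a catalytic efficiency (specificity constant, M^-1 s^-1) to a
#' confidence score in \[0, 1\] by piecewise-linear interpolation in
#' log10(value) between the anchor points of the score table. Exact anchor
#' values return the anchor scores; values above the top anchor clamp to the
#' top score; nonzero values below the bottom anchor clamp to the bottom
#' anchor score; a value of exactly 0 (no detectable activity) returns the
#' zero-activity score.
#'
#' With the default anchors, kcat/Km = 5e6 gives
#' `(log10(5e6) - 6) * (0.99 - 0.85) + 0.85 = 0.948` (to 3 decimals).
#'
#' @param value kcat/Km in M^-1 s^-1; non-negative. Vectorised.
#' @param table A [score_table()].
#' @return Numeric score(s) in \[0, 1\].
#' @export
#' @examples
#' score_kinetic(5e6)   # 0.948
#' score_kinetic(1e7)   # 0.99
#' score_kinetic(0)     # 0.01
score_kinetic <- function(value, table = score_table()) {
  interp_log_anchors(value, table$kinetic_anchors, table$kinetic_zero_score)
}

#' Score a pseudo-kcat/Km estimate
#'
#' Same log-linear interpolation scheme as [score_kinetic()], over the
#' pseudo-kcat/Km anchor set, which assigns systematically lower scores
#' because pseudo-kcat/Km values are crude estimates derived from
#' relative-activity screens (see [pseudo_kcat_km()]).
#'
#' @inheritParams score_kinetic
#' @return Numeric score(s) in \[0, 1\].
#' @export
score_pseudo_kinetic <- function(value, table = score_table()) {
  interp_log_anchors(value, table$pseudo_anchors, table$pseudo_zero_score)
}

interp_log_anchors <- function(value, anchors, zero_score) {
  if (any(is.na(value)) || any(value < 0)) {
    stop("kcat/Km values must be non-negative and non-missing")
  }
  out <- numeric(length(value))
  zero <- value == 0
  out[zero] <- zero_score
  if (any(!zero)) {
    lx <- as.numeric(names(anchors))
    # rule = 2 clamps below the bottom and above the top anchor
    out[!zero] <- stats::approx(lx, unname(anchors), xout = log10(value[!zero]),
                                rule = 2)$y
  }
  out
}

#' Pseudo-kcat/Km from a relative-activity screen
#'
#' Within one substrate screen where substrate B has an independently
#' measured kcat/Km, the pseudo-kcat/Km of substrate A is estimated as
#' `(rel_a / rel_b)^2 * kcat_km_b`. The squared activity ratio reflects the
#' (crude) assumption that catalytic efficiency changes faster than linearly
#' with relative activity.
#'
#' @param rel_a Relative activity of substrate A, percent.
#' @param rel_b Relative activity of the reference substrate B, percent;
#'   must be > 0.
#' @param kcat_km_b Measured kcat/Km of substrate B, M^-1 s^-1.
#' @return Pseudo-kcat/Km of substrate A, M^-1 s^-1.
#' @export
#' @examples
#' pseudo_kcat_km(50, 100, 1e6)  # 2.5e5
pseudo_kcat_km <- function(rel_a, rel_b, kcat_km_b) {
  if (any(rel_b <= 0)) stop("reference relative activity must be > 0")
  if (any(rel_a < 0) || any(kcat_km_b < 0)) {
    stop("relative activity and kcat/Km must be non-negative")
  }
  (rel_a / rel_b)^2 * kcat_km_b
}

#' Score a relative-activity measurement
#'
#' Screening data with no associated kcat/Km are scored linearly from 0 (at
#' 0% relative activity) to the table's maximum (default 0.1, at 100%).
#' Values above 100% (a screen whose best substrate was redefined mid-way)
#' are clamped to 100 with a warning.
#'
#' @param rel Relative activity in percent.
#' @inheritParams score_kinetic
#' @return Numeric score(s).
#' @export
score_relative_activity <- function(rel, table = score_table()) {
  if (any(is.na(rel)) || any(rel < 0)) {
    stop("relative activity must be non-negative and non-missing")
  }
  if (any(rel > 100)) {
    warning("relative activity > 100% clamped to 100")
    rel <- pmin(rel, 100)
  }
  table$relative_activity_max_score * rel / 100
}

evidence_subtypes <- function() {
  list(
    genetic = c("knockout_predicted", "knockout_related",
                "knockout_inexplicable", "rescue"),
    biochemical = c("kcat_km", "pseudo_kcat_km", "relative_activity",
                    "gel_rare_substrate", "gel_hplc_common", "xray_binding",
                    "xray_substrate", "positive_activity")
  )
}

valued_subtypes <- function() c("kcat_km", "pseudo_kcat_km", "relative_activity")

#' Construct a table of evidence records
#'
#' Builds and validates a data frame of experimental evidence records, each
#' one observation tied to a protein-function pair. Quantitative subtypes
#' (`kcat_km`, `pseudo_kcat_km` in M^-1 s^-1; `relative_activity` in
#' percent) require a value; all other subtypes must have `value = NA`.
#'
#' @param protein_id,function_id Character identifiers.
#' @param category `"genetic"` or `"biochemical"`.
#' @param subtype One of the evidence subtypes (see Details).
#' @param value Numeric value for quantitative subtypes, `NA` otherwise.
#' @param source_ref Optional free-text provenance.
#'
#' @details Genetic subtypes: `knockout_predicted`, `knockout_related`,
#'   `knockout_inexplicable`, `rescue`. Biochemical subtypes: `kcat_km`,
#'   `pseudo_kcat_km`, `relative_activity`, `gel_rare_substrate`,
#'   `gel_hplc_common`, `xray_binding`, `xray_substrate`,
#'   `positive_activity`.
#' @return A data frame with class `evidence_table`.
#' @export
evidence_records <- function(protein_id, function_id, category, subtype,
                             value = NA_real_, source_ref = NA_character_) {
  n <- length(protein_id)
  df <- data.frame(protein_id = as.character(protein_id),
                   function_id = as.character(function_id),
                   category = as.character(category),
                   subtype = as.character(subtype),
                   value = rep_len(as.numeric(value), n),
                   source_ref = rep_len(as.character(source_ref), n),
                   stringsAsFactors = FALSE)
  validate_evidence(df)
  class(df) <- c("evidence_table", "data.frame")
  df
}

validate_evidence <- function(df) {
  msg <- evidence_row_problems(df)
  if (any(!is.na(msg))) {
    bad <- which(!is.na(msg))
    stop("invalid evidence rows: ",
         paste(sprintf("row %d (%s)", bad, msg[bad]), collapse = "; "))
  }
  invisible(df)
}

# per-row problem description, NA where the row is well-formed
evidence_row_problems <- function(df) {
  st <- evidence_subtypes()
  msg <- rep(NA_character_, nrow(df))
  ok_cat <- df$category %in% names(st)
  msg[!ok_cat] <- "unknown category"
  for (cat in names(st)) {
    sel <- ok_cat & df$category == cat & !(df$subtype %in% st[[cat]])
    msg[sel] <- paste0("subtype not valid for category ", cat)
  }
  need_val <- df$subtype %in% valued_subtypes()
  sel <- is.na(msg) & need_val & (is.na(df$value) | df$value < 0)
  msg[sel] <- "quantitative subtype requires a non-negative value"
  sel <- is.na(msg) & !need_val & !is.na(df$value)
  msg[sel] <- "qualitative subtype must not carry a value"
  sel <- is.na(msg) & df$subtype == "relative_activity" & df$value < 0
  msg[sel] <- "relative activity outside [0, 100]"
  msg
}

#' Score a single evidence record
#'
#' Dispatches one record to the appropriate scorer: kinetic interpolation
#' for `kcat_km`, the pseudo-kinetic anchors for `pseudo_kcat_km`, the
#' linear scale for `relative_activity`, and direct table lookup for genetic
#' and qualitative subtypes.
#'
#' @param subtype Evidence subtype string.
#' @param value Numeric value (ignored for qualitative subtypes).
#' @inheritParams score_kinetic
#' @return A score in \[0, 1\].
#' @export
score_record <- function(subtype, value = NA_real_, table = score_table()) {
  switch(subtype,
    kcat_km = score_kinetic(value, table),
    pseudo_kcat_km = score_pseudo_kinetic(value, table),
    relative_activity = score_relative_activity(value, table),
    {
      sc <- c(table$genetic_scores, table$qualitative_scores)[subtype]
      if (is.na(sc)) stop("unknown evidence subtype: ", subtype)
      unname(sc)
    })
}

#' Score one evidence category for one annotation
#'
#' Scores every record and returns the maximum: within each category
#' (genetic or biochemical) the strongest single piece of evidence sets the
#' category score.
#'
#' @param records An evidence table (all rows for one protein-function pair
#'   and one category).
#' @inheritParams score_kinetic
#' @return The maximum per-record score; a category with no records is
#'   handled upstream as score 0.
#' @export
score_category <- function(records, table = score_table()) {
  if (nrow(records) == 0L) stop("score_category requires at least one record")
  if (length(unique(records$category)) != 1L) {
    stop("score_category records must share one category")
  }
  max(vapply(seq_len(nrow(records)), function(i) {
    score_record(records$subtype[i], records$value[i], table)
  }, numeric(1)))
}

#' Combine genetic and biochemical category scores
#'
#' The overall confidence for an annotation is the noisy-OR combination
#' `1 - (1 - s_genetic) * (1 - s_biochem)`, reflecting the independence of
#' physiological and biochemical measurements. A missing category
#' contributes 0, so the overall score reduces to the other category's
#' score.
#'
#' @param s_genetic,s_biochem Scores in \[0, 1\]. Vectorised.
#' @return Overall score(s) in \[0, 1\].
#' @export
combine_overall <- function(s_genetic, s_biochem) {
  if (any(s_genetic < 0 | s_genetic > 1) || any(s_biochem < 0 | s_biochem > 1)) {
    stop("category scores must lie in [0, 1]")
  }
  1 - (1 - s_genetic) * (1 - s_biochem)
}

#' Adjust overall scores across all functions of one protein
#'
#' When a protein has been assayed against many substrates, an outlier
#' function with a high overall score becomes more convincing. Each overall
#' score S is converted to a Z-score against the mean and standard deviation
#' of the protein's full set of overall scores, and then adjusted:
#' `1 - (1 - S) / (1 + |Z|)` for Z > 0, `S / (1 + |Z|)` for Z < 0, and S
#' unchanged for Z = 0. If the standard deviation is 0 (all scores equal, or
#' a single annotation) every Z is defined as 0 and scores pass through.
#'
#' The adjustment is monotone in S, so the rank order of a protein's
#' functions is preserved.
#'
#' @param overall_scores Numeric vector of overall scores for all functions
#'   of one protein.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`.
#' @return A data frame with columns `s_overall`, `z_score`, `s_final`, one
#'   row per input score, in input order.
#' @export
#' @examples
#' adjust_final(c(0.9, 0.1, 0.1, 0.1))
adjust_final <- function(overall_scores, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  s <- overall_scores
  if (length(s) == 0L) stop("adjust_final requires a non-empty score list")
  n <- length(s)
  m <- mean(s)
  sdev <- if (n == 1L) 0 else {
    ss <- stats::sd(s)                      # sample SD
    if (sd_type == "population") ss * sqrt((n - 1) / n) else ss
  }
  z <- if (sdev == 0 || is.na(sdev)) rep(0, n) else (s - m) / sdev
  sf <- ifelse(z > 0, 1 - (1 - s) / (1 + abs(z)),
        ifelse(z < 0, s / (1 + abs(z)), s))
  data.frame(s_overall = s, z_score = z, s_final = sf)
}

#' Score a full evidence table
#'
#' The scoring pipeline: groups records by (protein, function); takes the
#' maximum per-record score within each evidence category ([score_category()]);
#' combines categories with the noisy-OR ([combine_overall()], a missing
#' category contributing 0); and applies the per-protein Z-score adjustment
#' ([adjust_final()]) across all functions of each protein. Malformed rows
#' are reported on standard error with their row number and skipped.
#'
#' @param records An evidence table (see [evidence_records()] /
#'   [read_evidence_tsv()]).
#' @inheritParams score_kinetic
#' @return A data frame with one row per (protein, function) pair, columns
#'   `protein_id`, `function_id`, `s_genetic`, `s_biochem`, `s_overall`,
#'   `z_score`, `s_final`, `n_records`, sorted by protein then function id
#'   (lexicographic, C locale).
#' @export
score_dataset <- function(records, table = score_table()) {
  empty <- data.frame(protein_id = character(), function_id = character(),
                      s_genetic = numeric(), s_biochem = numeric(),
                      s_overall = numeric(), z_score = numeric(),
                      s_final = numeric(), n_records = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)

  probs <- evidence_row_problems(records)
  if (any(!is.na(probs))) {
    for (i in which(!is.na(probs))) {
      message(sprintf("score_dataset: skipping row %d: %s", i, probs[i]))
    }
    records <- records[is.na(probs), , drop = FALSE]
  }
  if (nrow(records) == 0L) return(empty)

  # relative activities above 100% are clamped (once, with a warning)
  over <- records$subtype == "relative_activity" & records$value > 100
  if (any(over, na.rm = TRUE)) {
    warning(sum(over, na.rm = TRUE),
            " relative-activity record(s) > 100% clamped to 100")
    records$value[which(over)] <- 100
  }

  key <- paste(records$protein_id, records$function_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)

  ann <- do.call(rbind, lapply(groups, function(idx) {
    rec <- records[idx, , drop = FALSE]
    sg <- if (any(rec$category == "genetic")) {
      score_category(rec[rec$category == "genetic", , drop = FALSE], table)
    } else 0
    sb <- if (any(rec$category == "biochemical")) {
      score_category(rec[rec$category == "biochemical", , drop = FALSE], table)
    } else 0
    data.frame(protein_id = rec$protein_id[1], function_id = rec$function_id[1],
               s_genetic = sg, s_biochem = sb,
               s_overall = combine_overall(sg, sb),
               n_records = nrow(rec), stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL

  # deterministic order: protein then function, byte-wise
  ord <- order(ann$protein_id, ann$function_id, method = "radix")
  ann <- ann[ord, , drop = FALSE]

  adj <- do.call(rbind, lapply(split(ann, ann$protein_id), function(block) {
    a <- adjust_final(block$s_overall, sd_type = table$sd_type)
    block$z_score <- a$z_score
    block$s_final <- a$s_final
    block
  }))
  ord <- order(adj$protein_id, adj$function_id, method = "radix")
  adj <- adj[ord, c("protein_id", "function_id", "s_genetic", "s_biochem",
                    "s_overall", "z_score", "s_final", "n_records")]
  rownames(adj) <- NULL
  adj
}

#' Read an evidence table from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `protein_id`,
#' `function_id`, `category`, `subtype`, `value`, `source_ref`; the value
#' field is empty for qualitative subtypes.
#'
#' @param path Path to the TSV file.
#' @return An evidence data frame (unvalidated; [score_dataset()] reports
#'   and skips malformed rows).
#' @export
read_evidence_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(protein_id = "character",
                                         function_id = "character",
                                         category = "character",
                                         subtype = "character",
                                         value = "numeric",
                                         source_ref = "character"),
                          na.strings = c("NA", ""), encoding = "UTF-8")
  need <- c("protein_id", "function_id", "category", "subtype", "value",
            "source_ref")
  if (!all(need %in% names(df))) {
    stop("evidence TSV must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Write scored annotations to TSV
#'
#' Scores are printed to 4 decimals; identifiers verbatim.
#'
#' @param scored Output of [score_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scored, path) {
  out <- scored
  for (col in c("s_genetic", "s_biochem", "s_overall", "z_score", "s_final")) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
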