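#' Evidence score table
#'
#' Bundles every per-evidence scoring constant used by the confidence-score
#' model into a single configuration object, so that all constants can be
#' overridden without code changes (programmatically here, or from a YAML
#' file via [read_score_config()]).
#'
#' The defaults encode the consolidated assignment table of the model:
#' kcat/Km anchors at 10^3..10^7 M^-1 s^-1 mapping to scores
#' 0.1, 0.2, 0.5, 0.85, 0.99 (zero activity 0.01); pseudo-kcat/Km anchors
#' mapping to 0.05, 0.1, 0.25, 0.5, 0.7 (zero 0.01); genetic phenotype
#' scores (predicted 0.99, related 0.7, inexplicable 0.1, cross-species
#' rescue 0.5); qualitative biochemical scores (gel electrophoresis for rare
#' substrates 0.5, gel/HPLC for common substrates 0.05, X-ray structure with
#' substrate for a binding reaction 0.5, X-ray structure with substrate
#' 0.01, bare positive-activity data 0.01); and a maximum score of 0.1 for
#' 100% relative activity in a substrate screen.
#'
#' @param kinetic_anchors Named numeric vector mapping log10(kcat/Km) anchor
#'   points (as names) to scores.
#' @param kinetic_zero_score Score for kcat/Km = 0 (no detectable activity).
#' @param pseudo_anchors Named numeric vector of anchors for pseudo-kcat/Km.
#' @param pseudo_zero_score Score for pseudo-kcat/Km = 0.
#' @param genetic_scores Named numeric vector over the genetic subtypes
#'   `knockout_predicted`, `knockout_related`, `knockout_inexplicable`,
#'   `rescue`.
#' @param qualitative_scores Named numeric vector over the qualitative
#'   biochemical subtypes `gel_rare_substrate`, `gel_hplc_common`,
#'   `xray_binding`, `xray_substrate`, `positive_activity`.
#' @param relative_activity_max_score Score assigned to 100% relative
#'   activity; lower percentages scale linearly through zero.
#' @param sd_type Standard deviation used in the per-protein Z-score
#'   adjustment: `"population"` (divide by n, the default) or `"sample"`.
#'
#' @return An object of class `score_table` (a validated list).
#' @seealso [score_kinetic()], [score_dataset()], [read_score_config()]
#' @export
#' @examples
#' tab <- score_table()
#' score_kinetic(5e6, tab)   # 0.948 to 3 decimals
#' score_table(genetic_scores = c(rescue = 0.7))  # stricter rescue score
score_table <- function(kinetic_anchors = NULL,
                        kinetic_zero_score = 0.01,
                        pseudo_anchors = NULL,
                        pseudo_zero_score = 0.01,
                        genetic_scores = NULL,
                        qualitative_scores = NULL,
                        relative_activity_max_score = 0.1,
                        sd_type = c("population", "sample")) {
  def_kin <- c("3" = 0.1, "4" = 0.2, "5" = 0.5, "6" = 0.85, "7" = 0.99)
  def_pse <- c("3" = 0.05, "4" = 0.1, "5" = 0.25, "6" = 0.5, "7" = 0.7)
  def_gen <- c(knockout_predicted = 0.99, knockout_related = 0.7,
               knockout_inexplicable = 0.1, rescue = 0.5)
  def_qual <- c(gel_rare_substrate = 0.5, gel_hplc_common = 0.05,
                xray_binding = 0.5, xray_substrate = 0.01,
                positive_activity = 0.01)

  tab <- list(
    kinetic_anchors = merge_named(def_kin, kinetic_anchors),
    kinetic_zero_score = kinetic_zero_score,
    pseudo_anchors = merge_named(def_pse, pseudo_anchors),
    pseudo_zero_score = pseudo_zero_score,
    genetic_scores = merge_named(def_gen, genetic_scores),
    qualitative_scores = merge_named(def_qual, qualitative_scores),
    relative_activity_max_score = relative_activity_max_score,
    sd_type = match.arg(sd_type)
  )
  validate_score_table(tab)
  structure(tab, class = "score_table")
}

# override defaults entry-wise; unknown names are rejected by the validator
merge_named <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  stopifnot(!is.null(names(override)))
  bad <- setdiff(names(override), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown score table entries: ", paste(bad, collapse = ", "))
  }
  defaults[names(override)] <- override
  defaults
}

validate_score_table <- function(tab) {
  all_scores <- c(tab$kinetic_anchors, tab$kinetic_zero_score,
                  tab$pseudo_anchors, tab$pseudo_zero_score,
                  tab$genetic_scores, tab$qualitative_scores,
                  tab$relative_activity_max_score)
  if (any(all_scores < 0 | all_scores > 1)) {
    stop("all scores must lie in [0, 1]")
  }
  for (anc in list(tab$kinetic_anchors, tab$pseudo_anchors)) {
    lx <- as.numeric(names(anc))
    if (anyNA(lx) || is.unsorted(lx, strictly = TRUE)) {
      stop("anchor names must be strictly increasing log10 values")
    }
    if (is.unsorted(anc, strictly = TRUE)) {
      stop("anchor scores must be strictly increasing with log10 value")
    }
  }
  invisible(tab)
}

#' @export
print.score_table <- function(x, ...) {
  cat("Evidence score table\n")
  cat("  kcat/Km anchors (log10 -> score): ",
      paste(names(x$kinetic_anchors), x$kinetic_anchors, sep = "->",
            collapse = ", "),
      "; zero -> ", x$kinetic_zero_score, "\n", sep = "")
  cat("  pseudo anchors (log10 -> score): ",
      paste(names(x$pseudo_anchors), x$pseudo_anchors, sep = "->",
            collapse = ", "),
      "; zero -> ", x$pseudo_zero_score, "\n", sep = "")
  cat("  genetic: ",
      paste(names(x$genetic_scores), x$genetic_scores, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  qualitative: ",
      paste(names(x$qualitative_scores), x$qualitative_scores, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  relative activity max score: ", x$relative_activity_max_score,
      "; SD type: ", x$sd_type, "\n", sep = "")
  invisible(x)
}

#' Read a score-table configuration from a YAML file
#'
#' The file may contain any subset of the keys `kinetic_anchors`,
#' `kinetic_zero_score`, `pseudo_anchors`, `pseudo_zero_score`,
#' `genetic_scores`, `qualitative_scores`, `relative_activity_max_score`,
#' `sd_type`; anchor/score maps are given as YAML mappings. Keys not present
#' keep their defaults. Every applied override is reported on standard
#' error.
#'
#' @param path Path to a YAML configuration file.
#' @return A `score_table`.
#' @export
read_score_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("kinetic_anchors", "kinetic_zero_score", "pseudo_anchors",
             "pseudo_zero_score", "genetic_scores", "qualitative_scores",
             "relative_activity_max_score", "sd_type")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  for (key in names(cfg)) {
    message("score config override: ", key, " = ",
            paste(names(cfg[[key]]), cfg[[key]], sep = "->", collapse = ", "))
  }
  do.call(score_table, cfg)
}
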