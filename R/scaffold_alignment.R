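#' Read / write an aligned FASTA file
#'
#' Alignments are handled as named character vectors of equal-length
#' aligned residue strings over the amino-acid alphabet plus the gap
#' character `-`. Record order is preserved.
#'
#' @param path FASTA path.
#' @return Named character vector (an alignment).
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  aln <- as.character(x)
  names(aln) <- sub("\\s.*$", "", names(x))  # id = first token of header
  check_alignment(aln)
  aln
}

#' @rdname read_alignment_fasta
#' @param aln Alignment (named character vector of equal-length rows).
#' @export
write_alignment_fasta <- function(aln, path) {
  check_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), path)
  invisible(path)
}

check_alignment <- function(aln) {
  if (length(aln) == 0L) stop("alignment has no sequences")
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    stop("alignment rows must have unique sequence ids")
  }
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows must all have equal length")
  }
  invisible(aln)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# map each subgroup column to a scaffold column index (0 = insert column),
# by walking the residue-bearing columns of the scaffold rows in order
scaffold_column_map <- function(scaffold, subgroup) {
  ids <- names(scaffold)
  missing <- setdiff(ids, names(subgroup))
  if (length(missing) > 0L) {
    stop("subgroup is missing scaffold sequence(s): ",
         paste(missing, collapse = ", "))
  }
  for (id in ids) {
    if (!identical(degap(scaffold[[id]]), degap(subgroup[[id]]))) {
      stop("ungapped scaffold sequence differs in subgroup: ", id)
    }
  }
  smat <- do.call(rbind, strsplit(unname(scaffold[ids]), ""))
  gmat <- do.call(rbind, strsplit(unname(subgroup[ids]), ""))
  s_gapfree <- colSums(smat != "-") > 0
  if (!all(s_gapfree)) {
    stop("scaffold alignment contains all-gap column(s); ",
         "column correspondence would be ambiguous")
  }
  g_has_res <- colSums(gmat != "-") > 0
  map <- integer(ncol(gmat))
  nxt <- 1L
  for (j in seq_len(ncol(gmat))) {
    if (!g_has_res[j]) next  # insert column (all-gap across scaffold rows)
    if (nxt > ncol(smat) || !identical(gmat[, j], smat[, nxt])) {
      stop("subgroup columns do not embed the scaffold columns in order ",
           "(at subgroup column ", j, ")")
    }
    map[j] <- nxt
    nxt <- nxt + 1L
  }
  if (nxt != ncol(smat) + 1L) {
    stop("subgroup does not contain every scaffold column")
  }
  map
}

#' Merge subgroup alignments on a shared scaffold alignment
#'
#' Combines several subgroup alignments that all contain a common core
#' (scaffold) alignment into one alignment, using the scaffold's columns as
#' the correspondence guide. Columns homologous to a scaffold column are
#' merged across subgroups; columns unique to one subgroup (inserts) appear
#' as a contiguous block at the corresponding scaffold position, gap-padded
#' in all rows from other subgroups — regions unique to a subgroup are not
#' aligned between subgroups. When several subgroups insert at the same
#' scaffold position, their blocks appear in subgroup input order.
#'
#' Every row's ungapped sequence is preserved exactly; scaffold sequences
#' appear once in the output (first, in scaffold order), followed by each
#' subgroup's own sequences in input order.
#'
#' @param scaffold The core alignment shared by all subgroups.
#' @param subgroups List of subgroup alignments; each must contain every
#'   scaffold sequence id with an identical ungapped sequence. Non-scaffold
#'   ids must not repeat across subgroups.
#' @return The combined alignment (named character vector).
#' @export
merge_on_scaffold <- function(scaffold, subgroups) {
  check_alignment(scaffold)
  if (!is.list(subgroups)) subgroups <- list(subgroups)
  lapply(subgroups, check_alignment)
  sids <- names(scaffold)
  extra <- lapply(subgroups, function(g) setdiff(names(g), sids))
  dup <- unlist(extra)[duplicated(unlist(extra))]
  if (length(dup) > 0L) {
    stop("sequence id(s) present in more than one subgroup: ",
         paste(unique(dup), collapse = ", "))
  }

  n_scol <- nchar(scaffold[[1L]])
  maps <- lapply(subgroups, function(g) scaffold_column_map(scaffold, g))
  gmats <- lapply(subgroups, function(g) {
    do.call(rbind, strsplit(unname(g), ""))
  })
  smat <- do.call(rbind, strsplit(unname(scaffold), ""))

  out_ids <- c(sids, unlist(extra))
  n_out <- length(out_ids)
  row_of <- stats::setNames(seq_len(n_out), out_ids)

  # assemble output column blocks slot by slot: inserts before scaffold
  # column k+1 live in slot k (slot 0 = leading inserts)
  blocks <- list()
  for (slot in 0:n_scol) {
    for (gi in seq_along(subgroups)) {
      map <- maps[[gi]]
      cols <- insert_cols_in_slot(map, slot)
      if (length(cols) == 0L) next
      blk <- matrix("-", nrow = n_out, ncol = length(cols))
      blk[row_of[names(subgroups[[gi]])], ] <- gmats[[gi]][, cols, drop = FALSE]
      blocks[[length(blocks) + 1L]] <- blk
    }
    if (slot < n_scol) {
      k <- slot + 1L
      col <- matrix("-", nrow = n_out, ncol = 1L)
      col[row_of[sids], 1L] <- smat[, k]
      for (gi in seq_along(subgroups)) {
        j <- which(maps[[gi]] == k)
        col[row_of[names(subgroups[[gi]])], 1L] <- gmats[[gi]][, j]
      }
      blocks[[length(blocks) + 1L]] <- col
    }
  }
  outmat <- do.call(cbind, blocks)
  out <- apply(outmat, 1L, paste, collapse = "")
  names(out) <- out_ids
  out
}

# subgroup insert columns falling between scaffold columns slot and slot+1
insert_cols_in_slot <- function(map, slot) {
  ins <- which(map == 0L)
  if (length(ins) == 0L) return(integer(0))
  match_pos <- which(map > 0L)
  # for each insert column, the scaffold column immediately preceding it
  prev_match <- vapply(ins, function(j) {
    before <- match_pos[match_pos < j]
    if (length(before) == 0L) 0L else map[max(before)]
  }, integer(1))
  ins[prev_match == slot]
}

#' Build a regular expression for a compact motif pattern
#'
#' Expands a compact motif notation into a regular expression over the
#' amino-acid alphabet: plain letters match themselves, `X` matches any
#' residue, `Xn` (e.g. `X5`) matches n arbitrary residues, and `U` matches
#' one residue from `u_set` (default the bulky aliphatic residues L, I, V).
#' The canonical Nudix box, `GX5EX7REUXEEXGU`, expands to a 23-position
#' pattern.
#'
#' @param motif Compact motif string; default the canonical Nudix box.
#' @param u_set Residues matched by `U`.
#' @return List with elements `regex` (the anchored-nowhere regex) and
#'   `width` (the fixed match width in residues).
#' @export
motif_pattern <- function(motif = "GX5EX7REUXEEXGU", u_set = c("L", "I", "V")) {
  toks <- regmatches(motif, gregexpr("X[0-9]+|X|U|[A-Z]", motif))[[1L]]
  if (paste(toks, collapse = "") != motif) stop("cannot parse motif: ", motif)
  u_cls <- paste0("[", paste(u_set, collapse = ""), "]")
  parts <- vapply(toks, function(t) {
    if (t == "X") "." else if (grepl("^X[0-9]+$", t)) {
      paste0(".{", substring(t, 2L), "}")
    } else if (t == "U") u_cls else t
  }, character(1))
  width <- sum(vapply(toks, function(t) {
    if (grepl("^X[0-9]+$", t)) as.integer(substring(t, 2L)) else 1L
  }, integer(1)))
  list(regex = paste(parts, collapse = ""), width = width)
}

#' Scan a sequence for the Nudix box motif
#'
#' Finds all (possibly overlapping) matches of the ~23-residue Nudix box
#' motif — by default `GX5EX7REUXEEXGU`, the loop-helix-loop signature of
#' Nudix pyrophosphohydrolases, with `U` a bulky aliphatic residue (L, I, V)
#' and `X` any amino acid. Gap characters are removed before scanning;
#' coordinates are 1-based, inclusive, in ungapped residue space.
#'
#' @param sequence A residue string (one protein sequence; gaps allowed and
#'   ignored).
#' @param pattern A [motif_pattern()] (or a compact motif string).
#' @param sequence_id Id recorded in the output.
#' @return Data frame of motif hits: `sequence_id`, `start`, `end`,
#'   `match`, `pattern_name` (zero rows when there is no hit).
#' @export
#' @examples
#' scan_nudix_box("GAAAAAEAAAAAAARELAEEAGL")
scan_nudix_box <- function(sequence, pattern = motif_pattern(),
                           sequence_id = "seq") {
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  seq0 <- degap(toupper(sequence))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYBJOUXZ*]", seq0)) {
    stop("sequence contains non-residue characters")
  }
  hits <- data.frame(sequence_id = character(), start = integer(),
                     end = integer(), match = character(),
                     pattern_name = character(), stringsAsFactors = FALSE)
  if (nchar(seq0) < pattern$width) return(hits)
  # lookahead finds overlapping matches; each match has fixed width
  starts <- gregexpr(paste0("(?=", pattern$regex, ")"), seq0, perl = TRUE)[[1L]]
  if (starts[1L] == -1L) return(hits)
  starts <- as.integer(starts)
  name <- if (identical(pattern$regex, motif_pattern()$regex)) {
    "nudix_box_canonical"
  } else "custom"
  data.frame(sequence_id = sequence_id, start = starts,
             end = starts + pattern$width - 1L,
             match = substring(seq0, starts, starts + pattern$width - 1L),
             pattern_name = name, stringsAsFactors = FALSE)
}

#' Scan every sequence of a FASTA/alignment for the Nudix box
#'
#' @param sequences Named character vector of sequences (gaps allowed).
#' @inheritParams scan_nudix_box
#' @return Combined hit data frame across sequences.
#' @export
scan_nudix_box_many <- function(sequences, pattern = motif_pattern()) {
  do.call(rbind, lapply(names(sequences), function(id) {
    scan_nudix_box(sequences[[id]], pattern, sequence_id = id)
  }))
}

#' Locate the X-loop window downstream of a Nudix box hit
#'
#' The X-loop — the substrate-specificity loop that contacts the variable
#' "X" moiety of Nudix hydrolase substrates — sits approximately 17 residues
#' downstream of the Nudix box. Given a motif hit, this returns the window
#' starting `offset` residues after the motif end, of the requested length,
#' truncated at the sequence end and clamped to the configured length
#' bounds (loops of 2–19 residues are observed; 5–10 is typical, and 10 is
#' the default reported length when the true boundary is unknown).
#'
#' @param sequence Residue string the hit refers to (gaps allowed).
#' @param motif_hit One row of [scan_nudix_box()] output (or a list with
#'   `end`).
#' @param offset Residues between motif end and window start; default 17.
#' @param length Requested window length; default 10.
#' @param length_bounds Allowed window lengths, inclusive; default `c(2, 19)`.
#' @return A list with `sequence_id`, `start`, `end`, `length`, `window`
#'   (the residue string) and `truncated`; or `NULL` (a no-window result)
#'   when fewer than `length_bounds[1]` residues remain after the offset.
#' @export
#' @examples
#' seq <- paste(rep("A", 160), collapse = "")
#' locate_xloop(seq, list(sequence_id = "p", end = 119))  # window 137-146
locate_xloop <- function(sequence, motif_hit, offset = 17L, length = 10L,
                         length_bounds = c(2L, 19L)) {
  seq0 <- degap(toupper(sequence))
  n <- nchar(seq0)
  end_hit <- as.integer(motif_hit$end)
  if (end_hit < 1L || end_hit > n) stop("motif hit does not fit the sequence")
  length <- min(max(as.integer(length), length_bounds[1L]), length_bounds[2L])
  start <- end_hit + as.integer(offset) + 1L
  avail <- n - start + 1L
  if (avail < length_bounds[1L]) return(NULL)
  len <- min(length, avail)
  list(sequence_id = motif_hit$sequence_id %||% NA_character_,
       start = start, end = start + len - 1L, length = len,
       window = substring(seq0, start, start + len - 1L),
       truncated = avail < length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map an ungapped residue position to an alignment column
#'
#' Motif and X-loop coordinates are reported in ungapped residue space;
#' this converts them to 1-based column indices of an aligned row.
#'
#' @param aligned_row One aligned sequence (with gaps).
#' @param pos Ungapped residue position(s), 1-based.
#' @return Column index/indices.
#' @export
ungapped_to_column <- function(aligned_row, pos) {
  chars <- strsplit(aligned_row, "")[[1L]]
  res_cols <- which(chars != "-")
  if (any(pos < 1L | pos > length(res_cols))) {
    stop("ungapped position out of range")
  }
  res_cols[pos]
}
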