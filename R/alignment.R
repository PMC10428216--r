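#' Read a multiple sequence alignment
#'
#' Parses FASTA or Clustal alignments into a validated MSA object. All
#' aligned sequences must have equal length and unique ids; the input
#' order is preserved.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`; `"auto"` guesses from the first
#'   non-blank line.
#' @return An object of class `msa`: list with `ids` and `seqs` (aligned
#'   sequences, gap character `-`).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop_field("path", "no FASTA records found")
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      lo <- bounds[i] + 1L; hi <- bounds[i + 1L] - 1L
      body <- if (hi >= lo) lines[lo:hi] else character(0)
      gsub("\\s", "", paste(body, collapse = ""))
    }, "")
  } else {
    body <- lines[!grepl("^(CLUSTAL|MUSCLE)", lines, ignore.case = TRUE)]
    body <- body[nzchar(trimws(body))]
    # drop conservation lines (only symbols ' ', '*', ':', '.')
    body <- body[grepl("^\\S+\\s+\\S", body)]
    toks <- regmatches(body, regexec("^(\\S+)\\s+([-A-Za-z.]+)", body))
    toks <- toks[vapply(toks, length, 0L) == 3L]
    if (!length(toks)) stop_field("path", "no Clustal alignment rows found")
    ids_all <- vapply(toks, `[[`, "", 2L)
    seq_all <- vapply(toks, `[[`, "", 3L)
    ids <- unique(ids_all)
    seqs <- vapply(ids, function(id) paste(seq_all[ids_all == id], collapse = ""), "")
  }
  new_msa(ids, unname(seqs))
}

#' @rdname read_alignment
#' @param ids Sequence identifiers (unique).
#' @param seqs Aligned sequences of equal length.
#' @export
new_msa <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (anyDuplicated(ids)) {
    stop_field("ids", paste("duplicate sequence id:", ids[duplicated(ids)][1]))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- ids[lens != lens[1]][1]
    rlang::abort(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                         off, nchar(seqs[ids == off]), lens[1]),
                 class = "kinoflex_format_error")
  }
  structure(list(ids = ids, seqs = seqs), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences, aligned length %d\n",
              length(x$ids), nchar(x$seqs[1])))
  invisible(x)
}

#' Write an MSA as aligned FASTA
#'
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  out <- character(0)
  for (i in seq_along(msa$ids)) out <- c(out, paste0(">", msa$ids[i]), msa$seqs[i])
  writeLines(out, path)
  invisible(path)
}

#' Map alignment columns to per-kinase residue ids
#'
#' For each kinase, the j-th non-gap character of its aligned sequence
#' corresponds to the j-th entry of its residue-id list, which must match
#' in length. The panel-wide retained columns are those with no gap in any
#' sequence, so every retained column resolves to exactly one residue in
#' every kinase.
#'
#' @param msa An `msa` object.
#' @param residue_ids Named list (one entry per MSA sequence id) of ordered
#'   residue-id integer vectors, typically the `residue_id` column of each
#'   kinase's RMSF profile.
#' @return An object of class `alignment_map`: tibble `map` with columns
#'   `kinase`, `column`, `residue_id` (retained columns only) and vector
#'   `retained_columns`.
#' @export
build_column_map <- function(msa, residue_ids) {
  if (!inherits(msa, "msa")) stop_field("msa", "must be an msa object")
  missing <- setdiff(msa$ids, names(residue_ids))
  if (length(missing)) {
    stop_field("residue_ids", paste("no residue list for:", paste(missing, collapse = ", ")))
  }
  chars <- lapply(msa$seqs, function(s) strsplit(s, "")[[1]])
  L <- length(chars[[1]])
  gap_free <- Reduce(`&`, lapply(chars, function(cc) cc != "-"))
  retained <- which(gap_free)
  rows <- purrr::map_dfr(seq_along(msa$ids), function(i) {
    id <- msa$ids[i]
    ung <- which(chars[[i]] != "-")
    rid <- residue_ids[[id]]
    if (length(ung) != length(rid)) {
      rlang::abort(sprintf(
        "correspondence error for '%s': %d ungapped alignment positions vs %d residues",
        id, length(ung), length(rid)), class = "kinoflex_format_error")
    }
    if (any(diff(rid) <= 0)) {
      stop_field("residue_ids", sprintf("residue ids of '%s' must be strictly increasing", id))
    }
    pos <- match(retained, ung)
    tibble::tibble(kinase = id, column = retained, residue_id = rid[pos])
  })
  structure(list(map = rows, retained_columns = retained, n_columns = L),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %d kinases, %d of %d columns retained\n",
              length(unique(x$map$kinase)), length(x$retained_columns), x$n_columns))
  invisible(x)
}

#' Assemble the kinases-by-columns fluctuation matrix
#'
#' Places each kinase's per-residue RMSF values into the retained alignment
#' columns: the value at (kinase, column) is that kinase's RMSF at the
#' mapped residue id. The result is complete by construction; any
#' unresolvable (kinase, column) pairs are reported together in one error.
#'
#' @param profiles Named list of RMSF profiles (tibbles with `residue_id`,
#'   `rmsf`), one per kinase in the map.
#' @param map An `alignment_map` from [build_column_map()].
#' @param labels Named character vector of `active`/`inactive` labels, one
#'   per kinase.
#' @return A `fluct_panel` tibble (`kinase`, `label`, and one `c<column>`
#'   column per retained alignment column), rows in map order.
#' @export
assemble_matrix <- function(profiles, map, labels) {
  if (!inherits(map, "alignment_map")) stop_field("map", "must be an alignment_map")
  kinases <- unique(map$map$kinase)
  missing <- setdiff(kinases, names(profiles))
  if (length(missing)) {
    stop_field("profiles", paste("missing profiles for:", paste(missing, collapse = ", ")))
  }
  labels <- check_labels(labels[kinases], "labels")
  failures <- character(0)
  mat <- matrix(NA_real_, length(kinases), length(map$retained_columns),
                dimnames = list(kinases, paste0("c", map$retained_columns)))
  for (k in kinases) {
    sub <- map$map[map$map$kinase == k, ]
    prof <- profiles[[k]]
    hit <- match(sub$residue_id, prof$residue_id)
    bad <- is.na(hit)
    if (any(bad)) {
      failures <- c(failures, sprintf("%s: column %d (residue %d)",
                                      k, sub$column[bad], sub$residue_id[bad]))
      next
    }
    mat[k, paste0("c", sub$column)] <- prof$rmsf[hit]
  }
  if (length(failures)) {
    rlang::abort(paste0("unresolvable (kinase, column) pairs:\n  ",
                        paste(failures, collapse = "\n  ")),
                 class = "kinoflex_assembly_error")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(kinase = kinases, label = labels),
    tibble::as_tibble(as.data.frame(mat))
  )
  structure(out, class = c("fluct_panel", class(out)))
}

#' Activity label from a per-frame activity-probability series
#'
#' A kinase is labelled active when its mean per-frame activity probability
#' reaches the cut (default 0.5), i.e. it spends at least half the
#' trajectory in conformations classified as active.
#'
#' @param series Numeric vector of per-frame activity probabilities in
#'   `[0, 1]`.
#' @param cut Threshold on the mean activity (default 0.5).
#' @return `"active"` or `"inactive"`.
#' @export
#' @examples
#' label_from_activity(rep(0.177, 100)) # "inactive"
label_from_activity <- function(series, cut = 0.5) {
  if (!length(series)) stop_field("series", "must be non-empty")
  if (anyNA(series) || any(series < 0) || any(series > 1)) {
    stop_field("series", "activity probabilities must lie in [0, 1]")
  }
  check_prob(cut, "cut")
  if (mean(series) >= cut) "active" else "inactive"
}

#' Read a per-frame activity series CSV
#'
#' Expects columns `frame` and `activity` (probability in `[0, 1]`).
#'
#' @param path CSV path.
#' @return Numeric vector of activities ordered by frame.
#' @export
read_activity_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("frame", "activity") %in% names(tab))) {
    stop_field("path", "CSV must have columns frame, activity")
  }
  tab$activity[order(tab$frame)]
}
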