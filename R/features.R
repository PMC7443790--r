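# Assembly of named feature matrices and the degenerate-feature filter.

#' Full linguistic feature vector for one transcript
#'
#' Amount-of-speech statistics (words per sentence: min, max, mean, sample
#' sd), semantic-coherence statistics over consecutive-sentence cosines
#' (min, max, mean, sample sd) and part-of-speech tag relative frequencies
#' (prefixed \code{pos_}).  The punctuation-free \code{pos_other} bucket is
#' retained so frequencies sum to 1 but is typically constant and removed by
#' the degenerate-feature filter.
#'
#' @param t a \code{transcript} with >= 2 sentences.
#' @param space a \code{semantic_space} for the coherence features.
#' @param tagset tagset passed to \code{pos_tag_frequencies}.
#' @return named numeric vector with attribute \code{subject_id}.
#' @export
linguistic_features <- function(t, space, tagset = ptb_tagset()) {
  sl <- sentence_length_stats(t)
  co <- coherence_stats(coherence_series(t, space))
  pf <- pos_tag_frequencies(t, tagset)
  names(pf) <- paste0("pos_", names(pf))
  out <- c(sl, co, pf)
  attr(out, "subject_id") <- t$subject_id
  out
}

#' Stack per-subject feature vectors into a named feature matrix
#'
#' @param vectors list of named numeric vectors carrying a
#'   \code{subject_id} attribute (as from \code{linguistic_features}).
#' @param provenance block label ("language", "clinical", "connectivity",
#'   "morphometry").
#' @return numeric matrix, rows = subjects in input order (rownames =
#'   subject ids), columns = features in the order of the first vector;
#'   attribute \code{provenance} set, raw (not z-scored) state.
#' @export
assemble_feature_matrix <- function(vectors, provenance = "language") {
  if (length(vectors) < 2)
    err("insufficient_subjects", "need at least 2 subjects")
  ids <- unname(vapply(vectors, function(v)
    as.character(attr(v, "subject_id") %||% NA_character_), character(1)))
  if (anyNA(ids)) err("inconsistent_feature_sets", "vectors lack subject_id")
  if (anyDuplicated(ids))
    err("duplicate_subject", paste0("duplicate subject id(s): ",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  feats <- names(vectors[[1]])
  same <- vapply(vectors, function(v) identical(names(v), feats), logical(1))
  if (!all(same))
    err("inconsistent_feature_sets",
        "all subjects must share an identical feature name set")
  m <- do.call(rbind, lapply(vectors, as.numeric))
  dimnames(m) <- list(ids, feats)
  attr(m, "provenance") <- provenance
  m
}

#' @rdname assemble_feature_matrix
#' @export
assemble_linguistic_matrix <- function(vectors) {
  assemble_feature_matrix(vectors, provenance = "language")
}

#' Drop features on which the cohort is (nearly) degenerate
#'
#' A feature is dropped when the proportion of subjects sharing its modal
#' value strictly exceeds \code{threshold} — the rule used to exclude
#' features on which more than half the sample achieved the same score.
#' A modal proportion exactly equal to the threshold is retained.
#'
#' @param m raw feature matrix (subjects x features).
#' @param threshold proportion in (0, 1); default 0.5.
#' @return list: \code{matrix} (retained columns, original order) and
#'   \code{dropped} (character vector of dropped feature names).
#' @export
drop_degenerate_features <- function(m, threshold = 0.5) {
  m <- as.matrix(m)
  if (isTRUE(attr(m, "zscored")))
    err("zstate_error", "degenerate filter must run on the raw matrix")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    err("config_error", "threshold must lie strictly between 0 and 1")
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  mode_prop <- apply(m, 2, function(col) max(table(col)) / length(col))
  drop <- mode_prop > threshold
  if (all(drop))
    err("all_features_dropped",
        "every feature is degenerate at this threshold")
  out <- m[, !drop, drop = FALSE]
  attr(out, "provenance") <- attr(m, "provenance")
  list(matrix = out, dropped = colnames(m)[drop])
}

#' Write a feature matrix as TSV (subject_id first column)
#' @param m feature matrix with rownames.
#' @param path output file.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(subject_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param provenance block label attached to the matrix read back.
#' @export
read_feature_matrix <- function(path, provenance = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    err("config_error", "feature matrix TSV must start with a subject_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$subject_id)
  attr(m, "provenance") <- provenance
  m
}
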