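# Transcript ingestion and sentence segmentation.
#
# Transcripts are assumed pre-filtered to participant speech; an optional
# speaker-prefix filter handles interleaved interviewer/participant lines.

# periods inside these never end a sentence
ABBREVIATIONS <- c("mr.", "mrs.", "ms.", "dr.", "prof.", "st.", "jr.", "sr.",
                   "e.g.", "i.e.", "etc.", "vs.", "a.m.", "p.m.", "u.s.",
                   "no.", "approx.")

#' Segment raw text into a transcript of tokenized sentences
#'
#' Sentences are split on runs of terminal punctuation (\code{. ! ?}), so an
#' ellipsis acts as a single boundary; periods in a small abbreviation guard
#' list and inside decimal numbers do not split.  Tokens are whitespace
#' fields with punctuation stripped from the edges; original casing is
#' retained (part-of-speech tagging is case-sensitive; semantic analysis
#' lowercases on its own).
#'
#' @param raw_text character scalar, the full transcript.
#' @param subject_id identifier carried through the pipeline.
#' @param keep_speaker optional speaker prefix (e.g. \code{"P"}): lines
#'   beginning \code{"<letter>:"} with a different letter are dropped and the
#'   kept prefix is stripped.  Off (NULL) by default.
#' @return object of class \code{"transcript"}: subject_id, sentences (list
#'   of character vectors), raw_text.
#' @export
segment_sentences <- function(raw_text, subject_id = "subject",
                              keep_speaker = NULL) {
  if (!is.character(raw_text) || length(raw_text) != 1 || is.na(raw_text))
    err("empty_transcript", "raw_text must be a single character string")
  txt <- raw_text
  if (!is.null(keep_speaker)) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    tagged <- grepl("^\\s*[A-Za-z]{1,3}:", lines)
    keep <- !tagged | grepl(paste0("^\\s*", keep_speaker, ":"), lines)
    lines <- lines[keep]
    lines <- sub(paste0("^\\s*", keep_speaker, ":\\s*"), "", lines)
    txt <- paste(lines, collapse = "\n")
  }
  if (!nzchar(trimws(txt)))
    err("empty_transcript", paste0("transcript '", subject_id, "' is empty"))
  # protect abbreviation and decimal periods (word-boundary anchored)
  for (ab in ABBREVIATIONS) {
    variants <- unique(c(ab,
                         paste0(toupper(substr(ab, 1, 1)), substring(ab, 2)),
                         toupper(ab)))
    for (v in variants) {
      pat <- paste0("(^|\\s)", gsub(".", "\\.", v, fixed = TRUE))
      txt <- gsub(pat, paste0("\\1", gsub(".", "\x01", v, fixed = TRUE)), txt)
    }
  }
  txt <- gsub("([0-9])\\.([0-9])", "\\1\x01\\2", txt)
  pieces <- strsplit(txt, "[.!?]+")[[1]]
  pieces <- gsub("\x01", ".", pieces, fixed = TRUE)
  sentences <- lapply(pieces, function(p) {
    toks <- strsplit(trimws(p), "\\s+")[[1]]
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
    toks[nzchar(toks)]
  })
  sentences <- sentences[lengths(sentences) > 0]
  if (length(sentences) == 0)
    err("empty_transcript",
        paste0("no sentence with at least one token in '", subject_id, "'"))
  structure(list(subject_id = subject_id, sentences = sentences,
                 raw_text = raw_text),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript '%s': %d sentences, %d tokens>\n",
              x$subject_id, length(x$sentences), sum(lengths(x$sentences))))
  invisible(x)
}

#' Read a directory of transcript files or a two-column manifest
#'
#' @param path directory of UTF-8 \code{.txt} files (file stem = subject id)
#'   or a TSV with columns \code{subject_id}, \code{path}.
#' @param ... passed to \code{segment_sentences}.
#' @return named list of \code{transcript} objects.
#' @export
read_transcripts <- function(path, ...) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    ids <- sub("\\.txt$", "", basename(files))
  } else {
    man <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "path") %in% names(man)))
      err("config_error", "transcript manifest needs subject_id and path columns")
    files <- man$path
    ids <- as.character(man$subject_id)
  }
  if (length(files) == 0) err("empty_transcript", "no transcript files found")
  out <- Map(function(f, id) {
    segment_sentences(paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                            collapse = "\n"),
                      subject_id = id, ...)
  }, files, ids)
  names(out) <- ids
  out
}

#' Sentence-length statistics (amount of speech)
#'
#' Minimum, maximum, mean and sample standard deviation (denominator n - 1;
#' 0 for a single sentence) of the number of words per sentence.
#'
#' @param t a \code{transcript}.
#' @return named numeric: sentlen_min, sentlen_max, sentlen_mean, sentlen_sd.
#' @export
sentence_length_stats <- function(t) {
  stopifnot(inherits(t, "transcript"))
  n <- lengths(t$sentences)
  if (length(n) == 0) err("empty_transcript", "transcript has no sentences")
  stat_quad(n, "sentlen")
}
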