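# Latent semantic analysis over a term-passage matrix.
#
# A passage is a sentence; the weighted count matrix is decomposed by
# truncated SVD and word vectors are the left singular vectors scaled by the
# singular values.  Semantic coherence of a transcript is the cosine
# similarity between mean word vectors of consecutive sentences.

#' Build a semantic space from a transcript corpus
#'
#' Constructs the term-passage (sentence) count matrix over lowercased
#' tokens, applies the chosen weighting and takes a rank-k truncated SVD.
#' The default log-entropy weighting multiplies \eqn{\log(1 + tf)} by one
#' minus the normalized entropy of the term's distribution over passages, so
#' terms spread evenly across passages (little semantic information) are
#' down-weighted.
#'
#' @param corpus list of \code{transcript} objects (the background corpus;
#'   by convention the analysis corpus itself).
#' @param k target dimension (>= 2); reduced with a warning when the matrix
#'   has fewer nonzero singular values.
#' @param weighting one of \code{"log_entropy"}, \code{"tfidf"}, \code{"tf"}.
#' @return object of class \code{"semantic_space"}: vocabulary (named index
#'   vector), vectors (|V| x k matrix, rownames = tokens), k, weighting.
#' @export
build_semantic_space <- function(corpus, k = 50,
                                 weighting = c("log_entropy", "tfidf", "tf")) {
  weighting <- match.arg(weighting)
  if (inherits(corpus, "transcript")) corpus <- list(corpus)
  stopifnot(all(vapply(corpus, inherits, logical(1), "transcript")))
  if (!is_count(k) || k < 2) err("vocabulary_too_small", "k must be an integer >= 2")
  passages <- unlist(lapply(corpus, function(t)
    lapply(t$sentences, tolower)), recursive = FALSE)
  vocab <- sort(unique(unlist(passages)))
  if (length(vocab) < k)
    err("vocabulary_too_small",
        sprintf("vocabulary (%d tokens) smaller than k = %d", length(vocab), k))
  tp <- matrix(0, nrow = length(vocab), ncol = length(passages),
               dimnames = list(vocab, NULL))
  for (j in seq_along(passages)) {
    tab <- table(passages[[j]])
    tp[names(tab), j] <- tp[names(tab), j] + as.numeric(tab)
  }
  w <- switch(weighting,
    tf = tp,
    tfidf = {
      df <- rowSums(tp > 0)
      tp * log(ncol(tp) / df)
    },
    log_entropy = {
      gf <- rowSums(tp)
      p <- tp / gf
      plogp <- ifelse(p > 0, p * log(p), 0)
      entropy <- -rowSums(plogp)
      gw <- 1 - entropy / log(max(ncol(tp), 2))
      log(1 + tp) * gw
    })
  sv <- svd(w)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < k) {
    warn("rank_deficient",
         sprintf("only %d nonzero singular values; reducing k from %d", rank, k))
    k <- rank
  }
  vectors <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(vectors) <- vocab
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 vectors = vectors, k = k, weighting = weighting),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic space: %d tokens, k = %d, %s weighting>\n",
              length(x$vocabulary), x$k, x$weighting))
  invisible(x)
}

#' Persist / restore a semantic space as plain text
#'
#' A directory with the vocabulary list, the vector matrix (TSV) and a JSON
#' manifest (k, weighting, content hash) so coherence features are
#' reproducible across runs.
#' @param space a \code{semantic_space}.
#' @param dir target directory (created).
#' @export
write_semantic_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(names(space$vocabulary), file.path(dir, "vocabulary.txt"))
  utils::write.table(space$vectors, file.path(dir, "vectors.tsv"),
                     sep = "\t", col.names = FALSE, row.names = FALSE)
  hash <- sum(abs(space$vectors)) # cheap content fingerprint
  jsonlite::write_json(list(k = space$k, weighting = space$weighting,
                            n_tokens = length(space$vocabulary),
                            checksum = signif(hash, 12)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_semantic_space
#' @export
read_semantic_space <- function(dir) {
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  vectors <- as.matrix(utils::read.table(file.path(dir, "vectors.tsv"),
                                         sep = "\t"))
  dimnames(vectors) <- list(vocab, NULL)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 vectors = vectors, k = man$k, weighting = man$weighting),
            class = "semantic_space")
}

#' Mean word vector of a sentence
#'
#' Arithmetic mean of the vectors of in-vocabulary (lowercased) tokens; a
#' sentence with no in-vocabulary token maps to the zero vector with
#' attribute \code{oov = TRUE} so downstream coherence can skip it.
#'
#' @param tokens character vector of tokens.
#' @param space a \code{semantic_space}.
#' @export
sentence_vector <- function(tokens, space) {
  stopifnot(inherits(space, "semantic_space"))
  idx <- space$vocabulary[tolower(tokens)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    v <- numeric(space$k)
    attr(v, "oov") <- TRUE
    return(v)
  }
  colMeans(space$vectors[idx, , drop = FALSE])
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Semantic coherence series of a transcript
#'
#' Cosine similarity between mean word vectors of consecutive sentences.
#' Pairs in which either sentence has a zero vector (all tokens out of
#' vocabulary) are skipped and counted in attribute \code{n_skipped}.
#'
#' @param t a \code{transcript} with >= 2 sentences.
#' @param space a \code{semantic_space}.
#' @return numeric vector of cosines in [-1, 1], length
#'   (#sentences - 1) - #skipped.
#' @export
coherence_series <- function(t, space) {
  stopifnot(inherits(t, "transcript"))
  if (length(t$sentences) < 2)
    err("empty_transcript", "coherence needs at least 2 sentences")
  vecs <- lapply(t$sentences, sentence_vector, space = space)
  vals <- vapply(seq_len(length(vecs) - 1), function(i)
    cosine(vecs[[i]], vecs[[i + 1]]), numeric(1))
  skipped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    err("all_pairs_skipped",
        paste0("every consecutive sentence pair of '", t$subject_id,
               "' had an out-of-vocabulary side"))
  attr(vals, "n_skipped") <- skipped
  vals
}

#' Summary statistics of a coherence series
#'
#' @param series numeric vector from \code{coherence_series}.
#' @return named numeric: coh_min, coh_max, coh_mean, coh_sd (sample sd,
#'   0 for a length-1 series).
#' @export
coherence_stats <- function(series) {
  if (length(series) < 1)
    err("all_pairs_skipped", "empty coherence series")
  stat_quad(as.numeric(series), "coh")
}
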