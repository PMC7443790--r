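# shared fixture builders (everything generated in code, no data files)

# transcript from a list of token vectors, bypassing segmentation
make_transcript <- function(sentences, id = "t1") {
  structure(list(subject_id = id, sentences = sentences,
                 raw_text = paste(vapply(sentences, paste, "",
                                         collapse = " "), collapse = ". ")),
            class = "transcript")
}

# semantic space with hand-chosen vectors, for closed-form coherence cases
make_space <- function(vectors) {
  structure(list(vocabulary = stats::setNames(seq_len(nrow(vectors)),
                                              rownames(vectors)),
                 vectors = vectors, k = ncol(vectors),
                 weighting = "tf"),
            class = "semantic_space")
}

# panel from a node x timepoint matrix
make_panel <- function(series, id = "s1") {
  timeseries_panel(id, series)
}

small_atlas <- function(nodes_per_network = 3) {
  default_atlas(nodes_per_network)
}

zs <- function(m) zscore_block(as.matrix(m))

# brute-force cohesiveness: naive double loop over node pairs
cohesiveness_oracle <- function(series, nodes) {
  zsum <- 0; np <- 0
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    r <- stats::cor(series[nodes[i], ], series[nodes[j], ])
    zsum <- zsum + atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
    np <- np + 1
  }
  zsum / np
}
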