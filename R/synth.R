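# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of (parameters, seed).  Transcripts are
# sampled from part-of-speech templated grammars over a topic-partitioned
# vocabulary drawn from the tagger's own lexicon, so tag ground truth is
# exact; feature blocks carry planted sparse canonical modes; time-series
# panels follow per-network one-factor models calibrated to target
# correlations; morphometry tables follow the default schema.

lexicon_words <- function(tag) names(.lexicon)[.lexicon == tag]

# sentence templates by part-of-speech; "V" slots resolve to topic verbs
.templates <- list(
  declarative  = c("PRP", "VBD", "DT", "JJ", "NN", "IN", "DT", "NN"),
  question     = c("WRB", "VBD", "PRP", "VB", "DT", "NN"),
  fragment     = c("DT", "JJ", "NN"),
  conjunctive  = c("PRP", "VBD", "DT", "NN", "CC", "PRP", "VBD", "DT", "NN"),
  subordinate  = c("IN", "PRP", "VBD", "DT", "NN", "PRP", "VBD", "RB"),
  interjection = c("UH", "PRP", "VBP", "RB", "JJ")
)
# syntactically complex templates (moved by the complexity setting)
.complex_templates <- c("conjunctive", "subordinate")

#' Generate synthetic interview transcripts
#'
#' Sentences are sampled from six part-of-speech templates (declarative,
#' question, fragment, conjunctive, subordinate, interjection-initial) over
#' a vocabulary partitioned into topics.  Consecutive sentences keep the
#' current topic with probability \code{1 - drift}, so low drift produces
#' semantically coherent transcripts; \code{complexity} weights the
#' conjunctive/subordinate templates, moving the coordinating-conjunction,
#' subordinating-conjunction and adverb tag frequencies.
#'
#' @param n_subjects number of transcripts.
#' @param settings list: \code{n_sentences} (default 50),
#'   \code{target_length} (mean words/sentence, default 8; sentences are
#'   padded with adjective-noun pairs toward a Poisson draw around it),
#'   \code{drift} in [0, 1] (scalar or per-subject, default 0.2),
#'   \code{complexity} in [0, 1] (scalar or per-subject, default 0.5),
#'   \code{n_topics} (default 4).
#' @param seed integer seed.
#' @return list: \code{transcripts} (named list of \code{transcript}),
#'   \code{truth} (data.frame of per-subject drift, complexity,
#'   mean sentence length realized).
#' @export
generate_transcripts <- function(n_subjects, settings = list(), seed = 1) {
  s <- utils::modifyList(list(n_sentences = 50, target_length = 8,
                              drift = 0.2, complexity = 0.5, n_topics = 4),
                         settings)
  if (s$n_sentences < 2 || s$target_length < 3 || s$n_topics < 2 ||
      any(s$drift < 0 | s$drift > 1) ||
      any(s$complexity < 0 | s$complexity > 1))
    err("invalid_settings", "transcript generator settings out of range")
  drift <- rep_len(s$drift, n_subjects)
  complexity <- rep_len(s$complexity, n_subjects)

  nouns <- lexicon_words("NN"); adjs <- lexicon_words("JJ")
  vbds <- setdiff(lexicon_words("VBD"),
                  c("was", "were", "had", "did"))
  topic_of <- function(words) split(words, rep_len(seq_len(s$n_topics),
                                                   length(words)))
  tn <- topic_of(nouns); ta <- topic_of(adjs); tv <- topic_of(vbds)
  fill <- list(PRP = c("i", "he", "she", "we", "they"),
               DT = c("the", "a", "this", "that"),
               IN = c("in", "on", "with", "because", "although", "after"),
               CC = c("and", "but", "or"),
               WRB = c("when", "where", "why", "how"),
               UH = c("oh", "um", "well", "yeah", "hmm")[-3],
               RB = c("really", "quite", "often", "slowly", "again"),
               VBP = c("feel", "think", "seem"),
               VB = c("go", "see", "find", "remember"))

  withr::with_seed(seed, {
    out <- vector("list", n_subjects)
    ids <- sprintf("sub%03d", seq_len(n_subjects))
    realized <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      w_complex <- 0.1 + 0.8 * complexity[i]
      tw <- stats::setNames(rep(1, length(.templates)), names(.templates))
      tw[.complex_templates] <- 1 + 6 * w_complex
      tw <- tw / sum(tw)
      # mean template length under these weights, so padding centres the
      # realized sentence length on the target
      etmpl <- sum(tw * lengths(.templates))
      extra <- max(0, s$target_length - etmpl)
      topic <- sample.int(s$n_topics, 1)
      sents <- character(s$n_sentences)
      for (j in seq_len(s$n_sentences)) {
        if (j > 1 && stats::runif(1) < drift[i])
          topic <- sample.int(s$n_topics, 1)
        tmpl <- .templates[[sample(names(.templates), 1, prob = tw)]]
        toks <- vapply(tmpl, function(tag) {
          pool <- switch(tag,
                         NN = tn[[topic]], JJ = ta[[topic]],
                         VBD = tv[[topic]], fill[[tag]])
          sample(pool, 1)
        }, character(1), USE.NAMES = FALSE)
        # pad with adjective/noun filler only, one token at a time, so
        # padding does not move the conjunction/preposition frequencies
        # that complexity controls
        want <- length(toks) + stats::rpois(1, extra)
        while (length(toks) < want) {
          pool <- if (length(toks) %% 2) tn[[topic]] else ta[[topic]]
          toks <- c(toks, sample(pool, 1))
        }
        sents[j] <- paste(toks, collapse = " ")
      }
      out[[i]] <- segment_sentences(paste0(sents, ".", collapse = " "),
                                    subject_id = ids[i])
      realized[i] <- mean(lengths(out[[i]]$sentences))
    }
    names(out) <- ids
    list(transcripts = out,
         truth = data.frame(subject_id = ids, drift = drift,
                            complexity = complexity,
                            mean_sentlen = realized,
                            stringsAsFactors = FALSE))
  })
}

#' Two feature blocks sharing a planted sparse canonical mode
#'
#' A latent subject score s drives block X through a sparse unit weight
#' vector w_x, and a correlated score \eqn{t = \rho s + \sqrt{1-\rho^2} e}
#' drives Y through w_y.  Noise is standard normal projected orthogonally to
#' the planted weight within each block, so \eqn{\rho} is exactly the
#' population canonical correlation of the planted mode.  Optional batch
#' location/scale effects and a group mean shift are applied afterwards.
#'
#' @param n subjects (>= 10).
#' @param p1,p2 features per block.
#' @param truth optional list overriding any of: \code{support1},
#'   \code{support2} (index vectors, default first 10), \code{rho}
#'   (default 0.7), \code{batch} (list: \code{labels}, \code{shift},
#'   \code{scale}, applied to Y), \code{group} (list: \code{labels},
#'   \code{effect}, mean shift along w_x for the second level).
#' @param seed integer seed.
#' @return list \code{x}, \code{y}, \code{truth} (with unit \code{w_x},
#'   \code{w_y}, supports, rho, latent scores, batch/group settings).
#' @export
generate_linked_blocks <- function(n, p1 = 100, p2 = 100, truth = list(),
                                   seed = 1) {
  if (n < 10) err("dimension_error", "need n >= 10")
  tr <- utils::modifyList(list(support1 = seq_len(min(10, p1)),
                               support2 = seq_len(min(10, p2)),
                               rho = 0.7, batch = NULL, group = NULL),
                          truth)
  if (max(tr$support1) > p1 || max(tr$support2) > p2)
    err("dimension_error", "support outside block dimensions")
  if (tr$rho < 0 || tr$rho >= 1)
    err("dimension_error", "rho must lie in [0, 1)")
  w_x <- numeric(p1); w_x[tr$support1] <- 1 / sqrt(length(tr$support1))
  w_y <- numeric(p2); w_y[tr$support2] <- 1 / sqrt(length(tr$support2))
  withr::with_seed(seed, {
    s <- stats::rnorm(n)
    t <- tr$rho * s + sqrt(1 - tr$rho^2) * stats::rnorm(n)
    ortho_noise <- function(p, w) {
      E <- matrix(stats::rnorm(n * p), n, p)
      E - (E %*% w) %*% t(w)
    }
    X <- s %*% t(w_x) + ortho_noise(p1, w_x)
    Y <- t %*% t(w_y) + ortho_noise(p2, w_y)
    colnames(X) <- paste0("x", seq_len(p1))
    colnames(Y) <- paste0("y", seq_len(p2))
    if (!is.null(tr$group)) {
      g2 <- tr$group$labels == unique(tr$group$labels)[2]
      X[g2, ] <- X[g2, ] + tr$group$effect * rep(w_x, each = sum(g2))
    }
    if (!is.null(tr$batch)) {
      lab <- factor(tr$batch$labels)
      shift <- rep_len(tr$batch$shift, nlevels(lab))
      scale <- rep_len(tr$batch$scale %||% 1, nlevels(lab))
      for (b in seq_len(nlevels(lab))) {
        rows <- lab == levels(lab)[b]
        Y[rows, ] <- Y[rows, ] * scale[b] + shift[b]
      }
    }
    tr$w_x <- w_x; tr$w_y <- w_y; tr$s <- s; tr$t <- t; tr$seed <- seed
    list(x = X, y = Y, truth = tr)
  })
}

#' One-factor time-series panels calibrated to target correlations
#'
#' Node series within a network share a network factor so the expected
#' within-network node-pair correlation equals \code{within_r}; network
#' factors share a hub factor calibrated so the correlation between the hub
#' and each other network's node-average series is approximately
#' \code{between_r}.
#'
#' @param n_subjects number of panels.
#' @param atlas a \code{network_atlas}.
#' @param within_r target within-network pair correlation, in [0, 1).
#' @param between_r target hub-to-network mean-series correlation,
#'   0 <= between_r <= within_r (0 forced when within_r = 0).
#' @param T timepoints (>= 50).
#' @param seed integer seed.
#' @return named list of \code{timeseries_panel}, with attribute
#'   \code{truth} (the calibrated factor loadings).
#' @export
generate_timeseries_panels <- function(n_subjects, atlas, within_r = 0.5,
                                       between_r = 0.2, T = 200, seed = 1) {
  stopifnot(inherits(atlas, "network_atlas"))
  if (T < 50) err("invalid_correlation_spec", "need T >= 50")
  if (any(between_r < 0) || any(within_r < 0) || any(within_r >= 1) ||
      any(between_r > within_r))
    err("invalid_correlation_spec",
        "need 0 <= between_r <= within_r < 1")
  within_r <- rep_len(within_r, n_subjects)
  nets <- names(atlas$networks)
  hub <- atlas$hub
  withr::with_seed(seed, {
    panels <- vector("list", n_subjects)
    ids <- sprintf("sub%03d", seq_len(n_subjects))
    b_used <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      a <- within_r[i]
      if (a > 0) {
        nh <- length(atlas$networks[[hub]])
        navg <- mean(lengths(atlas$networks))
        m_var <- a + (1 - a) / navg
        b <- min(0.999, between_r * sqrt((a + (1 - a) / nh) * m_var) / a)
      } else b <- 0
      b_used[i] <- b
      g <- stats::rnorm(T)
      rows <- list()
      for (nm in nets) {
        f <- if (nm == hub) g else b * g + sqrt(1 - b^2) * stats::rnorm(T)
        nodes <- atlas$networks[[nm]]
        sig <- matrix(stats::rnorm(length(nodes) * T), length(nodes), T)
        sig <- sqrt(a) * matrix(f, length(nodes), T, byrow = TRUE) +
          sqrt(1 - a) * sig
        rownames(sig) <- nodes
        rows[[nm]] <- sig
      }
      panels[[i]] <- timeseries_panel(ids[i], do.call(rbind, rows))
    }
    names(panels) <- ids
    attr(panels, "truth") <- list(within_r = within_r,
                                  between_r = between_r, b = b_used, T = T)
    panels
  })
}

#' Synthetic morphometry table with plausible scales
#'
#' Cortical thickness around 2.5 mm and structure-specific subcortical
#' volumes, per-feature Gaussian variation truncated well above zero.  An
#' optional latent score plants covariation on chosen features.
#'
#' @param n_subjects rows.
#' @param schema feature/role table (default \code{morphometry_schema()}).
#' @param effects optional list: \code{latent} (length-n score),
#'   \code{features} (names to load), \code{loading} (in per-feature sd
#'   units, default 1).
#' @param seed integer seed.
#' @return feature matrix accepted by \code{read_morphometry_table}'s
#'   validation (all positive), provenance "morphometry".
#' @export
generate_morphometry <- function(n_subjects, schema = morphometry_schema(),
                                 effects = NULL, seed = 1) {
  vol_means <- c("Thalamus-Proper" = 7000, "Caudate" = 3500,
                 "Putamen" = 5000, "Pallidum" = 1800,
                 "Hippocampus" = 4000, "Amygdala" = 1600,
                 "Accumbens-area" = 600, "VentralDC" = 4000,
                 "Lateral-Ventricle" = 8000, "Cerebellum-Cortex" = 50000)
  mu <- vapply(seq_len(nrow(schema)), function(j) {
    if (schema$role[j] == "cortical_thickness") return(2.5)
    vol_means[sub("^(Left|Right)-", "", schema$feature[j])]
  }, numeric(1))
  sdv <- ifelse(schema$role == "cortical_thickness", 0.15, 0.08 * mu)
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_subjects * nrow(schema)), n_subjects) *
      rep(sdv, each = n_subjects) + rep(mu, each = n_subjects)
    colnames(m) <- schema$feature
    rownames(m) <- sprintf("sub%03d", seq_len(n_subjects))
    if (!is.null(effects)) {
      if (!all(effects$features %in% schema$feature))
        err("schema_violation", "effect features outside the schema")
      idx <- match(effects$features, schema$feature)
      load <- effects$loading %||% 1
      m[, idx] <- m[, idx] + outer(effects$latent, load * sdv[idx])
    }
    m <- pmax(m, matrix(0.05 * mu, n_subjects, nrow(schema), byrow = TRUE))
    attr(m, "provenance") <- "morphometry"
    m
  })
}

#' Write a complete synthetic study to disk
#'
#' Generates an aligned study — transcripts, time-series panels,
#' morphometry, metadata with diagnosis/site/handedness/clinical items —
#' in which a single latent subject score drives semantic coherence and
#' syntactic complexity of the transcripts, network cohesiveness, a sparse
#' set of morphometry features, and the clinical items, with site
#' location/scale effects on the imaging blocks.  The ground truth is
#' written as \code{truth.json}.
#'
#' @param dir output directory (created).
#' @param n_chr,n_hi group sizes (defaults 46 and 22).
#' @param rho latent cross-block correlation (default 0.7).
#' @param T timepoints per panel (default 150).
#' @param seed integer master seed.
#' @return (invisibly) the directory, with attribute \code{truth}.
#' @export
write_study_fixture <- function(dir, n_chr = 46, n_hi = 22, rho = 0.7,
                                T = 150, seed = 1) {
  n <- n_chr + n_hi
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)

  atlas <- default_atlas()
  withr::with_seed(derive_seed(seed, 10L), {
    s <- stats::rnorm(n)
    t_conn <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n)
    t_morph <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n)
    t_clin <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n)
    diagnosis <- c(rep("CHR", n_chr), rep("HI", n_hi))
    site <- sample(rep_len(c("siteA", "siteB"), n))
    handedness <- round(stats::runif(n, -1, 1), 2)
  })

  drift <- pmin(pmax(0.5 - 0.25 * s, 0.02), 0.98)
  complexity <- stats::plogis(0.9 * s)
  tg <- generate_transcripts(n, list(drift = drift, complexity = complexity),
                             seed = derive_seed(seed, 11L))
  for (id in names(tg$transcripts))
    writeLines(tg$transcripts[[id]]$raw_text,
               file.path(dir, "transcripts", paste0(id, ".txt")))

  within_r <- pmin(pmax(0.45 + 0.1 * t_conn, 0.05), 0.9)
  panels <- generate_timeseries_panels(n, atlas, within_r = within_r,
                                       between_r = 0.15, T = T,
                                       seed = derive_seed(seed, 12L))
  site_scale <- c(siteA = 1, siteB = 1.3)
  site_shift <- c(siteA = 0, siteB = 0.6)
  for (i in seq_len(n)) {
    p <- panels[[i]]
    ser <- p$series * site_scale[site[i]] + site_shift[site[i]]
    df <- data.frame(node = rownames(ser), ser, check.names = FALSE)
    utils::write.table(df, file.path(dir, "timeseries",
                                     paste0(names(panels)[i], ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  schema <- morphometry_schema()
  morph_feats <- schema$feature[c(17, 19, 29, 63, 45, 47, 69, 73, 79, 83)]
  morph <- generate_morphometry(n, schema,
                                effects = list(latent = t_morph,
                                               features = morph_feats,
                                               loading = 1),
                                seed = derive_seed(seed, 13L))
  msite <- morph
  msite[site == "siteB", ] <- msite[site == "siteB", ] * 1.05
  write_feature_matrix(msite, file.path(dir, "morphometry.tsv"))

  clin_items <- paste0("clin_", c("avolition", "emotion", "stress",
                                  "bizarre", "ideation"))
  clin <- withr::with_seed(derive_seed(seed, 14L),
    sapply(seq_along(clin_items), function(j)
      round(pmin(pmax(2 + 1.2 * t_clin + stats::rnorm(n, sd = 0.8), 0), 6))))
  colnames(clin) <- clin_items
  meta <- data.frame(subject_id = names(tg$transcripts),
                     diagnosis = diagnosis, site = site,
                     handedness = handedness, clin,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(networks = atlas$networks, hub = atlas$hub),
                       file.path(dir, "atlas.json"), auto_unbox = TRUE)

  truth <- list(seed = seed, rho = rho, latent = s,
                drift = drift, complexity = complexity,
                within_r = within_r,
                morph_features = morph_feats,
                clin_items = clin_items,
                site_scale = as.list(site_scale),
                site_shift = as.list(site_shift),
                # linguistic features the latent drives through the drift and
                # template-mix settings (|cor with latent| >= 0.3 on an
                # independent n = 300 calibration draw of the generator)
                language_features = c("coh_mean", "coh_min", "sentlen_sd",
                                      "sentlen_max", "pos_JJ", "pos_PRP",
                                      "pos_VBD", "pos_NN", "pos_CC",
                                      "pos_VBP", "pos_DT"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(dir, "truth") <- truth
  invisible(dir)
}

#' Default 6-network atlas used by the synthetic study
#'
#' LAN, DMN, ECN, SAL, SMN and AN with \code{nodes_per_network} synthetic
#' node ids each; hub = LAN.
#' @param nodes_per_network nodes per network (default 10).
#' @export
default_atlas <- function(nodes_per_network = 10) {
  nets <- c("LAN", "DMN", "ECN", "SAL", "SMN", "AN")
  network_atlas(stats::setNames(lapply(nets, function(nm)
    paste0(nm, "_", seq_len(nodes_per_network))), nets), hub = "LAN")
}
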