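# End-to-end study orchestration: transcripts -> linguistic features,
# panels -> connectivity, morphometry ingestion, site harmonization of the
# imaging blocks, and one sparse CCA per configured analysis.

#' Assemble a study configuration
#'
#' @param transcripts directory of .txt transcripts (or manifest TSV).
#' @param timeseries directory of per-subject node x timepoint TSVs.
#' @param morphometry morphometry TSV path.
#' @param metadata metadata TSV (subject_id, diagnosis, site, handedness,
#'   clinical items prefixed \code{clin_}).
#' @param atlas atlas JSON path or a \code{network_atlas}.
#' @param out_dir output directory for result JSON/TSV files (NULL: no
#'   files written).
#' @param semantic_k,semantic_weighting semantic-space settings.
#' @param drop_threshold degenerate-feature threshold.
#' @param harmonize logical; harmonize the imaging blocks by site.
#' @param n_perm,seed permutation count and master seed.
#' @param analyses list of per-analysis lists: \code{name}, \code{block_y}
#'   ("clinical", "connectivity" or "morphometry"), \code{subset} (optional
#'   diagnosis value, e.g. "CHR"), \code{append} (metadata columns appended
#'   to the language block, e.g. c("diagnosis", "handedness")).
#' @export
study_config <- function(transcripts, timeseries = NULL, morphometry = NULL,
                         metadata, atlas = NULL, out_dir = NULL,
                         semantic_k = 50, semantic_weighting = "log_entropy",
                         drop_threshold = 0.5, harmonize = TRUE,
                         n_perm = 10000, seed = 1,
                         analyses = default_analyses()) {
  cfg <- list(transcripts = transcripts, timeseries = timeseries,
              morphometry = morphometry, metadata = metadata, atlas = atlas,
              out_dir = out_dir, semantic_k = semantic_k,
              semantic_weighting = semantic_weighting,
              drop_threshold = drop_threshold, harmonize = harmonize,
              n_perm = n_perm, seed = seed, analyses = analyses)
  for (key in c("transcripts", "metadata")) {
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      err("config_error", paste0("config key '", key, "' missing or path absent"))
  }
  nm <- vapply(cfg$analyses, `[[`, character(1), "name")
  if (anyDuplicated(nm)) err("config_error", "analysis names must be unique")
  cfg
}

#' The three analyses of the standard study design
#'
#' Language against clinical symptoms within the clinical-high-risk group
#' only, and language (with diagnosis and handedness indicators appended)
#' against each imaging block in the whole sample.
#' @export
default_analyses <- function() {
  list(
    list(name = "language_clinical", block_y = "clinical", subset = "CHR",
         append = NULL),
    list(name = "language_connectivity", block_y = "connectivity",
         subset = NULL, append = c("diagnosis", "handedness")),
    list(name = "language_morphometry", block_y = "morphometry",
         subset = NULL, append = c("diagnosis", "handedness"))
  )
}

#' Read a study configuration from YAML
#' @param path YAML file with the \code{study_config} fields.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

log_line <- function(log, stage, msg) {
  c(log, paste0("[", stage, "] ", msg))
}

#' Run the full study
#'
#' Executes: linguistic feature extraction (segmentation, semantic space
#' built from the study corpus, coherence, tag frequencies), connectivity
#' and morphometry ingestion, site harmonization of the imaging blocks,
#' cohort-wide degenerate-feature filtering of the language block, then one
#' sparse CCA per configured analysis.  Subjects are inner-joined on id
#' across sources; every exclusion and filter decision is logged.
#'
#' @param config list from \code{study_config} (or a YAML path).
#' @return list of class \code{"study_result"}: per-analysis \code{scca}
#'   fits, feature blocks, exclusion log, manifest.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  log <- character(0)

  meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(meta))
    err("config_error", "metadata lacks subject_id")
  meta$subject_id <- as.character(meta$subject_id)
  if (isTRUE(config$harmonize) && !"site" %in% names(meta))
    err("config_error", "harmonization enabled but metadata lacks a 'site' column")

  transcripts <- read_transcripts(config$transcripts)
  space <- build_semantic_space(transcripts, k = config$semantic_k,
                                weighting = config$semantic_weighting)
  ling <- assemble_linguistic_matrix(
    lapply(transcripts, linguistic_features, space = space))
  log <- log_line(log, "lingfeat",
                  sprintf("%d transcripts, %d raw features", nrow(ling),
                          ncol(ling)))

  blocks <- list()
  if (!is.null(config$timeseries)) {
    atlas <- if (inherits(config$atlas, "network_atlas")) config$atlas
             else read_atlas(config$atlas)
    files <- sort(list.files(config$timeseries, pattern = "\\.tsv$",
                             full.names = TRUE))
    panels <- lapply(files, read_timeseries_panel)
    conn <- assemble_connectivity_matrix(
      lapply(panels, connectivity_vector, atlas = atlas))
    blocks$connectivity <- conn
    log <- log_line(log, "brainfeat",
                    sprintf("%d connectivity panels, %d measures",
                            nrow(conn), ncol(conn)))
  }
  if (!is.null(config$morphometry)) {
    blocks$morphometry <- read_morphometry_table(config$morphometry)
    log <- log_line(log, "brainfeat",
                    sprintf("%d morphometry rows", nrow(blocks$morphometry)))
  }
  clin_cols <- grep("^clin_", names(meta), value = TRUE)
  if (length(clin_cols) > 0) {
    clin <- as.matrix(meta[, clin_cols, drop = FALSE])
    rownames(clin) <- meta$subject_id
    attr(clin, "provenance") <- "clinical"
    blocks$clinical <- clin
  }

  # inner join on subject id across all sources
  ids <- Reduce(intersect, c(list(rownames(ling), meta$subject_id),
                             lapply(blocks, rownames)))
  all_ids <- unique(c(rownames(ling), meta$subject_id,
                      unlist(lapply(blocks, rownames))))
  for (ex in setdiff(all_ids, ids))
    log <- log_line(log, "join",
                    paste0("excluded '", ex, "': absent from some source"))
  ling <- ling[ids, , drop = FALSE]
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  blocks <- lapply(blocks, function(b) b[ids, , drop = FALSE])

  if (isTRUE(config$harmonize)) {
    for (bn in intersect(c("connectivity", "morphometry"), names(blocks))) {
      fit <- combat_fit(blocks[[bn]], batch = meta$site)
      blocks[[bn]] <- combat_apply(fit, blocks[[bn]], meta$site)
      log <- log_line(log, "harmonize",
                      sprintf("%s harmonized across %d sites", bn,
                              length(fit$batches)))
    }
  }

  # cohort-wide degenerate filter on the language block, before any analysis
  lf <- drop_degenerate_features(ling, threshold = config$drop_threshold)
  ling <- lf$matrix
  for (dn in lf$dropped)
    log <- log_line(log, "filter", paste0("dropped degenerate feature '",
                                          dn, "'"))

  results <- list()
  for (k in seq_along(config$analyses)) {
    an <- config$analyses[[k]]
    if (!an$block_y %in% names(blocks))
      err("config_error", paste0("analysis '", an$name, "' needs block '",
                                 an$block_y, "' which is not available"))
    keep <- rep(TRUE, length(ids))
    if (!is.null(an$subset)) {
      keep <- meta$diagnosis == an$subset
      log <- log_line(log, an$name,
                      sprintf("subset %s: %d of %d subjects", an$subset,
                              sum(keep), length(keep)))
    }
    x <- ling[keep, , drop = FALSE]
    add <- NULL
    if (!is.null(an$append)) {
      add <- sapply(an$append, function(cl) {
        v <- meta[[cl]][keep]
        if (cl == "diagnosis") as.numeric(v == "CHR") else as.numeric(v)
      })
      colnames(add) <- an$append
      log <- log_line(log, an$name,
                      paste0("appended indicator column(s): ",
                             paste(an$append, collapse = ", ")))
    }
    y <- blocks[[an$block_y]][keep, , drop = FALSE]
    attr(y, "zscored") <- NULL
    fit <- scca(x, y, n_perm = config$n_perm,
                seed = derive_seed(config$seed, k),
                drop_threshold = config$drop_threshold,
                append = add, analysis = an$name,
                allow_small = config$n_perm < 100)
    results[[an$name]] <- fit
    log <- log_line(log, an$name,
                    sprintf("mode 1 r = %.3f, p = %.4g", fit$modes[[1]]$r,
                            fit$modes[[1]]$p))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("speechscca")),
    seed = config$seed, n_perm = config$n_perm,
    n_subjects = length(ids),
    analyses = stats::setNames(lapply(results, function(f)
      list(n = f$n, r = f$modes[[1]]$r, p = f$modes[[1]]$p,
           c1 = f$modes[[1]]$c1, c2 = f$modes[[1]]$c2)), names(results)),
    semantic = list(k = space$k, weighting = space$weighting,
                    vocabulary = length(space$vocabulary)),
    dropped_language_features = lf$dropped)

  out <- structure(list(results = results, manifest = manifest,
                        log = log, subjects = ids),
                   class = "study_result")
  if (!is.null(config$out_dir)) write_study_result(out, config$out_dir)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study run:", x$manifest$n_subjects, "subjects,",
      length(x$results), "analyses\n")
  for (nm in names(x$results)) {
    m <- x$results[[nm]]$modes[[1]]
    cat(sprintf("  %s: r = %.3f, p = %s\n", nm, m$r,
                format(m$p, digits = 3)))
  }
  invisible(x)
}

#' Serialize study results (JSON per analysis, weight TSVs, manifest)
#' @param res a \code{study_result}.
#' @param dir output directory (created).
#' @export
write_study_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$results)) {
    f <- res$results[[nm]]
    ser <- list(analysis = nm, n = f$n, seed = f$seed,
                dropped = f$dropped,
                grid = list(c1 = f$grid$c1_grid, c2 = f$grid$c2_grid,
                            trace = as.data.frame(unname(f$grid$trace))),
                modes = lapply(f$modes, function(m)
                  list(r = m$r, c1 = m$c1, c2 = m$c2, p = m$p,
                       p_plus_one = m$p_plus_one,
                       u = as.list(m$u), v = as.list(m$v))))
    jsonlite::write_json(ser, file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    for (side in c("x", "y"))
      utils::write.table(report_weights(f, Inf, side = side),
                         file.path(dir, paste0(nm, "_weights_", side, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Features of a mode sorted by absolute weight
#'
#' @param result an \code{scca} fit.
#' @param top_k rows to keep (Inf: all).
#' @param side "x" or "y" weight vector.
#' @param mode which mode.
#' @return data.frame(feature, weight), |weight| descending, ties by name.
#' @export
report_weights <- function(result, top_k = 10, side = c("x", "y"), mode = 1) {
  side <- match.arg(side)
  w <- result$modes[[mode]][[if (side == "x") "u" else "v"]]
  ord <- order(-abs(w), names(w))
  w <- w[ord]
  k <- min(top_k, length(w))
  data.frame(feature = names(w)[seq_len(k)], weight = unname(w[seq_len(k)]),
             stringsAsFactors = FALSE)
}
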