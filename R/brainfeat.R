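# Resting-state network connectivity statistics and morphometry ingestion.
#
# Connectivity works on per-subject node x timepoint panels grouped by a
# 6-network atlas (LAN, DMN, ECN, SAL, SMN, AN).  Cohesiveness of a network
# is the mean Fisher-z correlation over all within-network node pairs;
# integration is the Fisher-z correlation between two networks' average
# time series.  With a hub network (LAN) paired against each of the other
# five, a 6-network atlas yields the 11 connectivity measures per subject.

#' Define a network atlas
#'
#' @param networks named list, network name -> character vector of node ids;
#'   >= 2 networks of >= 2 disjoint nodes each.
#' @param hub hub network for the integration measures (default "LAN").
#' @return object of class \code{"network_atlas"}.
#' @export
network_atlas <- function(networks, hub = "LAN") {
  if (!is.list(networks) || length(networks) < 2 || is.null(names(networks)))
    err("config_error", "atlas needs >= 2 named networks")
  if (any(lengths(networks) < 2))
    err("config_error", "every network needs >= 2 nodes")
  nodes <- unlist(networks, use.names = FALSE)
  if (anyDuplicated(nodes))
    err("config_error", "network node sets must be disjoint")
  if (!hub %in% names(networks))
    err("config_error", paste0("hub network '", hub, "' not in the atlas"))
  structure(list(networks = lapply(networks, as.character), hub = hub),
            class = "network_atlas")
}

#' Read an atlas from JSON ({"networks": {name: [nodes]}, "hub": "LAN"})
#' @param path JSON file.
#' @export
read_atlas <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  network_atlas(as.list(j$networks), hub = j$hub %||% "LAN")
}

#' A per-subject node x timepoint panel
#'
#' @param subject_id identifier.
#' @param series numeric matrix, rows = nodes (rownames = node ids),
#'   columns = timepoints (>= 8); all values finite.
#' @export
timeseries_panel <- function(subject_id, series) {
  series <- as.matrix(series)
  if (is.null(rownames(series)))
    err("config_error", "series needs node ids as rownames")
  if (ncol(series) < 8)
    err("config_error", "need at least 8 timepoints")
  if (!all(is.finite(series)))
    err("config_error", paste0("non-finite values in panel '", subject_id, "'"))
  structure(list(subject_id = subject_id, series = series,
                 T = ncol(series)),
            class = "timeseries_panel")
}

#' Read a panel from delimited text (rows = nodes, first column = node id)
#' @param path TSV file; stem used as subject id unless given.
#' @param subject_id optional id override.
#' @export
read_timeseries_panel <- function(path, subject_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  timeseries_panel(subject_id %||% sub("\\.[^.]*$", "", basename(path)), m)
}

#' Fisher z-transform of a correlation
#'
#' \eqn{z = atanh(r)} with r clipped to \eqn{\pm(1 - 10^{-7})} so perfectly
#' correlated (e.g. duplicated) series stay finite.
#'
#' @param r correlation(s), |r| <= 1 (tolerance 1e-12).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12))
    err("domain_error", "correlation outside [-1, 1]")
  eps <- 1e-7
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

check_node_variance <- function(series, nodes, subject_id) {
  v <- apply(series[nodes, , drop = FALSE], 1, stats::var)
  if (any(v < 1e-24)) {
    bad <- nodes[v < 1e-24]
    err("zero_variance_node",
        paste0("zero-variance node(s) in '", subject_id, "': ",
               paste(bad, collapse = ", ")))
  }
}

check_nodes_present <- function(p, nodes) {
  missing <- setdiff(nodes, rownames(p$series))
  if (length(missing) > 0)
    err("config_error", paste0("panel '", p$subject_id, "' lacks node(s): ",
                               paste(missing, collapse = ", ")))
}

#' Network cohesiveness
#'
#' Mean over all unordered within-network node pairs of the Fisher-z
#' transformed Pearson correlation of the two node time series.
#'
#' @param p a \code{timeseries_panel}.
#' @param nodes node ids of the network (>= 2).
#' @export
network_cohesiveness <- function(p, nodes) {
  stopifnot(inherits(p, "timeseries_panel"))
  if (length(nodes) < 2) err("config_error", "need >= 2 nodes")
  check_nodes_present(p, nodes)
  check_node_variance(p$series, nodes, p$subject_id)
  cm <- stats::cor(t(p$series[nodes, , drop = FALSE]))
  mean(fisher_z(cm[upper.tri(cm)]))
}

#' Network integration
#'
#' Fisher-z Pearson correlation between the node-average time series of two
#' disjoint networks.
#'
#' @param p a \code{timeseries_panel}.
#' @param nodes_a,nodes_b disjoint node sets, each >= 2 nodes.
#' @export
network_integration <- function(p, nodes_a, nodes_b) {
  stopifnot(inherits(p, "timeseries_panel"))
  if (length(nodes_a) < 2 || length(nodes_b) < 2)
    err("config_error", "need >= 2 nodes per network")
  if (length(intersect(nodes_a, nodes_b)) > 0)
    err("config_error", "networks must be disjoint")
  check_nodes_present(p, c(nodes_a, nodes_b))
  check_node_variance(p$series, c(nodes_a, nodes_b), p$subject_id)
  ma <- colMeans(p$series[nodes_a, , drop = FALSE])
  mb <- colMeans(p$series[nodes_b, , drop = FALSE])
  if (stats::var(ma) < 1e-24 || stats::var(mb) < 1e-24)
    err("zero_variance_mean",
        paste0("degenerate averaged series in '", p$subject_id, "'"))
  fisher_z(stats::cor(ma, mb))
}

#' All connectivity measures for one subject
#'
#' Cohesiveness of every atlas network plus integration of the hub network
#' with each other network: \code{#networks + (#networks - 1)} measures,
#' i.e. 11 under the default 6-network atlas.  With \code{all_pairs = TRUE}
#' integration is computed for every network pair instead.
#'
#' @param p a \code{timeseries_panel} covering the atlas.
#' @param atlas a \code{network_atlas}.
#' @param all_pairs literal every-pair integration instead of hub-centric.
#' @return named numeric vector ("coh_<NET>", "int_<HUB>_<NET>") with
#'   attribute \code{subject_id}.
#' @export
connectivity_vector <- function(p, atlas, all_pairs = FALSE) {
  stopifnot(inherits(atlas, "network_atlas"))
  nets <- names(atlas$networks)
  coh <- vapply(nets, function(nm)
    network_cohesiveness(p, atlas$networks[[nm]]), numeric(1))
  names(coh) <- paste0("coh_", nets)
  if (all_pairs) {
    pairs <- utils::combn(nets, 2, simplify = FALSE)
  } else {
    pairs <- lapply(setdiff(nets, atlas$hub), function(nm) c(atlas$hub, nm))
  }
  intg <- vapply(pairs, function(pr)
    network_integration(p, atlas$networks[[pr[1]]], atlas$networks[[pr[2]]]),
    numeric(1))
  names(intg) <- vapply(pairs, function(pr)
    paste0("int_", pr[1], "_", pr[2]), character(1))
  out <- c(coh, intg)
  attr(out, "subject_id") <- p$subject_id
  out
}

#' @rdname assemble_feature_matrix
#' @export
assemble_connectivity_matrix <- function(vectors) {
  assemble_feature_matrix(vectors, provenance = "connectivity")
}

#' Default morphometry schema: Desikan-Killiany thickness + subcortical
#'
#' 34 cortical regions per hemisphere (\code{<hemi>_<region>_thickness},
#' role "cortical_thickness", mm) and 10 bilateral subcortical structures
#' (role "subcortical_volume", mm^3): 68 + 20 = 88 features.
#'
#' @return data.frame with columns \code{feature}, \code{role}.
#' @export
morphometry_schema <- function() {
  dk <- c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
          "cuneus", "entorhinal", "fusiform", "inferiorparietal",
          "inferiortemporal", "isthmuscingulate", "lateraloccipital",
          "lateralorbitofrontal", "lingual", "medialorbitofrontal",
          "middletemporal", "parahippocampal", "paracentral",
          "parsopercularis", "parsorbitalis", "parstriangularis",
          "pericalcarine", "postcentral", "posteriorcingulate",
          "precentral", "precuneus", "rostralanteriorcingulate",
          "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
          "superiortemporal", "supramarginal", "frontalpole",
          "temporalpole", "transversetemporal", "insula")
  sub <- c("Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
           "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC",
           "Lateral-Ventricle", "Cerebellum-Cortex")
  data.frame(
    feature = c(paste0("lh_", dk, "_thickness"),
                paste0("rh_", dk, "_thickness"),
                paste0("Left-", sub), paste0("Right-", sub)),
    role = c(rep("cortical_thickness", 68), rep("subcortical_volume", 20)),
    stringsAsFactors = FALSE)
}

#' Read and validate a morphometry table
#'
#' TSV with a \code{subject_id} column plus one column per schema feature.
#' Role counts are checked (68 cortical thickness + 20 subcortical volume
#' under the default schema); all values must be positive.  Missing values
#' fail hard unless \code{impute = TRUE} (column-mean imputation, reported
#' via message).
#'
#' @param path TSV file.
#' @param schema feature/role table as from \code{morphometry_schema}.
#' @param impute mean-impute missing values instead of failing.
#' @return feature matrix (subjects x 88) with provenance "morphometry" and
#'   attribute \code{schema}.
#' @export
read_morphometry_table <- function(path, schema = morphometry_schema(),
                                   impute = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    err("schema_violation", "morphometry table needs a subject_id column")
  feats <- setdiff(names(df), "subject_id")
  missing <- setdiff(schema$feature, feats)
  unknown <- setdiff(feats, schema$feature)
  if (length(missing) > 0)
    err("schema_violation", paste0(length(missing), " schema feature(s) absent: ",
        paste(utils::head(missing, 40), collapse = ", ")))
  if (length(unknown) > 0)
    err("schema_violation", paste0("unknown feature(s): ",
        paste(utils::head(unknown, 10), collapse = ", ")))
  m <- as.matrix(df[, schema$feature, drop = FALSE])
  rownames(m) <- as.character(df$subject_id)
  if (anyNA(m)) {
    if (!impute)
      err("schema_violation", "missing values present (set impute = TRUE to mean-impute)")
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) m[na, j] <- mean(m[!na, j])
    }
    message("mean-imputed ", sum(is.na(df[, schema$feature])), " missing values")
  }
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    err("non_positive_value",
        paste0("non-positive value: subject '", rownames(m)[bad[1, 1]],
               "', feature '", colnames(m)[bad[1, 2]], "'"))
  attr(m, "provenance") <- "morphometry"
  attr(m, "schema") <- schema
  m
}

#' Assemble a brain feature matrix
#'
#' From a list of connectivity vectors or an already validated morphometry
#' matrix; optionally checks subject alignment against a metadata id vector.
#'
#' @param x list of connectivity vectors or a morphometry matrix.
#' @param subjects optional expected subject-id order.
#' @export
assemble_brain_matrix <- function(x, subjects = NULL) {
  m <- if (is.list(x)) assemble_connectivity_matrix(x) else as.matrix(x)
  if (!is.null(subjects) && !identical(rownames(m), as.character(subjects)))
    err("alignment_error", "subject order does not match metadata")
  m
}
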