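# Parametric empirical-Bayes batch harmonization (location/scale model).
#
# Feature-wise model: x_ij = alpha + w_i' beta + gamma_b(i) + delta_b(i) e_ij.
# After least-squares standardization, per-batch locations get a normal
# prior and squared scales an inverse-gamma prior, with hyperparameters
# estimated by method of moments across features; the conditional posterior
# updates are iterated to convergence.  Fitting and applying are separate so
# the model can be audited, serialized, and applied to aligned data.

#' Fit a batch-harmonization model
#'
#' @param m raw feature matrix (subjects x features, rownames = ids).
#' @param batch factor/character of batch (site) labels, length nrow(m);
#'   every batch needs >= 3 subjects.
#' @param covariates optional numeric matrix/data.frame of covariates whose
#'   effects are estimated jointly and preserved by the adjustment.
#' @param eb_tol,eb_max_iter convergence control of the posterior updates
#'   (absolute change < \code{eb_tol}, default 1e-6; cap 200).
#' @return object of class \code{"combat_model"}.
#' @export
combat_fit <- function(m, batch, covariates = NULL,
                       eb_tol = 1e-6, eb_max_iter = 200) {
  m <- as.matrix(m)
  n <- nrow(m); p <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(p))
  batch <- factor(batch)
  if (length(batch) != n)
    err("alignment_error", "batch labels do not match the subject count")
  nb <- nlevels(batch)
  n_per <- as.integer(table(batch))
  if (any(n_per < 3))
    err("too_few_per_batch",
        paste0("batch(es) with < 3 subjects: ",
               paste(levels(batch)[n_per < 3], collapse = ", ")))
  sds <- apply(m, 2, stats::sd)
  if (any(sds < 1e-12))
    err("constant_feature", paste0("constant feature(s): ",
        paste(colnames(m)[sds < 1e-12], collapse = ", ")))
  B <- matrix(0, n, nb)
  B[cbind(seq_len(n), as.integer(batch))] <- 1
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n)
      err("alignment_error", "covariates do not match the subject count")
    if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
  }
  D <- cbind(B, C)
  if (qr(D)$rank < ncol(D))
    err("singular_design",
        "design matrix (batch indicators + covariates) is rank deficient")
  beta <- solve(crossprod(D), crossprod(D, m))   # (nb + q) x p
  beta_batch <- beta[seq_len(nb), , drop = FALSE]
  beta_cov <- if (is.null(C)) NULL else beta[-seq_len(nb), , drop = FALSE]
  alpha <- as.numeric(crossprod(beta_batch, n_per / n))  # weighted grand mean
  stand_mean <- matrix(alpha, n, p, byrow = TRUE)
  if (!is.null(C)) stand_mean <- stand_mean + C %*% beta_cov
  resid <- m - D %*% beta
  var_pooled <- colMeans(resid^2)                        # 1/n convention
  Z <- (m - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_hat <- delta2_hat <- gamma_star <- delta2_star <-
    matrix(0, nb, p, dimnames = list(levels(batch), colnames(m)))
  for (b in seq_len(nb)) {
    Zb <- Z[batch == levels(batch)[b], , drop = FALSE]
    nbk <- nrow(Zb)
    g_hat <- colMeans(Zb)
    d_hat <- colMeans(sweep(Zb, 2, g_hat)^2)             # 1/n_b convention
    gamma_hat[b, ] <- g_hat
    delta2_hat[b, ] <- d_hat
    # method-of-moments hyperparameters across features
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    d_m <- mean(d_hat); d_s2 <- stats::var(d_hat)
    shrink_delta <- d_s2 > 1e-12
    a_pr <- if (shrink_delta) (2 * d_s2 + d_m^2) / d_s2 else NA_real_
    b_pr <- if (shrink_delta) (d_m * d_s2 + d_m^3) / d_s2 else NA_real_
    g <- g_hat; d <- d_hat
    for (it in seq_len(eb_max_iter)) {
      g_new <- if (t2 > 1e-12)
        (nbk * t2 * g_hat + d * g_bar) / (nbk * t2 + d) else g_hat
      d_new <- if (shrink_delta) {
        sum2 <- nbk * d_hat + nbk * (g_hat - g_new)^2
        (0.5 * sum2 + b_pr) / (nbk / 2 + a_pr - 1)
      } else d_hat
      ch <- max(abs(g_new - g), abs(d_new - d))
      g <- g_new; d <- d_new
      if (ch < eb_tol) break
    }
    gamma_star[b, ] <- g
    delta2_star[b, ] <- d
  }
  model <- structure(list(
    alpha = stats::setNames(alpha, colnames(m)),
    beta_cov = beta_cov, var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    batches = levels(batch), n_per_batch = stats::setNames(n_per, levels(batch)),
    features = colnames(m), mean_offset = numeric(p)
  ), class = "combat_model")
  # restore each feature's grand mean exactly (a common shift across batches
  # cannot reintroduce a batch effect); offset frozen at fit time
  adj <- combat_apply(model, m, batch, covariates, .check = FALSE)
  model$mean_offset <- colMeans(m) - colMeans(adj)
  model
}

#' Apply a fitted harmonization model
#'
#' @param model a \code{combat_model}.
#' @param m feature matrix with the model's features; batches must have
#'   been seen at fit.
#' @param batch batch labels for the rows of \code{m}.
#' @param covariates covariates matching those used at fit (same columns).
#' @return harmonized matrix with attribute \code{harmonized = TRUE}.
#' @export
combat_apply <- function(model, m, batch, covariates = NULL, .check = TRUE) {
  stopifnot(inherits(model, "combat_model"))
  m <- as.matrix(m)
  if (.check) {
    if (is.null(colnames(m)) || !identical(colnames(m), model$features))
      err("feature_mismatch", "feature columns differ from those seen at fit")
    if (is.null(model$beta_cov) != is.null(covariates))
      err("feature_mismatch", "covariate presence differs from fit")
  }
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen) > 0)
    err("unseen_batch", paste0("batch(es) not seen at fit: ",
                               paste(unseen, collapse = ", ")))
  n <- nrow(m); p <- ncol(m)
  stand_mean <- matrix(model$alpha, n, p, byrow = TRUE)
  if (!is.null(model$beta_cov))
    stand_mean <- stand_mean + as.matrix(covariates) %*% model$beta_cov
  sig <- matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  Z <- (m - stand_mean) / sig
  g <- model$gamma_star[batch, , drop = FALSE]
  d <- sqrt(model$delta2_star[batch, , drop = FALSE])
  adj <- sig * (Z - g) / d + stand_mean
  adj <- sweep(adj, 2, model$mean_offset, "+")
  dimnames(adj) <- dimnames(m)
  attr(adj, "harmonized") <- TRUE
  attr(adj, "provenance") <- attr(m, "provenance")
  adj
}

#' @export
predict.combat_model <- function(object, newdata, batch, covariates = NULL, ...) {
  combat_apply(object, newdata, batch, covariates)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat model: %d features, %d batch(es): %s>\n",
              length(x$features), length(x$batches),
              paste(sprintf("%s (n=%d)", x$batches, x$n_per_batch),
                    collapse = ", ")))
  cat(sprintf("  mean |gamma*| = %.4f, mean delta*^2 = %.4f\n",
              mean(abs(x$gamma_star)), mean(x$delta2_star)))
  invisible(x)
}

#' Serialize a harmonization model to JSON for audit
#' @param model a \code{combat_model}.
#' @param path output JSON path.
#' @export
write_combat_model <- function(model, path) {
  jsonlite::write_json(lapply(unclass(model), function(x) {
    if (is.matrix(x)) list(rows = rownames(x), values = unname(as.data.frame(x)))
    else x
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
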