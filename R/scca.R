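#' Z-score the columns of a feature block
#'
#' Centres each column and scales it to unit sample standard deviation
#' (denominator n - 1), marking the result so it cannot be scaled twice.
#' Canonical correlation models in this package require z-scored blocks so
#' that weights are comparable across features measured in different units.
#'
#' @param x numeric matrix (subjects x features), raw state.
#' @return matrix with attribute \code{zscored = TRUE} and attributes
#'   \code{center}/\code{scale} holding the column statistics used.
#' @export
zscore_block <- function(x) {
  x <- as.matrix(x)
  if (isTRUE(attr(x, "zscored")))
    err("zstate_error", "block is already z-scored; refusing to scale twice")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl < 1e-12)) {
    bad <- colnames(x)[scl < 1e-12] %||% which(scl < 1e-12)
    err("constant_column", paste0(
      "constant column(s) cannot be z-scored: ",
      paste(bad, collapse = ", "),
      " (run the degenerate-feature filter first)"))
  }
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  attr(z, "zscored") <- TRUE
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Soft-thresholding operator
#'
#' Elementwise \eqn{sign(x) max(|x| - \lambda, 0)}, the proximal operator of
#' the L1 penalty used in each penalized matrix decomposition update.
#'
#' @param x numeric vector.
#' @param lambda threshold, \eqn{\ge 0}.
#' @export
soft_threshold <- function(x, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    err("negative_lambda", "lambda must be a single non-negative number")
  out <- as.numeric(.cpp_soft_threshold(as.numeric(x), lambda))
  names(out) <- names(x)
  out
}

#' Project a direction onto the L2 sphere intersected with an L1 ball
#'
#' Returns \eqn{u = S(a, \lambda) / ||S(a, \lambda)||_2} where the threshold
#' \eqn{\lambda \ge 0} is the smallest value (bisection to 1e-10) such that
#' \eqn{||u||_1 \le c}; \eqn{\lambda = 0} when the unconstrained direction
#' already satisfies the budget.  When the budget is below what any spread
#' over tied maxima can achieve, ties are broken by index order (first
#' maximum wins, one-hot solution).
#'
#' @param a nonzero numeric vector.
#' @param c L1 budget in \eqn{[1, \sqrt{length(a)}]}.
#' @export
l1_unit_project <- function(a, c) {
  a <- as.numeric(a)
  if (all(a == 0)) err("zero_vector", "cannot project the zero vector")
  if (!is.numeric(c) || length(c) != 1 || is.na(c) ||
      c < 1 || c > sqrt(length(a)) + 1e-8)
    err("budget_out_of_range",
        sprintf("L1 budget must lie in [1, sqrt(p)] = [1, %.4f]",
                sqrt(length(a))))
  as.numeric(.cpp_l1_unit_project(a, c))
}

# default sparsity grid: linear over the feasible L1-budget range
make_sparsity_grid <- function(p, length_out = 10) {
  seq(1, sqrt(p), length.out = length_out)
}

check_zscored <- function(x, label) {
  if (!isTRUE(attr(x, "zscored")))
    err("not_zscored", paste0("block ", label, " must be z-scored first"))
}

#' Rank-1 penalized matrix decomposition of the cross-product matrix
#'
#' One sparse canonical mode: alternating soft-thresholded power iterations
#' on \eqn{M = X'Y}, each side projected to unit L2 norm and L1 budget
#' (\code{c1}, \code{c2}), initialized at the leading singular pair of M.
#' The reported \code{r} is the Pearson correlation of the subject scores
#' \eqn{Xu} and \eqn{Yv}.  The sign convention makes the largest-magnitude
#' entry of \code{u} positive (both sides flipped jointly, leaving r intact).
#'
#' @param x,y z-scored blocks sharing subject order (n >= 4).
#' @param c1,c2 L1 budgets for the x- and y-side weight vectors.
#' @param max_iter,tol iteration cap and max-change convergence tolerance.
#' @return list with elements \code{u}, \code{v}, \code{r}, \code{c1},
#'   \code{c2}, \code{iterations}, \code{converged}.
#' @export
pmd_rank1 <- function(x, y, c1, c2, max_iter = 500, tol = 1e-8) {
  check_zscored(x, "x"); check_zscored(y, "y")
  if (nrow(x) != nrow(y)) err("alignment_error", "blocks differ in subject count")
  if (nrow(x) < 4) err("alignment_error", "need at least 4 shared subjects")
  if (c1 < 1 || c1 > sqrt(ncol(x)) + 1e-8 || c2 < 1 || c2 > sqrt(ncol(y)) + 1e-8)
    err("budget_out_of_range", "c1/c2 outside the feasible range [1, sqrt(p)]")
  M <- crossprod(x, y)
  f <- .cpp_pmd_rank1(unclass(x), unclass(y), M, c1, c2, max_iter, tol)
  if (!f$converged)
    warn("no_convergence",
         sprintf("PMD did not converge in %d iterations; returning best iterate",
                 max_iter))
  u <- as.numeric(f$u); names(u) <- colnames(x)
  v <- as.numeric(f$v); names(v) <- colnames(y)
  list(u = u, v = v, r = f$r, c1 = c1, c2 = c2,
       iterations = f$iterations, converged = f$converged)
}

#' Choose sparsity by grid search over (c1, c2)
#'
#' Fits a rank-1 mode at every grid point and returns the point with maximal
#' canonical correlation, the selection rule of the analysis this package
#' implements.  Ties (within 1e-10) are broken toward the sparser model
#' (smaller c1 + c2), then lexicographically by grid index.
#'
#' @param x,y z-scored blocks.
#' @param c1_grid,c2_grid L1 budget grids; default 10 points linear on
#'   \eqn{[1, \sqrt{p}]} per block.
#' @return list: chosen \code{c1}, \code{c2}, the fitted \code{mode}, and a
#'   \code{trace} matrix of r over the full grid (rows = c1, cols = c2).
#' @export
grid_search_sparsity <- function(x, y, c1_grid = NULL, c2_grid = NULL,
                                 max_iter = 500, tol = 1e-8) {
  check_zscored(x, "x"); check_zscored(y, "y")
  c1_grid <- c1_grid %||% make_sparsity_grid(ncol(x))
  c2_grid <- c2_grid %||% make_sparsity_grid(ncol(y))
  if (length(c1_grid) == 0 || length(c2_grid) == 0)
    err("empty_grid", "sparsity grid must be non-empty")
  g <- .cpp_grid_search(unclass(x), unclass(y),
                        as.numeric(c1_grid), as.numeric(c2_grid),
                        max_iter, tol)
  u <- as.numeric(g$u); names(u) <- colnames(x)
  v <- as.numeric(g$v); names(v) <- colnames(y)
  trace <- g$trace
  dimnames(trace) <- list(c1 = signif(c1_grid, 6), c2 = signif(c2_grid, 6))
  list(c1 = g$c1, c2 = g$c2,
       mode = list(u = u, v = v, r = g$r, c1 = g$c1, c2 = g$c2,
                   iterations = g$iterations, converged = g$converged),
       c1_grid = c1_grid, c2_grid = c2_grid, trace = trace)
}

#' Permutation test with the maximal-correlation null
#'
#' For each permutation the rows of one block are permuted (the other fixed)
#' and the full sparsity grid search is re-run; the maximum canonical
#' correlation over the grid is recorded.  The p-value is the number of
#' permutations whose maximal correlation exceeds the observed correlation,
#' divided by the number of permutations (the k/N convention); the
#' (k+1)/(N+1) estimator is reported alongside as \code{p_plus_one}.
#' Because the null statistic is the maximum over all models searched, the
#' p-value is inherently corrected for the sparsity selection.
#'
#' @param x,y z-scored blocks.
#' @param c1_grid,c2_grid the grids used for the observed fit.
#' @param observed_r observed (grid-maximal) canonical correlation; computed
#'   from the data when NULL.
#' @param n_perm number of permutations (>= 100 unless
#'   \code{allow_small = TRUE}, for toy examples only).
#' @param seed integer seed; permutations are reproducible.
#' @param permute which block's rows to permute.
#' @return list: \code{p}, \code{p_plus_one}, \code{observed_r},
#'   \code{perm_max} (per-permutation maxima), \code{n_perm}, \code{seed}.
#' @export
permutation_test <- function(x, y, c1_grid = NULL, c2_grid = NULL,
                             observed_r = NULL, n_perm = 10000, seed = 1,
                             permute = c("y", "x"), allow_small = FALSE,
                             max_iter = 500, tol = 1e-8) {
  check_zscored(x, "x"); check_zscored(y, "y")
  permute <- match.arg(permute)
  if (n_perm < 100 && !allow_small)
    err("too_few_permutations",
        "n_perm < 100 gives an unusably coarse p-value; set allow_small = TRUE for toy runs")
  c1_grid <- c1_grid %||% make_sparsity_grid(ncol(x))
  c2_grid <- c2_grid %||% make_sparsity_grid(ncol(y))
  if (is.null(observed_r)) {
    observed_r <- grid_search_sparsity(x, y, c1_grid, c2_grid,
                                       max_iter = max_iter, tol = tol)$mode$r
  }
  n <- nrow(x)
  perms <- withr::with_seed(seed,
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  if (permute == "y") {
    pm <- .cpp_perm_max_r(unclass(x), unclass(y),
                          as.numeric(c1_grid), as.numeric(c2_grid),
                          perms - 1L, max_iter, tol)
  } else {
    pm <- .cpp_perm_max_r(unclass(y), unclass(x),
                          as.numeric(c2_grid), as.numeric(c1_grid),
                          perms - 1L, max_iter, tol)
  }
  pm <- as.numeric(pm)
  k <- sum(pm > observed_r)
  list(p = k / n_perm, p_plus_one = (k + 1) / (n_perm + 1),
       observed_r = observed_r, perm_max = pm, n_perm = n_perm, seed = seed,
       permuted = permute)
}

# deflate the cross-product matrix by an extracted mode
deflate_cross <- function(M, u, v) {
  d <- as.numeric(crossprod(u, M %*% v))
  M - d * tcrossprod(u, v)
}

#' Extract further canonical modes by deflation
#'
#' Removes each extracted rank-1 component from the cross-product matrix
#' (\eqn{M \leftarrow M - d\,uv'}, \eqn{d = u'Mv}) and refits at the mode-1
#' sparsity.  Each further mode receives an unadjusted permutation p-value
#' against its own deflated null: per permutation, the permuted cross-product
#' is deflated by the previously extracted observed modes and refitted at the
#' same sparsity.
#'
#' @param x,y z-scored blocks.
#' @param first_mode the mode-1 fit (list with u, v, c1, c2, r).
#' @param k_max total number of modes wanted (1 = no further modes).
#' @param n_perm,seed permutation settings for the further-mode p-values.
#' @return list of further modes (possibly empty), each with u, v, r, p.
#' @export
extract_further_modes <- function(x, y, first_mode, k_max = 2,
                                  n_perm = 1000, seed = 1,
                                  max_iter = 500, tol = 1e-8) {
  check_zscored(x, "x"); check_zscored(y, "y")
  if (k_max <= 1) return(list())
  n <- nrow(x)
  c1 <- first_mode$c1; c2 <- first_mode$c2
  extracted <- list(first_mode)
  further <- list()
  perms <- withr::with_seed(derive_seed(seed, 1L),
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  for (k in seq_len(k_max - 1)) {
    M <- crossprod(x, y)
    for (m in extracted) M <- deflate_cross(M, m$u, m$v)
    f <- .cpp_pmd_rank1(unclass(x), unclass(y), M, c1, c2, max_iter, tol)
    u <- as.numeric(f$u); names(u) <- colnames(x)
    v <- as.numeric(f$v); names(v) <- colnames(y)
    # deflated null: permute y, deflate the permuted cross-product by the
    # observed extracted modes, refit at the same sparsity
    perm_r <- vapply(seq_len(n_perm), function(b) {
      yp <- y[perms[, b], , drop = FALSE]
      Mp <- crossprod(x, yp)
      for (m in extracted) Mp <- deflate_cross(Mp, m$u, m$v)
      fp <- .cpp_pmd_rank1(unclass(x), unclass(yp), Mp, c1, c2, max_iter, tol)
      fp$r
    }, numeric(1))
    kk <- sum(perm_r > f$r)
    further[[k]] <- list(u = u, v = v, r = f$r, c1 = c1, c2 = c2,
                         iterations = f$iterations, converged = f$converged,
                         p = kk / n_perm, p_plus_one = (kk + 1) / (n_perm + 1),
                         perm_r = perm_r)
    extracted <- c(extracted, list(further[[k]]))
  }
  further
}

#' Sparse canonical correlation analysis of two feature blocks
#'
#' Fits the full analysis chain on two raw feature blocks sharing subject
#' order: degenerate-feature filtering, column z-scoring, sparsity selection
#' by grid search maximizing the canonical correlation, permutation inference
#' against the null distribution of maximal correlations, and deflation-based
#' extraction of further modes with unadjusted permutation p-values.
#'
#' @param x,y numeric matrices (subjects x features), raw scale; rownames,
#'   when present on both, must agree (subject alignment).
#' @param n_perm permutations for the mode-1 max-correlation null.
#' @param seed integer; all randomness in the fit derives from it.
#' @param c1_grid,c2_grid L1-budget grids; default 10 points linear on
#'   \eqn{[1, \sqrt p]} per block.
#' @param k_max total modes to extract (default 2: mode 1 plus one further
#'   mode to check that no residual covariation remains).
#' @param drop_threshold degenerate-feature threshold: a feature is dropped
#'   when the proportion of subjects sharing its modal value strictly
#'   exceeds this (default 0.5).
#' @param append optional matrix/data.frame of indicator columns (e.g. a
#'   diagnosis dummy, a handedness score) appended to block x AFTER the
#'   degenerate filter — group indicators are intentionally exempt from the
#'   majority-value rule — and z-scored with the rest.
#' @param permute which block's rows are permuted under the null.
#' @param analysis label carried into printed output and serialization.
#' @return an object of class \code{"scca"}; see \code{summary.scca},
#'   \code{coef.scca}, \code{predict.scca}, \code{plot.scca}.
#' @export
scca <- function(x, y, n_perm = 1000, seed = 1,
                 c1_grid = NULL, c2_grid = NULL, k_max = 2,
                 drop_threshold = 0.5, append = NULL,
                 permute = c("y", "x"),
                 allow_small = FALSE, max_iter = 500, tol = 1e-8,
                 analysis = "scca") {
  cl <- match.call()
  permute <- match.arg(permute)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) err("alignment_error", "blocks differ in subject count")
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y)))
    err("alignment_error", "block rownames (subject ids) do not match")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))

  fx <- drop_degenerate_features(x, threshold = drop_threshold)
  fy <- drop_degenerate_features(y, threshold = drop_threshold)
  if (!is.null(append)) {
    add <- as.matrix(append)
    if (nrow(add) != nrow(fx$matrix))
      err("alignment_error", "appended columns do not match the subject count")
    if (is.null(colnames(add)))
      colnames(add) <- paste0("ind", seq_len(ncol(add)))
    fx$matrix <- cbind(fx$matrix, add)
  }
  zx <- zscore_block(fx$matrix)
  zy <- zscore_block(fy$matrix)

  gs <- grid_search_sparsity(zx, zy, c1_grid, c2_grid,
                             max_iter = max_iter, tol = tol)
  pt <- permutation_test(zx, zy, gs$c1_grid, gs$c2_grid,
                         observed_r = gs$mode$r, n_perm = n_perm,
                         seed = seed, permute = permute,
                         allow_small = allow_small,
                         max_iter = max_iter, tol = tol)
  mode1 <- c(gs$mode, list(p = pt$p, p_plus_one = pt$p_plus_one))
  further <- extract_further_modes(zx, zy, gs$mode, k_max = k_max,
                                   n_perm = n_perm, seed = seed,
                                   max_iter = max_iter, tol = tol)
  modes <- c(list(mode1), further)

  structure(list(
    call = cl, analysis = analysis,
    modes = modes, n_modes = length(modes),
    grid = list(c1_grid = gs$c1_grid, c2_grid = gs$c2_grid, trace = gs$trace),
    perm = list(n_perm = n_perm, perm_max = pt$perm_max, permuted = permute),
    dropped = list(x = fx$dropped, y = fy$dropped),
    scaling = list(
      x = list(center = attr(zx, "center"), scale = attr(zx, "scale")),
      y = list(center = attr(zy, "center"), scale = attr(zy, "scale"))),
    features = list(x = colnames(fx$matrix), y = colnames(fy$matrix)),
    n = nrow(x), seed = seed
  ), class = "scca")
}

#' @export
print.scca <- function(x, ...) {
  m1 <- x$modes[[1]]
  cat("Sparse canonical correlation analysis:", x$analysis, "\n")
  cat(sprintf("  n = %d subjects; %d x-features, %d y-features (%d + %d dropped as degenerate)\n",
              x$n, length(x$features$x), length(x$features$y),
              length(x$dropped$x), length(x$dropped$y)))
  cat(sprintf("  mode 1: r = %.3f at (c1, c2) = (%.3f, %.3f); p = %s (%d permutations, max-correlation null)\n",
              m1$r, m1$c1, m1$c2, format(m1$p, digits = 3), x$perm$n_perm))
  if (x$n_modes > 1) {
    for (k in 2:x$n_modes) {
      mk <- x$modes[[k]]
      cat(sprintf("  mode %d: r = %.3f; unadjusted p = %s\n",
                  k, mk$r, format(mk$p, digits = 3)))
    }
  }
  invisible(x)
}

#' @export
summary.scca <- function(object, top_k = 10, ...) {
  tab <- do.call(rbind, lapply(seq_along(object$modes), function(k) {
    m <- object$modes[[k]]
    data.frame(mode = k, r = m$r, c1 = m$c1, c2 = m$c2, p = m$p,
               nonzero_u = sum(m$u != 0), nonzero_v = sum(m$v != 0))
  }))
  structure(list(analysis = object$analysis, modes = tab,
                 top_x = report_weights(object, top_k, side = "x"),
                 top_y = report_weights(object, top_k, side = "y"),
                 n = object$n),
            class = "summary.scca")
}

#' @export
print.summary.scca <- function(x, ...) {
  cat("sCCA summary:", x$analysis, sprintf("(n = %d)\n\n", x$n))
  print(x$modes, row.names = FALSE)
  cat("\nTop block-1 weights (mode 1):\n")
  print(x$top_x, row.names = FALSE)
  cat("\nTop block-2 weights (mode 1):\n")
  print(x$top_y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.scca <- function(object, ...) {
  list(x = vapply(object$modes, function(m) m$u,
                  numeric(length(object$features$x))),
       y = vapply(object$modes, function(m) m$v,
                  numeric(length(object$features$y))))
}

#' Subject scores on the canonical variates
#'
#' Applies the training-set z-scoring and fitted weight vectors to (new)
#' raw feature blocks, returning per-mode canonical scores.
#'
#' @param object fitted \code{scca} model.
#' @param newx,newy raw blocks with the model's (retained) feature columns;
#'   defaults missing, in which case an error prompts for data since the fit
#'   does not retain its training matrices.
#' @export
predict.scca <- function(object, newx, newy, ...) {
  score_side <- function(new, side) {
    new <- as.matrix(new)
    feats <- object$features[[side]]
    if (!all(feats %in% colnames(new)))
      err("feature_mismatch",
          paste0("newdata lacks feature(s): ",
                 paste(setdiff(feats, colnames(new)), collapse = ", ")))
    new <- new[, feats, drop = FALSE]
    sc <- object$scaling[[side]]
    z <- sweep(sweep(new, 2, sc$center, "-"), 2, sc$scale, "/")
    w <- if (side == "x") "u" else "v"
    vapply(object$modes, function(m) as.numeric(z %*% m[[w]]),
           numeric(nrow(new)))
  }
  out <- list()
  if (!missing(newx)) out$x <- score_side(newx, "x")
  if (!missing(newy)) out$y <- score_side(newy, "y")
  if (length(out) == 0)
    err("feature_mismatch", "supply newx and/or newy to score")
  out
}

#' Bar chart of the most heavily weighted features of a mode
#'
#' @param x fitted \code{scca} model.
#' @param mode which canonical mode to display.
#' @param top_k features per block.
#' @export
plot.scca <- function(x, mode = 1, top_k = 10, ...) {
  m <- x$modes[[mode]]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 9, 3, 1))
  on.exit(graphics::par(op))
  for (side in c("u", "v")) {
    w <- m[[side]]
    w <- w[order(abs(w), decreasing = TRUE)][seq_len(min(top_k, length(w)))]
    w <- rev(w)
    graphics::barplot(w, horiz = TRUE, las = 1, cex.names = 0.7,
                      col = ifelse(w >= 0, "steelblue", "firebrick"),
                      main = sprintf("mode %d %s-side (r = %.2f)",
                                     mode, if (side == "u") "x" else "y", m$r),
                      xlab = "weight")
  }
  invisible(x)
}
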