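# sparse CCA: scaling, projection operators, rank-1 PMD, grid search,
# permutation inference, deflation, and the fitted-model interface

test_that("z-scoring centres and scales with the sample-sd convention", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 10, 13))
  z <- zscore_block(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, stats::sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_error(zscore_block(z), class = "zstate_error")
  expect_error(zscore_block(cbind(k = rep(2, 5))), class = "constant_column")
})

test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 0), c(3, -1, 0.5))
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(2, 0, 0))
  expect_equal(soft_threshold(c(3, -1, 0.5), 5), c(0, 0, 0))
  expect_error(soft_threshold(1:3, -0.1), class = "negative_lambda")
})

test_that("L1-ball projection satisfies its defining properties", {
  # inactive constraint: plain normalization
  a <- c(3, 1, -2)
  expect_equal(l1_unit_project(a, sqrt(3)), a / sqrt(sum(a^2)))
  # tie at the maximum with a budget of 1: first index wins
  expect_equal(l1_unit_project(c(1, 1), 1), c(1, 0))
  expect_equal(l1_unit_project(c(-2, 2), 1), c(-1, 0))
  # brute-force oracle: maximize u'a over the discretized constraint set
  ang <- seq(0, 2 * pi, length.out = 6283)
  us <- rbind(cos(ang), sin(ang))
  feas <- us[, colSums(abs(us)) <= 1.2 + 1e-9]
  a <- c(2, 1)
  best <- feas[, which.max(crossprod(feas, a))]
  expect_equal(l1_unit_project(a, 1.2), best, tolerance = 1e-3)
  expect_error(l1_unit_project(c(0, 0), 1), class = "zero_vector")
  expect_error(l1_unit_project(1:4, 0.5), class = "budget_out_of_range")
  expect_error(l1_unit_project(1:4, 3), class = "budget_out_of_range")
})

test_that("projection invariants hold on random draws", {
  withr::with_seed(61, {
    for (i in 1:500) {
      p <- sample(2:30, 1)
      a <- stats::rnorm(p)
      c <- stats::runif(1, 1, sqrt(p))
      u <- l1_unit_project(a, c)
      expect_equal(sum(u^2), 1, tolerance = 1e-8)
      expect_lte(sum(abs(u)), c + 1e-7)
    }
  })
})

test_that("unconstrained PMD equals the leading singular pair of X'Y", {
  withr::with_seed(62, {
    for (i in 1:10) {
      n <- 20; p1 <- 5; p2 <- 4
      x <- zs(matrix(stats::rnorm(n * p1), n))
      y <- zs(matrix(stats::rnorm(n * p2), n))
      f <- pmd_rank1(x, y, sqrt(p1), sqrt(p2))
      sv <- svd(crossprod(x, y))
      u <- sv$u[, 1]; v <- sv$v[, 1]
      if (sign(u[which.max(abs(u))]) < 0) { u <- -u; v <- -v }
      expect_equal(unname(f$u), u, tolerance = 1e-6)
      expect_equal(unname(f$v), v, tolerance = 1e-6)
    }
  })
})

test_that("a column-permuted copy of a block is perfectly correlated", {
  withr::with_seed(63, {
    x <- zs(matrix(stats::rnorm(30 * 4), 30))
  })
  y <- x[, c(3, 1, 4, 2)]
  attr(y, "zscored") <- TRUE
  f <- pmd_rank1(x, y, 2, 2)
  expect_equal(f$r, 1, tolerance = 1e-6)
})

test_that("PMD norms and sign convention hold at every grid point", {
  withr::with_seed(64, {
    for (i in 1:25) {
      n <- 12; p1 <- sample(3:8, 1); p2 <- sample(3:8, 1)
      x <- zs(matrix(stats::rnorm(n * p1), n))
      y <- zs(matrix(stats::rnorm(n * p2), n))
      c1 <- stats::runif(1, 1, sqrt(p1)); c2 <- stats::runif(1, 1, sqrt(p2))
      f <- pmd_rank1(x, y, c1, c2)
      expect_equal(sum(f$u^2), 1, tolerance = 1e-8)
      expect_equal(sum(f$v^2), 1, tolerance = 1e-8)
      expect_lte(sum(abs(f$u)), c1 + 1e-7)
      expect_lte(sum(abs(f$v)), c2 + 1e-7)
      expect_gte(f$u[which.max(abs(f$u))], 0)
      expect_true(f$r >= -1 && f$r <= 1)
    }
  })
})

test_that("r is invariant to a joint row permutation of both blocks", {
  withr::with_seed(65, {
    x <- zs(matrix(stats::rnorm(40 * 6), 40))
    y <- zs(matrix(stats::rnorm(40 * 5), 40))
    perm <- sample(40)
  })
  f1 <- pmd_rank1(x, y, 1.8, 1.8)
  xp <- x[perm, ]; yp <- y[perm, ]
  attr(xp, "zscored") <- TRUE; attr(yp, "zscored") <- TRUE
  f2 <- pmd_rank1(xp, yp, 1.8, 1.8)
  expect_equal(f2$r, f1$r, tolerance = 1e-10)
})

test_that("grid search returns the maximum with a complete trace", {
  withr::with_seed(66, {
    x <- zs(matrix(stats::rnorm(25 * 6), 25))
    y <- zs(matrix(stats::rnorm(25 * 6), 25))
  })
  g <- grid_search_sparsity(x, y, c1_grid = 1.5, c2_grid = 1.5)
  expect_equal(c(g$c1, g$c2), c(1.5, 1.5))
  g2 <- grid_search_sparsity(x, y)
  expect_equal(dim(g2$trace), c(10, 10))
  expect_equal(max(g2$trace), g2$mode$r)
  expect_equal(g2$trace[which(g2$c1_grid == g2$c1),
                        which(g2$c2_grid == g2$c2)], g2$mode$r)
  expect_error(grid_search_sparsity(x, y, c1_grid = numeric(0)),
               class = "empty_grid")
})

test_that("a sparse planted mode is recovered at the true sparsity level", {
  # dimensions where the planted component dominates the cross-product
  # noise (n rho > sqrt(n)(sqrt(p1)+sqrt(p2))), so recovery is feasible
  g <- generate_linked_blocks(200, 20, 20,
                              truth = list(rho = 0.8, support1 = 1:5,
                                           support2 = 1:5), seed = 67)
  zx <- zs(g$x); zy <- zs(g$y)
  f <- pmd_rank1(zx, zy, sqrt(5), sqrt(5))
  # every planted feature is found, with at most a few noise features
  expect_true(all(1:5 %in% which(f$u != 0)))
  expect_true(all(1:5 %in% which(f$v != 0)))
  expect_lte(sum(f$u != 0), 10)
  expect_lte(sum(f$v != 0), 10)
  # and the true support carries nearly all of the weight mass
  expect_gt(sum(f$u[1:5]^2), 0.9)
  expect_gt(sum(f$v[1:5]^2), 0.9)
  expect_equal(f$r, 0.8, tolerance = 0.1)
})

test_that("permutation p-values follow the k/N convention and are seeded", {
  g <- generate_linked_blocks(40, 6, 6, truth = list(rho = 0.95,
                                                     support1 = 1:3,
                                                     support2 = 1:3),
                              seed = 68)
  zx <- zs(g$x); zy <- zs(g$y)
  pt <- permutation_test(zx, zy, n_perm = 60, seed = 5, allow_small = TRUE)
  expect_equal(pt$p, sum(pt$perm_max > pt$observed_r) / 60)
  expect_equal(pt$p_plus_one,
               (sum(pt$perm_max > pt$observed_r) + 1) / 61)
  # strong planted signal: no permuted maximum exceeds the observed r
  expect_equal(pt$p, 0)
  # reproducibility under the seed
  pt2 <- permutation_test(zx, zy, n_perm = 60, seed = 5, allow_small = TRUE)
  expect_identical(pt$perm_max, pt2$perm_max)
  expect_error(permutation_test(zx, zy, n_perm = 50, seed = 1),
               class = "too_few_permutations")
})

test_that("the identity permutation reproduces the observed correlation", {
  withr::with_seed(69, {
    x <- zs(matrix(stats::rnorm(20 * 4), 20))
    y <- zs(matrix(stats::rnorm(20 * 4), 20))
  })
  gs <- grid_search_sparsity(x, y)
  idperm <- matrix(0:19, ncol = 1)
  r_id <- speechscca:::.cpp_perm_max_r(unclass(x), unclass(y),
                                       gs$c1_grid, gs$c2_grid, idperm,
                                       500L, 1e-8)
  expect_equal(as.numeric(r_id), gs$mode$r, tolerance = 1e-12)
})

test_that("deflation removes the extracted component and stops at k_max", {
  g <- generate_linked_blocks(80, 8, 8, truth = list(rho = 0.9,
                                                     support1 = 1:4,
                                                     support2 = 1:4),
                              seed = 70)
  zx <- zs(g$x); zy <- zs(g$y)
  gs <- grid_search_sparsity(zx, zy)
  expect_identical(extract_further_modes(zx, zy, gs$mode, k_max = 1), list())
  further <- extract_further_modes(zx, zy, gs$mode, k_max = 2,
                                   n_perm = 100, seed = 3)
  expect_length(further, 1)
  m2 <- further[[1]]
  # deflation identity: extracted mode-1 direction is annihilated
  M <- crossprod(zx, zy)
  d <- as.numeric(crossprod(gs$mode$u, M %*% gs$mode$v))
  Mdef <- M - d * tcrossprod(gs$mode$u, gs$mode$v)
  expect_equal(as.numeric(crossprod(gs$mode$u, Mdef %*% gs$mode$v)), 0,
               tolerance = 1e-8)
  # rank-1 planted structure: mode 2 sits at the noise floor, clearly
  # below mode 1 and inside its own deflated permutation null
  expect_lt(m2$r, gs$mode$r - 0.2)
  expect_lte(m2$r, stats::quantile(m2$perm_r, 0.99))
})

test_that("the fitted scca object is complete, deterministic and methodful", {
  g <- generate_linked_blocks(60, 12, 9, truth = list(rho = 0.9,
                                                      support1 = 1:4,
                                                      support2 = 1:4),
                              seed = 71)
  fit <- scca(g$x, g$y, n_perm = 60, seed = 9, k_max = 2, allow_small = TRUE)
  expect_s3_class(fit, "scca")
  expect_length(fit$modes, 2)
  expect_equal(length(fit$modes[[1]]$u), 12)
  expect_equal(length(fit$modes[[1]]$v), 9)
  expect_lte(fit$modes[[1]]$p, 0.05)

  fit2 <- scca(g$x, g$y, n_perm = 60, seed = 9, k_max = 2, allow_small = TRUE)
  expect_equal(fit[setdiff(names(fit), "call")],
               fit2[setdiff(names(fit2), "call")])

  co <- coef(fit)
  expect_equal(dim(co$x), c(12, 2))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.scca")
  expect_equal(nrow(sm$modes), 2)
  expect_output(print(fit), "mode 1")

  pr <- predict(fit, newx = g$x, newy = g$y)
  expect_equal(stats::cor(pr$x[, 1], pr$y[, 1]), fit$modes[[1]]$r,
               tolerance = 1e-8)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))

  expect_error(scca(g$x, g$y[-1, ], allow_small = TRUE),
               class = "alignment_error")
})

test_that("appended null indicator columns get negligible weight", {
  withr::with_seed(72, {
    x <- matrix(stats::rnorm(80 * 10), 80, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- matrix(stats::rnorm(80 * 8), 80, 8)
    diagnosis <- sample(c(0, 1), 80, replace = TRUE)
  })
  fit <- scca(x, y, n_perm = 60, seed = 2, allow_small = TRUE, k_max = 1,
              append = cbind(diagnosis = diagnosis))
  w <- abs(fit$modes[[1]]$u)
  expect_true("diagnosis" %in% names(w))  # exempt from the majority filter
  # the diagnosis indicator should not dominate a null model
  expect_lt(w[["diagnosis"]], max(w))
})
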