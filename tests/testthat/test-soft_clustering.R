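test_that("unexpressed-gene filter removes exactly the all-zero rows", {
  x <- tiny_expression(5, 4)
  vals <- unclass(x)
  vals["g3", ] <- 0
  x <- expression_matrix(vals, "sp")
  f <- filter_unexpressed(x)
  expect_identical(f$removed_count, 1L)
  expect_identical(rownames(f$matrix), c("g1", "g2", "g4", "g5"))
  f2 <- filter_unexpressed(f$matrix)
  expect_identical(f2$removed_count, 0L)
  expect_identical(unclass(f2$matrix), unclass(f$matrix))
  allzero <- expression_matrix(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                               c("s1", "s2"))), "sp")
  expect_error(filter_unexpressed(allzero), "nothing to cluster")
})

test_that("standardization gives mean-0 sd-1 rows and flags constant rows", {
  x <- expression_matrix(matrix(c(1, 5, 2, 5, 3, 5), 2, 3,
                                dimnames = list(c("g1", "gflat"),
                                                paste0("s", 1:3))), "sp")
  expect_warning(std <- standardize(x), "zero-variance")
  expect_equal(unname(unclass(std)["g1", ]), c(-1, 0, 1))
  expect_equal(unname(unclass(std)["gflat", ]), c(0, 0, 0))

  set.seed(1)
  big <- expression_matrix(matrix(rexp(200 * 6), 200, 6,
                                  dimnames = list(sprintf("g%03d", 1:200),
                                                  paste0("s", 1:6))), "sp")
  std <- standardize(big)
  expect_true(all(abs(rowMeans(std)) < 1e-12))
  expect_true(all(abs(apply(std, 1, sd) - 1) < 1e-12))
})

test_that("fuzzy c-means keeps memberships normalized and the objective monotone", {
  p <- generate_species_pair(n_genes = 120, noise_sd = 0.3, seed = 21)
  std <- standardize(p$matrix_a)
  fit <- fuzzy_cmeans(std, k = 4, seed = 21)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  expect_true(all(diff(fit$objective_trace) <= 1e-8 * fit$objective_trace[1]))
  expect_true(fit$converged)
  expect_identical(unname(fit$hard_labels),
                   unname(max.col(fit$memberships, ties.method = "first")))
})

test_that("well-separated planted archetypes are recovered perfectly", {
  skip_if_not_installed("mclust")
  p <- generate_species_pair(n_genes = 200, n_archetypes = 2, frac_shifted = 0,
                             noise_sd = 0.05, seed = 22)
  std <- standardize(p$matrix_a)
  fit <- fuzzy_cmeans(std, k = 2, m = 1.25, seed = 22)
  ari <- mclust::adjustedRandIndex(fit$hard_labels, p$truth$archetype)
  expect_equal(ari, 1)
})

test_that("duplicated profiles separate into crisp memberships", {
  vals <- rbind(matrix(rep(c(1, 0, 0, 0), each = 5), 5, 4),
                matrix(rep(c(0, 0, 0, 1), each = 5), 5, 4))
  dimnames(vals) <- list(sprintf("g%02d", 1:10), paste0("s", 1:4))
  x <- structure(vals, species_id = "sp",
                 class = c("ExpressionMatrix", class(vals)))
  fit <- fuzzy_cmeans(x, k = 2, m = 1.25, seed = 1)
  crisp <- pmax(fit$memberships[, 1], fit$memberships[, 2])
  expect_true(all(crisp > 0.99))
  expect_identical(length(unique(fit$hard_labels[1:5])), 1L)
  expect_identical(length(unique(fit$hard_labels[6:10])), 1L)
})

test_that("a huge fuzzifier drives all memberships to 1/k", {
  # convergence to the uniform membership is O(1/m) with a data-dependent
  # constant; m = 400 sits well inside the asymptotic regime here
  p <- generate_species_pair(n_genes = 80, seed = 23)
  std <- standardize(p$matrix_a)
  fit <- fuzzy_cmeans(std, k = 4, m = 400, seed = 23)
  expect_true(all(abs(fit$memberships - 1 / 4) < 0.01))
  # and the deviation shrinks as m grows
  dev50 <- max(abs(fuzzy_cmeans(std, k = 4, m = 50, seed = 23)$memberships - 0.25))
  dev400 <- max(abs(fit$memberships - 0.25))
  expect_lt(dev400, dev50)
})

test_that("m near 1 recovers hard k-means labels on separated data", {
  p <- generate_species_pair(n_genes = 150, n_archetypes = 3, noise_sd = 0.1,
                             frac_shifted = 0, seed = 24)
  std <- standardize(p$matrix_a)
  fit <- fuzzy_cmeans(std, k = 3, m = 1.05, seed = 24)
  set.seed(24)
  km <- stats::kmeans(unclass(std), centers = 3, nstart = 10)
  # same partition up to label permutation
  expect_identical(length(unique(paste(fit$hard_labels, km$cluster))), 3L)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  p <- generate_species_pair(n_genes = 100, n_archetypes = 3, noise_sd = 0.15,
                             frac_shifted = 0, seed = 25)
  std <- standardize(p$matrix_a)
  init <- unclass(std)[c(1, 2, 3), , drop = FALSE]
  # seed both from identical explicit centers: same fixed point expected
  ours <- fuzzy_cmeans(std, k = 3, m = 1.5, centers = init, tol = 1e-9)
  ref <- e1071::cmeans(unclass(std), centers = init, m = 1.5,
                       iter.max = 1000, method = "cmeans")
  perm <- apply(ours$centroids, 1, function(v)
    which.min(colSums((t(ref$centers) - v)^2)))
  expect_identical(sort(perm), 1:3)
  expect_equal(unname(ours$memberships[, order(perm)]),
               unname(ref$membership), tolerance = 1e-4)
})

test_that("permutation of rows permutes memberships with fixed initial centers", {
  p <- generate_species_pair(n_genes = 60, seed = 26)
  std <- standardize(p$matrix_a)
  init <- unclass(std)[c(5, 25, 45), , drop = FALSE]
  fit1 <- fuzzy_cmeans(std, k = 3, centers = init)
  perm <- sample(nrow(std))
  permuted <- structure(unclass(std)[perm, ], species_id = "sp",
                        class = class(std))
  fit2 <- fuzzy_cmeans(permuted, k = 3, centers = init)
  expect_equal(fit2$memberships, fit1$memberships[perm, ], tolerance = 1e-9)
})

test_that("Calinski-Harabasz matches hand evaluation and flags degeneracy", {
  x <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(calinski_harabasz(x, c(1, 1, 2, 2)), 200)
  # every cluster internally constant -> +Inf sentinel
  xc <- matrix(c(0, 0, 5, 5), 4, 1)
  expect_identical(calinski_harabasz(xc, c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(x, c(1, 1, 1, 1)), "2 non-empty")
})

test_that("planted labels out-score random labels on separated data", {
  set.seed(31)
  wins <- 0L
  for (i in 1:25) {
    p <- generate_species_pair(n_genes = 80, n_archetypes = 3, noise_sd = 0.2,
                               frac_shifted = 0, seed = 100 + i)
    std <- unclass(standardize(p$matrix_a))
    ch_true <- calinski_harabasz(std, p$truth$archetype)
    ch_rand <- calinski_harabasz(std, sample(p$truth$archetype))
    wins <- wins + (ch_true > ch_rand)
  }
  expect_identical(wins, 25L)
})

test_that("k selection is deterministic and honors trivial ranges", {
  p <- generate_species_pair(n_genes = 100, seed = 27)
  std <- standardize(p$matrix_a)
  ks1 <- select_k(std, 2:6, seed = 7)
  ks2 <- select_k(std, 2:6, seed = 7)
  expect_identical(ks1$ch_scores, ks2$ch_scores)
  expect_identical(ks1$chosen_k, ks2$chosen_k)
  expect_identical(select_k(std, 3, seed = 7)$chosen_k, 3L)
  expect_error(select_k(std, integer(0)), "non-empty")
  expect_error(select_k(std, 1:3), "k_range")
})
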