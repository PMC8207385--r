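test_that("genotype encoding is one-hot over two copies", {
  tb <- toy_diploid()
  X <- encode_genotypes(tb)
  # i2 homozygous 100/100 at L1 -> (1, 0, ...) over L1 alleles
  l1 <- attr(X, "locus") == "L1"
  expect_equal(unname(X[2, which(l1)[1]]), 1)
  expect_equal(unname(rowSums(X[, l1, drop = FALSE])[1]), 1)  # block sums 1
  expect_equal(unname(X[1, "L1.100"]), 0.5)   # heterozygote
  expect_equal(unname(X[1, "L1.102"]), 0.5)
  expect_true(all(is.na(X[7, l1])))           # missing locus masked
  expect_equal(unname(rowSums(X[, !l1, drop = FALSE])), rep(1, 8))
})

test_that("K = 1 fit: Q all ones, G approaches column means", {
  d <- simulate_dataset(n_demes = 2, n_per_deme = 10, n_nssr = 4, seed = 51)
  X <- encode_genotypes(d$nuclear)
  fit <- fit_ancestry(X, cbind(d$nuclear$lat, d$nuclear$lon), K = 1,
                      seed = 1)
  expect_true(all(fit$Q == 1))
  expect_equal(as.numeric(fit$G), unname(colMeans(X)), tolerance = 1e-3)
})

test_that("objective is monotonically nonincreasing and rows stay on simplex", {
  d <- simulate_dataset(n_demes = 3, n_per_deme = 10, n_nssr = 8, seed = 52)
  X <- encode_genotypes(d$nuclear)
  fit <- fit_ancestry(X, cbind(d$nuclear$lat, d$nuclear$lon), K = 3,
                      lambda = 1, seed = 2)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-9)
  expect_true(all(fit$Q >= -1e-12))
  expect_true(all(fit$G >= -1e-12 & fit$G <= 1 + 1e-12))
})

test_that("large lambda shrinks ancestry rows toward a common membership", {
  d <- simulate_dataset(n_demes = 2, n_per_deme = 12, n_nssr = 6,
                        target_fst = 0.2, seed = 53)
  X <- encode_genotypes(d$nuclear)
  coords <- cbind(d$nuclear$lat, d$nuclear$lon)
  spread <- function(fit) mean(apply(fit$Q, 2, sd))
  s0 <- spread(fit_ancestry(X, coords, 2, lambda = 0, seed = 3))
  s9 <- spread(fit_ancestry(X, coords, 2, lambda = 1e4, seed = 3))
  expect_lt(s9, s0 / 4)
})

test_that("lambda = 0 matches an alternating least-squares baseline", {
  set.seed(54)
  d <- simulate_dataset(n_demes = 2, n_per_deme = 8, n_nssr = 5, seed = 54)
  X <- encode_genotypes(d$nuclear)
  keep <- !apply(is.na(X), 1, any)
  X <- X[keep, , drop = FALSE]
  fit <- fit_ancestry(X, matrix(rnorm(2 * nrow(X)), ncol = 2), 2,
                      lambda = 0, seed = 4, max_iter = 400, tol = 1e-9)
  rss <- function(Q, G) sum((X - Q %*% G)^2)
  # baseline: projected ALS with many restarts, written independently here
  best <- Inf
  for (r in 1:5) {
    Q <- matrix(runif(nrow(X) * 2), ncol = 2); Q <- Q / rowSums(Q)
    G <- matrix(runif(2 * ncol(X)), 2)
    for (it in 1:300) {
      G <- pmax(pmin(solve(t(Q) %*% Q + 1e-8 * diag(2), t(Q) %*% X), 1), 0)
      for (i in seq_len(nrow(X))) {
        q <- solve(G %*% t(G) + 1e-8 * diag(2), G %*% X[i, ])
        q <- pmax(q, 0); s <- sum(q)
        Q[i, ] <- if (s > 0) q / s else rep(0.5, 2)
      }
    }
    best <- min(best, rss(Q, G))
  }
  expect_lt(rss(fit$Q, fit$G), best * 1.05)
})

test_that("permuting individuals permutes Q rows (up to cluster relabeling)", {
  d <- simulate_dataset(n_demes = 3, n_per_deme = 8, n_nssr = 10,
                        target_fst = 0.25, seed = 55)
  X <- encode_genotypes(d$nuclear)
  coords <- cbind(d$nuclear$lat, d$nuclear$lon)
  fit1 <- fit_ancestry(X, coords, 3, seed = 5)
  set.seed(6)
  perm <- sample(nrow(X))
  fit2 <- fit_ancestry(X[perm, ], coords[perm, ], 3, seed = 5)
  Q1 <- fit1$Q[perm, ]
  Q2 <- fit2$Q
  # match columns by best correlation, then compare
  remap <- apply(cor(Q1, Q2), 1, which.max)
  expect_equal(length(unique(remap)), 3)
  expect_lt(mean(abs(Q1 - Q2[, remap])), 0.08)
})

test_that("select_k: panmictic K = 1, masking fraction 0 errors, K capped", {
  d <- simulate_dataset(n_demes = 1, n_per_deme = 24, n_nssr = 12,
                        target_fst = 0, seed = 56)
  X <- encode_genotypes(d$nuclear)
  coords <- cbind(d$nuclear$lat, d$nuclear$lon)
  expect_error(select_k(X, coords, 1:2, mask_fraction = 0), "> 0")
  cv <- select_k(X, coords, 1:3, replicates = 4, seed = 7)
  expect_equal(cv$chosen_k, 1)
  expect_true(all(cv$errors >= 0))
  expect_error(select_k(X, coords, 500), "exceed")
})

test_that("IDW interpolation: constant field, exact at sample points", {
  d <- simulate_dataset(n_demes = 2, n_per_deme = 6, n_nssr = 4, seed = 57)
  X <- encode_genotypes(d$nuclear)
  coords <- cbind(d$nuclear$lat, d$nuclear$lon)
  fit <- fit_ancestry(X, coords, 2, seed = 8)
  grid <- list(nrow = 5, ncol = 5, lat_range = range(coords[, 1]),
               lon_range = range(coords[, 2]))
  # constant Q -> constant raster
  fitc <- fit
  fitc$Q <- matrix(0.5, nrow(fit$Q), 2)
  r <- interpolate_ancestry(fitc, coords, grid)
  expect_true(all(abs(r$layers[[1]]$values - 0.5) < 1e-12))
  # grid node coincident with a sample -> exactly that sample's Q
  grid2 <- list(nrow = 2, ncol = 2,
                lat_range = c(coords[1, 1], coords[1, 1] + 1),
                lon_range = c(coords[1, 2], coords[1, 2] + 1))
  r2 <- interpolate_ancestry(fit, coords, grid2)
  expect_equal(r2$layers[[1]]$values[2, 1], fit$Q[1, 1])
  expect_error(interpolate_ancestry(fit, coords,
                                    list(nrow = 0, ncol = 3,
                                         lat_range = 0:1,
                                         lon_range = 0:1)),
               "empty")
})
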