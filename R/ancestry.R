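# Geographically regularized ancestry estimation.
#
# The model factorizes the one-hot genotype frequency matrix X (individuals x
# encoded alleles, entries in {0, 1/2, 1}) as Q G, with Q the individuals x K
# ancestry coefficients (rows on the simplex) and G the K x alleles cluster
# allele frequencies (in [0, 1]).  Geography enters through a graph-Laplacian
# penalty: minimize ||M o (X - QG)||^2 + lambda * tr(Q' L Q), where L is the
# *normalized* Laplacian of the heat-kernel similarity
# W_ij = exp(-(d_ij/sigma)^2) with sigma the mean pairwise great-circle
# distance, and M masks missing entries.  The normalized Laplacian keeps the
# penalty O(n) like the data term, so lambda = 1 is a mild default instead of
# overwhelming the likelihood as a raw Laplacian (O(n^2)) would.
# Optimization is block projected-gradient descent with Lipschitz step sizes,
# which makes the objective monotonically nonincreasing (asserted); Q starts
# from k-means on the zero-filled encoding (random fallback).

great_circle_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

pairwise_gc_km <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- great_circle_km(coords[i, 1], coords[i, 2],
                              coords[, 1], coords[, 2])
  d
}

#' One-hot frequency encoding of a diploid genotype table
#'
#' `X[i, (locus, allele)]` is the number of copies of the allele in
#' individual i divided by 2 (0, 0.5 or 1).  Entries of loci missing in an
#' individual are `NA` and are masked during fitting.
#'
#' @param table diploid `genotype_table`.
#' @return Numeric matrix with an attribute `locus` mapping columns to loci.
#' @export
encode_genotypes <- function(table) {
  if (table$ploidy != 2L) stop("encode_genotypes needs a diploid table")
  blocks <- lapply(seq_len(n_loci(table)), function(l) {
    g <- locus_alleles(table, l)
    alleles <- sort(unique(as.vector(g[g != MISSING_ALLELE])))
    x <- matrix(0, n_ind(table), length(alleles),
                dimnames = list(table$ind,
                                paste0(table$loci[l], ".", alleles)))
    for (j in seq_along(alleles))
      x[, j] <- (g[, 1] == alleles[j]) + (g[, 2] == alleles[j])
    x <- x / 2
    x[g[, 1] == MISSING_ALLELE | g[, 2] == MISSING_ALLELE, ] <- NA_real_
    x
  })
  X <- do.call(cbind, blocks)
  attr(X, "locus") <- rep(table$loci,
                          vapply(blocks, ncol, integer(1)))
  X
}

project_simplex <- function(v) {
  # Euclidean projection of each row of v onto the probability simplex
  if (ncol(v) == 1L) return(matrix(1, nrow(v), 1))
  t(apply(v, 1, function(y) {
    u <- sort(y, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u - (css - 1) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(y - theta, 0)
  }))
}

ancestry_objective <- function(X, M, Q, G, lambda, L) {
  R <- (X - Q %*% G)
  R[!M] <- 0
  sum(R^2) + lambda * sum(diag(t(Q) %*% L %*% Q))
}

#' Fit geographically regularized ancestry coefficients
#'
#' @param X encoded genotype matrix from [encode_genotypes()] (`NA` =
#'   missing, masked).
#' @param coords individuals x 2 matrix of (lat, lon) in decimal degrees.
#' @param K number of ancestral clusters (>= 1).
#' @param lambda spatial regularization weight (default 1).
#' @param seed RNG seed for the random start.
#' @param max_iter maximum outer sweeps.
#' @param tol stop when the relative objective change drops below this.
#' @param inner projected-gradient steps per block per sweep.
#' @return An `ancestry_fit`: `Q`, `G`, `K`, `lambda`, `objective` (trace,
#'   nonincreasing), `converged`, `seed`.
#' @export
fit_ancestry <- function(X, coords, K, lambda = 1, seed = 1, max_iter = 200,
                         tol = 1e-6, inner = 10) {
  set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  coords <- as.matrix(coords)
  if (nrow(coords) != n) stop("coords must align with X rows")
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0

  d <- pairwise_gc_km(coords)
  sigma <- mean(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  W <- exp(-(d / sigma)^2)
  diag(W) <- 0
  dsc <- 1 / sqrt(pmax(rowSums(W), 1e-12))
  L <- diag(n) - (dsc %o% dsc) * W  # normalized Laplacian

  if (K == 1) {
    Q <- matrix(1, n, 1)
    G <- matrix(runif(K * p), K, p)
  } else {
    km <- tryCatch(suppressWarnings(
      stats::kmeans(X0, centers = K, nstart = 5)),
      error = function(e) NULL)
    if (!is.null(km)) {
      Q <- matrix(0.5 / (K - 1), n, K)
      Q[cbind(seq_len(n), km$cluster)] <- 0.5
      Q <- Q / rowSums(Q)
      G <- pmax(pmin(km$centers, 1), 0)
    } else {
      Q <- project_simplex(matrix(runif(n * K), n, K))
      G <- matrix(runif(K * p), K, p)
    }
  }

  obj <- ancestry_objective(X0, M, Q, G, lambda, L)
  trace <- obj
  lip_L <- max(rowSums(abs(L)))  # bound on ||L||_2
  for (it in seq_len(max_iter)) {
    # G-step: box-constrained least squares by projected gradient
    step_g <- 1 / (2 * max(1e-12, norm(Q, "F")^2))
    for (s in seq_len(inner)) {
      R <- (Q %*% G - X0); R[!M] <- 0
      G <- pmax(pmin(G - step_g * 2 * (t(Q) %*% R), 1), 0)
    }
    # Q-step: simplex-projected gradient
    step_q <- 1 / (2 * max(1e-12, norm(G, "F")^2 + lambda * lip_L))
    for (s in seq_len(inner)) {
      R <- (Q %*% G - X0); R[!M] <- 0
      grad <- 2 * (R %*% t(G)) + 2 * lambda * (L %*% Q)
      Q <- project_simplex(Q - step_q * grad)
    }
    new_obj <- ancestry_objective(X0, M, Q, G, lambda, L)
    if (!is.finite(new_obj)) stop("non-finite objective; aborting")
    if (new_obj > obj + 1e-8 * max(1, obj))
      stop("objective increased; step-size bound violated")
    trace <- c(trace, new_obj)
    done <- (obj - new_obj) <= tol * max(1, obj)
    obj <- new_obj
    if (done) break
  }
  dimnames(Q) <- NULL
  dimnames(G) <- NULL
  structure(list(Q = Q, G = G, K = K, lambda = lambda, objective = trace,
                 converged = it < max_iter, seed = seed, sigma = sigma,
                 coords = coords),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, lambda = %g, objective %.4f after %d sweeps (%s)\n",
              x$K, x$lambda, x$objective[length(x$objective)],
              length(x$objective) - 1,
              if (x$converged) "converged" else "max_iter"))
  invisible(x)
}

#' Cross-validated choice of the number of clusters K
#'
#' Per replicate, a fraction of the observed entries of X is masked, the
#' model refitted, and the root-mean-square error between `Q G` and the
#' held-out entries recorded.  The chosen K is the smallest K whose median
#' error lies within one standard error of the global minimum median (an
#' operationalization of "lowest value before the curve plateaus").
#'
#' @param X encoded genotype matrix.
#' @param coords (lat, lon) matrix.
#' @param K_range candidate K values.
#' @param mask_fraction fraction of observed entries masked per replicate
#'   (default 0.05, must be > 0).
#' @param replicates replicates per K (default 100).
#' @param lambda,max_iter,tol passed to [fit_ancestry()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return A `cv_curve`: `errors` (K x replicate matrix), `median` per K,
#'   `chosen_k`, `best_k` (argmin median), `mask_fraction`.
#' @export
select_k <- function(X, coords, K_range, mask_fraction = 0.05,
                     replicates = 100, lambda = 1, max_iter = 60,
                     tol = 1e-5, seed = 1) {
  if (!length(K_range)) stop("K_range is empty")
  if (mask_fraction <= 0) stop("mask_fraction must be > 0")
  X <- as.matrix(X)
  n <- nrow(X)
  K_range <- K_range[K_range <= n]
  if (!length(K_range)) stop("all K exceed the number of individuals")
  obs_idx <- which(!is.na(X))
  errors <- matrix(NA_real_, length(K_range), replicates,
                   dimnames = list(paste0("K", K_range), NULL))
  for (r in seq_len(replicates)) {
    set.seed(seed * 1000L + r)
    mask <- sample(obs_idx, max(1, round(mask_fraction * length(obs_idx))))
    Xm <- X
    Xm[mask] <- NA_real_
    for (ki in seq_along(K_range)) {
      fit <- fit_ancestry(Xm, coords, K_range[ki], lambda = lambda,
                          seed = seed * 1000L + r, max_iter = max_iter,
                          tol = tol)
      pred <- fit$Q %*% fit$G
      errors[ki, r] <- sqrt(mean((pred[mask] - X[mask])^2))
    }
  }
  med <- apply(errors, 1, median)
  best <- which.min(med)
  se_best <- sd(errors[best, ]) / sqrt(replicates)
  chosen <- K_range[min(which(med <= med[best] + se_best))]
  structure(list(K_range = K_range, errors = errors, median = med,
                 chosen_k = chosen, best_k = K_range[best],
                 mask_fraction = mask_fraction, replicates = replicates),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("cross-validation curve (masked-entry RMSE):\n")
  print(round(x$median, 4))
  cat("chosen K =", x$chosen_k, "(argmin K =", x$best_k, ")\n")
  invisible(x)
}

#' Interpolate ancestry coefficients onto a raster grid
#'
#' Inverse-distance-weighted interpolation of each Q column; a grid cell
#' coincident with a sample point takes exactly that sample's coefficients.
#'
#' @param fit an `ancestry_fit`.
#' @param coords sample (lat, lon) matrix used in the fit.
#' @param grid list with `nrow`, `ncol`, `lat_range`, `lon_range`.
#' @param power IDW power (default 2).
#' @return List of K rasters (one per cluster) plus an `argmax` raster of the
#'   dominant cluster index.
#' @export
interpolate_ancestry <- function(fit, coords, grid, power = 2) {
  if (grid$nrow < 1 || grid$ncol < 1) stop("empty grid")
  lat_seq <- seq(grid$lat_range[2], grid$lat_range[1],
                 length.out = grid$nrow)  # row 0 = north edge
  lon_seq <- seq(grid$lon_range[1], grid$lon_range[2],
                 length.out = grid$ncol)
  K <- fit$K
  layers <- lapply(seq_len(K), function(k)
    matrix(NA_real_, grid$nrow, grid$ncol))
  for (i in seq_len(grid$nrow)) for (j in seq_len(grid$ncol)) {
    d <- great_circle_km(lat_seq[i], lon_seq[j], coords[, 1], coords[, 2])
    hit <- which(d < 1e-9)
    if (length(hit)) {
      wq <- fit$Q[hit[1], ]
    } else {
      w <- 1 / d^power
      wq <- as.numeric(t(fit$Q) %*% w / sum(w))
    }
    for (k in seq_len(K)) layers[[k]][i, j] <- wq[k]
  }
  cellsize <- diff(grid$lon_range) / max(1, grid$ncol - 1)
  rasters <- lapply(layers, function(m)
    raster_grid(m, xll = grid$lon_range[1], yll = grid$lat_range[1],
                cellsize = cellsize))
  am <- matrix(0L, grid$nrow, grid$ncol)
  for (i in seq_len(grid$nrow)) for (j in seq_len(grid$ncol))
    am[i, j] <- which.max(vapply(layers, function(m) m[i, j], numeric(1)))
  list(layers = rasters,
       argmax = raster_grid(am, xll = grid$lon_range[1],
                            yll = grid$lat_range[1], cellsize = cellsize))
}
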