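test_that("spatial thinning keeps stable-order representatives", {
  two <- data.frame(lat = c(0, 0.045), lon = c(0, 0))  # ~5 km apart
  expect_equal(nrow(thin_occurrences(two, 10)), 1)
  far <- data.frame(lat = c(0, 0.2, 0.4), lon = 0)     # ~22 km spacing
  expect_equal(nrow(thin_occurrences(far, 10)), 3)     # identity
  # 5 clustered within 10 km + 1 isolated -> 2 kept
  pts <- data.frame(lat = c(0, 0.01, 0.02, 0.03, 0.04, 1),
                    lon = c(0, 0.01, 0.02, 0.01, 0, 1))
  expect_equal(nrow(thin_occurrences(pts, 10)), 2)
})

test_that("correlated-variable selection drops the more specific member", {
  set.seed(61)
  base <- matrix(rnorm(100), 10, 10)
  r1 <- raster_grid(base)
  r2 <- raster_grid(base + rnorm(100, 0, 0.05))   # near-duplicate
  r3 <- raster_grid(matrix(rnorm(100), 10, 10))   # independent
  kept <- select_uncorrelated_variables(
    list(a = r1, b = r2, c = r3), specificity = c(a = 1, b = 2, c = 3))
  expect_equal(sort(kept), c("a", "c"))            # b is more specific
  # orthogonal checkerboards are both kept
  cb1 <- raster_grid(matrix(rep(c(0, 1), 50), 10, 10))
  cb2 <- raster_grid(matrix(rep(c(0, 0, 1, 1), 25), 10, 10))
  expect_equal(sort(select_uncorrelated_variables(
    list(x = cb1, y = cb2), c(1, 2))), c("x", "y"))
  r_small <- raster_grid(matrix(0, 3, 3))
  expect_error(select_uncorrelated_variables(list(a = r1, b = r_small),
                                             c(1, 2)), "misaligned")
})

test_that("TRI: flat zero, hand case, nodata masking", {
  expect_true(all(tri(raster_grid(matrix(7, 5, 5)))$values == 0))
  dem <- raster_grid(matrix(c(9, 9, 9, 9, 10, 9, 9, 9, 9), 3, byrow = TRUE))
  expect_equal(tri(dem)$values[2, 2], sqrt(8))
  # nodata neighbour excluded from the sum; nodata cell propagates
  z <- matrix(9, 3, 3); z[1, 1] <- NA; z[2, 2] <- 10
  trir <- tri(raster_grid(z))
  expect_equal(trir$values[2, 2], sqrt(7))
  expect_true(is.na(trir$values[1, 1]))
  expect_error(tri(raster_grid(matrix(NA_real_, 3, 3))), "nodata")
})

test_that("Fisher-Jenks breaks: exhaustive small case, invariances", {
  br <- jenks_breaks(c(1, 2, 100, 101), 2)
  expect_equal(br, c(1, 2, 101))                  # split between 2 and 100
  expect_equal(jenks_breaks(c(5, 1, 9), 1), c(1, 9))
  set.seed(62)
  v <- rnorm(200)
  expect_equal(jenks_breaks(v, 5), jenks_breaks(sample(v), 5))
  expect_warning(br2 <- jenks_breaks(c(1, 1, 2, 2), 3), "reduced")
  expect_length(br2, 3)
  # oracle: exhaustive search over all 2-class splits of a small vector
  x <- sort(c(0.2, 1.1, 1.3, 4.0, 4.2, 9.0))
  ssd <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best <- which.min(vapply(1:5, function(cut)
    ssd(x[1:cut]) + ssd(x[(cut + 1):6]), numeric(1)))
  expect_equal(jenks_breaks(x, 2)[2], x[best])
})

test_that("suitability rescaling matches the threshold formula", {
  r <- raster_grid(matrix(c(0, 0.1, 0.4, 0.9), 2, 2))
  out <- rescale_suitability(r, 0.4)
  expect_equal(sort(as.vector(out$values)), c(0, 25, 100, 100))
  expect_error(rescale_suitability(r, 0), "> 0")
  # monotone nondecreasing in v
  v <- seq(0, 1, by = 0.01)
  resc <- rescale_suitability(raster_grid(matrix(v, 1)), 0.37)$values
  expect_true(all(diff(as.vector(resc)) >= -1e-12))
})

test_that("habitat combination is a weighted mean with alignment checks", {
  a <- raster_grid(matrix(100, 4, 4))
  b <- raster_grid(matrix(0, 4, 4))
  expect_true(all(combine_habitat(a, a)$values == 100))      # identity
  expect_true(all(combine_habitat(a, b)$values == 50))
  expect_true(all(combine_habitat(a, b, c(1, 0))$values == 100))
  expect_error(combine_habitat(a, raster_grid(matrix(0, 3, 3))),
               "misaligned")
})

test_that("patch extraction: threshold, 8-connectivity, moving window", {
  expect_equal(nrow(extract_patches(raster_grid(matrix(100, 6, 6)))$patches),
               1)
  # two blocks separated by a sub-threshold corridor
  m <- matrix(80, 5, 5); m[, 3] <- 10
  ps <- extract_patches(raster_grid(m), 50)
  expect_equal(nrow(ps$patches), 2)
  expect_equal(ps$patches$area_km2, c(10, 10))
  # diagonal touching merges under 8-connectivity
  md <- matrix(0, 4, 4); md[1, 1] <- 100; md[2, 2] <- 100
  expect_equal(nrow(extract_patches(raster_grid(md), 50)$patches), 1)
  # moving-window mean can bridge a one-cell gap
  mw <- matrix(c(100, 0, 100), 1)
  expect_equal(nrow(extract_patches(raster_grid(mw), 50,
                                    window_cells = 2)$patches), 1)
  expect_warning(e <- extract_patches(raster_grid(matrix(0, 3, 3)), 50),
                 "no habitat")
  expect_equal(nrow(e$patches), 0)
})

test_that("least-cost distances: symmetry, uniform-resistance geometry", {
  # uniform habitat 100 -> resistance 1; two 1-cell patches on one row
  h <- matrix(0, 5, 7); h[3, 1] <- 100; h[3, 7] <- 100
  hab <- raster_grid(h)
  ps <- extract_patches(hab, 50)
  res <- raster_grid(matrix(1, 5, 7))   # uniform resistance 1
  d <- least_cost_distances(res, ps)
  expect_equal(d[1, 2], 6)              # 6 rook steps at mean resistance 1
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # doubling resistance doubles the distance
  d2 <- least_cost_distances(raster_grid(matrix(2, 5, 7)), ps)
  expect_equal(d2[1, 2], 12)
  # cost threshold marks far patches unreachable
  d3 <- least_cost_distances(res, ps, cost_threshold = 3)
  expect_true(is.infinite(d3[1, 2]))
  expect_error(least_cost_distances(raster_grid(matrix(0, 5, 7)), ps),
               "> 0")
})

test_that("Dijkstra equals brute-force path enumeration on small grids", {
  # independent oracle: recursive enumeration of all simple paths
  brute_lcd <- function(r, from, to) {
    nr <- nrow(r); nc <- ncol(r)
    best <- Inf
    rec <- function(i, j, visited, cost) {
      if (cost >= best) return()
      if (i == to[1] && j == to[2]) { best <<- min(best, cost); return() }
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- i + di; nj <- j + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (visited[ni, nj]) next
        step <- (r[i, j] + r[ni, nj]) / 2 *
          (if (di != 0 && dj != 0) sqrt(2) else 1)
        visited[ni, nj] <- TRUE
        rec(ni, nj, visited, cost + step)
        visited[ni, nj] <- FALSE
      }
    }
    v0 <- matrix(FALSE, nr, nc); v0[from[1], from[2]] <- TRUE
    rec(from[1], from[2], v0, 0)
    best
  }
  set.seed(63)
  for (rep in 1:4) {
    dims <- sample(3:4, 2, replace = TRUE)
    r <- matrix(sample(1:50, prod(dims), TRUE), dims[1], dims[2])
    h <- matrix(0, dims[1], dims[2])
    h[1, 1] <- 100; h[dims[1], dims[2]] <- 100
    ps <- extract_patches(raster_grid(h), 50)
    d <- least_cost_distances(raster_grid(r), ps)
    expect_equal(d[1, 2], brute_lcd(r, c(1, 1), dims), tolerance = 1e-9)
  }
})

test_that("ECA: closed forms, bounds, path upgrading, monotonicity", {
  expect_equal(eca(data.frame(area_km2 = 7), matrix(0, 1, 1))$eca, 7)
  expect_equal(eca(data.frame(area_km2 = c(1, 1)),
                   matrix(c(0, Inf, Inf, 0), 2))$eca, sqrt(2))
  # two patches areas 2, 3 with p* = 0.5 at d = 1
  expect_equal(eca(data.frame(area_km2 = c(2, 3)),
                   matrix(c(0, 1, 1, 0), 2))$eca, sqrt(19))
  expect_error(eca(data.frame(area_km2 = 1), matrix(0, 1, 1), d_ref = 0),
               "> 0")
  # max-product upgrade: stepping-stone path beats the direct edge
  d <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3)
  a <- data.frame(area_km2 = c(1, 1, 1))
  full <- eca(a, d)
  direct <- eca(a, d, direct_only = TRUE)
  expect_gt(full$eca, direct$eca)
  expect_equal(full$p[1, 3], 0.25)   # exp(-alpha * 2) = 0.5^2
  # bounds and monotonicity on random instances
  set.seed(64)
  for (rep in 1:10) {
    np <- sample(2:6, 1)
    areas <- runif(np, 1, 5)
    dm <- matrix(runif(np^2, 0.5, 8), np); dm <- (dm + t(dm)) / 2
    diag(dm) <- 0
    e <- eca(data.frame(area_km2 = areas), dm)$eca
    expect_gte(e + 1e-9, sqrt(sum(areas^2)))
    expect_lte(e, sum(areas) + 1e-9)
    # decreasing any distance never decreases ECA
    dm2 <- dm * 0.5
    expect_gte(eca(data.frame(area_km2 = areas), dm2)$eca + 1e-9, e)
    # adding a patch never decreases ECA
    e3 <- eca(data.frame(area_km2 = c(areas, 1)),
              rbind(cbind(dm, 5), c(rep(5, np), 0)))$eca
    expect_gte(e3 + 1e-9, e)
  }
})

test_that("area by elevation bins partitions the total area", {
  dem <- raster_grid(matrix(1500, 4, 5), cellsize = 2)  # cell area 4 km^2
  tab <- area_by_elevation_bin(dem)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$area_km2, 20 * 4)
  z <- matrix(c(rep(100, 6), rep(250, 6)), 3, 4)
  tab2 <- area_by_elevation_bin(raster_grid(z), bin = 100)
  expect_equal(tab2$n_cells[tab2$elev_lo == 100], 6)
  expect_equal(tab2$n_cells[tab2$elev_lo == 200], 6)
  expect_equal(sum(tab2$area_km2), 12)
  # mask restricts to a subregion
  msk <- matrix(FALSE, 3, 4); msk[, 1] <- TRUE
  expect_equal(sum(area_by_elevation_bin(raster_grid(z),
                                         mask = msk)$n_cells), 3)
})

test_that("ESRI ASCII grids round-trip with nodata", {
  set.seed(65)
  m <- matrix(rnorm(20), 4, 5)
  m[2, 3] <- NA
  r <- raster_grid(m, xll = -75.5, yll = 4.25, cellsize = 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$cellsize, 0.5)
  expect_equal(r2$xll, -75.5)
})
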