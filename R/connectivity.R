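# Landscape connectivity: habitat patches, least-cost graph, ECA.
#
# Resistance is 101 - habitat value (habitat on 0-100), so traversal cost is
# always positive.  Moving between adjacent cells costs the mean of their
# resistances times the step length (cellsize; sqrt(2) * cellsize for
# diagonals).  The equivalent connectivity area is
# ECA = sqrt(sum_ij a_i a_j p*_ij) with p*_ij the maximum product of direct
# dispersal probabilities p = exp(-alpha d) over graph paths; because
# -log p is additive, p* is computed as a shortest path on -log p edge
# weights (equivalently alpha * least-cost distance).

#' Greedy spatial thinning of occurrence records
#'
#' Iterates points in stable input order and keeps a point iff no previously
#' kept point lies within `radius_km` (great-circle).
#'
#' @param points data frame with `lat`, `lon` columns.
#' @param radius_km thinning radius (default 10 km).
#' @return The retained subset of `points`, original order.
#' @export
thin_occurrences <- function(points, radius_km = 10) {
  if (!nrow(points)) return(points)
  keep <- integer(0)
  for (i in seq_len(nrow(points))) {
    if (!length(keep)) { keep <- i; next }
    d <- great_circle_km(points$lat[i], points$lon[i],
                         points$lat[keep], points$lon[keep])
    if (all(d > radius_km)) keep <- c(keep, i)
  }
  points[keep, , drop = FALSE]
}

#' Drop pairwise-correlated variables, keeping the more general one
#'
#' Computes pairwise Pearson correlations over jointly valid cells and, while
#' any |r| exceeds `r_max`, removes the more specific member (larger
#' `specificity` rank) of the worst offending pair.
#'
#' @param rasters named list of aligned `oak_raster`s.
#' @param specificity numeric vector (same order/names): higher = more
#'   specific, dropped first.
#' @param r_max correlation threshold (default 0.7).
#' @return Character vector of retained raster names.
#' @export
select_uncorrelated_variables <- function(rasters, specificity,
                                          r_max = 0.7) {
  nm <- names(rasters)
  stopifnot(length(specificity) == length(rasters))
  for (i in seq_along(rasters)[-1])
    stop_if_misaligned(rasters[[1]], rasters[[i]])
  keep <- seq_along(rasters)
  vals <- vapply(rasters, function(r) as.vector(r$values),
                 numeric(length(rasters[[1]]$values)))
  repeat {
    if (length(keep) < 2) break
    cm <- suppressWarnings(cor(vals[, keep, drop = FALSE],
                               use = "pairwise.complete.obs"))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (max(abs(cm)) <= r_max) break
    pair <- keep[worst]
    drop <- pair[which.max(specificity[pair])]
    keep <- setdiff(keep, drop)
  }
  nm[keep]
}

#' Convert a habitat layer to a resistance layer
#' @param habitat an `oak_raster` on the 0-100 scale.
#' @return An `oak_raster` with resistance `101 - habitat` (range 1-101).
#' @export
resistance_from_habitat <- function(habitat) {
  raster_grid(101 - habitat$values, habitat$xll, habitat$yll,
              habitat$cellsize, habitat$nodata)
}

#' Extract habitat patches from a habitat layer
#'
#' A moving-window mean (square window of `2*window_cells - 1` cells on a
#' side; `window_cells = 1` means the raw cell value) at or above
#' `min_mean_value` defines habitat cells; patches are their 8-connected
#' components.  Habitat-mapping tools usually state the per-pixel threshold
#' of 0.5 on the 0-1 scale; on this module's 0-100 scale that is 50, the
#' default.
#'
#' @param habitat an `oak_raster` on the 0-100 scale.
#' @param min_mean_value habitat threshold (default 50).
#' @param window_cells moving-window half-size in cells (default 1 = raw).
#' @param min_area_cells drop patches smaller than this many cells.
#' @param cell_area_km2 per-cell area; default `cellsize^2`.
#' @return A `patch_set`: data frame `patches` (id, n_cells, area_km2,
#'   centroid row/col), list `cells` of cell-index matrices, and the
#'   logical habitat mask.
#' @export
extract_patches <- function(habitat, min_mean_value = 50, window_cells = 1,
                            min_area_cells = 1, cell_area_km2 = NULL) {
  v <- habitat$values
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(cell_area_km2)) cell_area_km2 <- habitat$cellsize^2
  w <- window_cells - 1L
  mv <- v
  if (w > 0) {
    mv <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      blk <- v[max(1, i - w):min(nr, i + w), max(1, j - w):min(nc, j + w)]
      mv[i, j] <- mean(blk, na.rm = TRUE)
    }
  }
  hab <- !is.na(mv) & mv >= min_mean_value
  if (!any(hab)) {
    warning("no habitat cells at threshold ", min_mean_value)
    return(structure(list(patches = data.frame(id = integer(0),
                                               n_cells = integer(0),
                                               area_km2 = numeric(0),
                                               centroid_row = numeric(0),
                                               centroid_col = numeric(0)),
                          cells = list(), mask = hab, habitat = habitat),
                     class = "patch_set"))
  }
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!hab[si, sj] || lab[si, sj] != 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(c(si, sj), 1)
    lab[si, sj] <- nextlab
    while (nrow(queue)) {
      cur <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (hab[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nextlab
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  cells <- lapply(seq_len(nextlab), function(k)
    which(lab == k, arr.ind = TRUE))
  sizes <- vapply(cells, nrow, integer(1))
  keep <- which(sizes >= min_area_cells)
  cells <- cells[keep]
  patches <- data.frame(
    id = seq_along(cells),
    n_cells = vapply(cells, nrow, integer(1)),
    area_km2 = vapply(cells, nrow, integer(1)) * cell_area_km2,
    centroid_row = vapply(cells, function(m) mean(m[, 1]), numeric(1)),
    centroid_col = vapply(cells, function(m) mean(m[, 2]), numeric(1)))
  structure(list(patches = patches, cells = cells, mask = hab,
                 habitat = habitat),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches, %d habitat cells, total area %.1f km^2\n",
              nrow(x$patches), sum(x$mask), sum(x$patches$area_km2)))
  invisible(x)
}

#' Least-cost distances among habitat patches
#'
#' Builds the 8-connected cell graph over traversable (non-nodata) cells with
#' edge cost `mean(resistance) * cellsize` (x sqrt(2) diagonal), then runs
#' multi-source Dijkstra from each patch's member cells; `d_ij` is the
#' minimum over member-cell pairs.  Distances above `cost_threshold` are
#' recorded as `Inf` (unreachable).
#'
#' @param resistance an `oak_raster` of positive resistances.
#' @param patches a `patch_set`.
#' @param cost_threshold cap above which patches count as unconnected
#'   (default 100000).
#' @return Symmetric matrix of least-cost distances (0 diagonal, `Inf` =
#'   unreachable).
#' @export
least_cost_distances <- function(resistance, patches,
                                 cost_threshold = 100000) {
  r <- resistance$values
  if (any(r[!is.na(r)] <= 0)) stop("resistance must be > 0")
  nr <- nrow(r); nc <- ncol(r)
  np <- nrow(patches$patches)
  out <- matrix(0, np, np)
  if (np < 2) return(out)
  id <- function(i, j) (j - 1L) * nr + i
  edges <- list(); wts <- list()
  for (dd in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                  c(1L, -1L, sqrt(2)))) {
    di <- dd[1]; dj <- dd[2]; mult <- dd[3]
    ii <- seq_len(nr - abs(di))
    if (di < 0) ii <- ii - di
    jj <- if (dj >= 0) seq_len(nc - dj) else seq(1 - dj, nc)
    from <- outer(ii, jj, id)
    to <- outer(ii + di, jj + dj, id)
    wA <- r[cbind(as.vector(row(from)) * 0 + rep(ii, length(jj)),
                  rep(jj, each = length(ii)))]
    wB <- r[cbind(rep(ii + di, length(jj)), rep(jj + dj, each = length(ii)))]
    ok <- !is.na(wA) & !is.na(wB)
    edges[[length(edges) + 1L]] <- cbind(as.vector(from)[ok],
                                         as.vector(to)[ok])
    wts[[length(wts) + 1L]] <- ((wA + wB) / 2 * mult *
                                  resistance$cellsize)[ok]
  }
  el <- do.call(rbind, edges)
  w_cell <- unlist(wts)
  # multi-source Dijkstra via a zero-cost virtual source per patch; the
  # graph is directed (cell edges in both directions, patch->member arcs
  # only outward) so paths can never teleport through another patch's
  # virtual node.
  pnode <- paste0("P", seq_len(np))
  member <- lapply(patches$cells, function(m)
    as.character(id(m[, 1], m[, 2])))
  el_dir <- rbind(cbind(as.character(el[, 1]), as.character(el[, 2])),
                  cbind(as.character(el[, 2]), as.character(el[, 1])),
                  do.call(rbind, lapply(seq_len(np), function(i)
                    cbind(pnode[i], member[[i]]))))
  g <- igraph::graph_from_edgelist(el_dir, directed = TRUE)
  igraph::E(g)$weight <- c(w_cell, w_cell,
                           rep(0, sum(lengths(member))))
  vname <- igraph::V(g)$name
  for (i in seq_len(np - 1)) {
    dv <- igraph::distances(g, v = pnode[i], to = vname, mode = "out")
    for (j in (i + 1):np) {
      dij <- suppressWarnings(min(dv[1, member[[j]][member[[j]] %in%
                                                      colnames(dv)]]))
      if (!is.finite(dij) || dij > cost_threshold) dij <- Inf
      out[i, j] <- out[j, i] <- dij
    }
  }
  diag(out) <- 0
  out
}

#' Equivalent connectivity area
#'
#' `alpha = -log(p_ref)/d_ref`; direct dispersal probabilities are
#' `p_ij = exp(-alpha d_ij)` and, unless `direct_only`, are upgraded to the
#' maximum product probability over paths in the patch graph.  Then
#' `ECA = sqrt(sum_i sum_j a_i a_j p*_ij)` (km^2).  Bounds:
#' `sqrt(sum a_i^2) <= ECA <= sum a_i`.
#'
#' @param patches a `patch_set` (or data frame with `area_km2`).
#' @param distances symmetric least-cost distance matrix (`Inf` =
#'   unreachable).
#' @param p_ref dispersal probability at the reference distance (default
#'   0.5).
#' @param d_ref reference distance in the cost units corresponding to 1 km
#'   of travel at minimum resistance (default 1).
#' @param direct_only use direct-edge probabilities without path upgrading.
#' @return An `eca_result`: `eca`, `areas`, `p` (probability matrix),
#'   `alpha`.
#' @export
eca <- function(patches, distances, p_ref = 0.5, d_ref = 1,
                direct_only = FALSE) {
  if (d_ref <= 0) stop("d_ref must be > 0")
  a <- if (inherits(patches, "patch_set")) patches$patches$area_km2
  else patches$area_km2
  np <- length(a)
  alpha <- -log(p_ref) / d_ref
  d <- as.matrix(distances)
  if (np == 1) d <- matrix(0, 1, 1)
  if (!direct_only && np > 2) {
    # max-product over paths == shortest path on the distance graph
    finite <- d; finite[is.infinite(finite)] <- NA
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.na(finite), 0, finite), mode = "undirected",
      weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g)
  }
  p <- exp(-alpha * d)
  p[is.infinite(d)] <- 0
  diag(p) <- 1
  structure(list(eca = sqrt(as.numeric(t(a) %*% p %*% a)), areas = a,
                 p = p, alpha = alpha, p_ref = p_ref, d_ref = d_ref),
            class = "eca_result")
}

#' @export
print.eca_result <- function(x, ...) {
  cat(sprintf("ECA = %.3f km^2 over %d patches (total area %.3f km^2)\n",
              x$eca, length(x$areas), sum(x$areas)))
  invisible(x)
}

#' Full connectivity stage for one period
#'
#' Rescales a 0-1 suitability model, combines it with TRI-derived
#' suitability, extracts patches, computes least-cost distances and ECA.
#'
#' @param suitability an `oak_raster` with values in \[0, 1\].
#' @param dem an aligned `oak_raster` DEM.
#' @param threshold logistic threshold for [rescale_suitability()].
#' @param weights layer weights for [combine_habitat()].
#' @param min_mean_value,window_cells,min_area_cells see
#'   [extract_patches()].
#' @param cost_threshold,p_ref,d_ref see [least_cost_distances()] and
#'   [eca()].
#' @return List: `habitat`, `patches`, `distances`, `eca` (an
#'   `eca_result`).
#' @export
connectivity_stage <- function(suitability, dem, threshold = 0.5,
                               weights = c(0.5, 0.5), min_mean_value = 50,
                               window_cells = 1, min_area_cells = 1,
                               cost_threshold = 100000, p_ref = 0.5,
                               d_ref = 1) {
  stop_if_misaligned(suitability, dem)
  climate <- rescale_suitability(suitability, threshold)
  rugged <- tri_to_suitability(tri(dem))
  habitat <- combine_habitat(climate, rugged, weights)
  patches <- extract_patches(habitat, min_mean_value, window_cells,
                             min_area_cells)
  if (!nrow(patches$patches))
    return(list(habitat = habitat, patches = patches, distances = NULL,
                eca = NULL))
  dmat <- least_cost_distances(resistance_from_habitat(habitat), patches,
                               cost_threshold)
  list(habitat = habitat, patches = patches, distances = dmat,
       eca = eca(patches, dmat, p_ref, d_ref))
}
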