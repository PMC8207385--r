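# Minimal georeferenced raster container and ESRI ASCII grid I/O.
#
# Values are stored as a numeric matrix with row 1 = north edge (the ASCII
# grid convention); coordinates refer to cell centers.  No raster package is
# assumed: the ASCII grid dialect is simple enough to own, and every
# downstream operation works on the matrix directly.

#' Construct a raster
#'
#' @param values numeric matrix (row 1 = north edge); `NA` = nodata.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (map units; kilometres in the synthetic
#'   landscapes).
#' @param nodata sentinel written to file for `NA` cells.
#' @return An object of class `oak_raster`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "oak_raster")
}

#' @export
print.oak_raster <- function(x, ...) {
  cat(sprintf("oak_raster: %d x %d, cellsize %g, origin (%g, %g), %d nodata cells\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return An `oak_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  raster_grid(m, xll, yll, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#' @param raster an `oak_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", raster$xll),
               paste("yllcorner", raster$yll),
               paste("cellsize", raster$cellsize),
               paste("NODATA_value", raster$nodata)), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

stop_if_misaligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$cellsize - b$cellsize) > 1e-9 ||
      abs(a$xll - b$xll) > 1e-9 || abs(a$yll - b$yll) > 1e-9)
    stop("rasters are misaligned")
}

#' Topographic ruggedness index
#'
#' `TRI(c) = sqrt(sum over the 8 neighbours (z_c - z_n)^2)`; edge cells use
#' their available neighbours and nodata neighbours are excluded from the
#' sum.  Nodata cells propagate to nodata.
#'
#' @param dem an `oak_raster` DEM.
#' @return An `oak_raster` of TRI values.
#' @export
tri <- function(dem) {
  z <- dem$values
  if (all(is.na(z))) stop("all-nodata DEM")
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) next
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    nb <- z[ii, jj]
    nb <- nb[!is.na(nb)]
    out[i, j] <- sqrt(sum((z[i, j] - nb)^2))  # center term contributes 0
  }
  raster_grid(out, dem$xll, dem$yll, dem$cellsize, dem$nodata)
}

#' Fisher-Jenks natural breaks
#'
#' Dynamic-programming minimisation of within-class sum of squared
#' deviations; deterministic and invariant to input order.  If fewer distinct
#' values than classes exist, k is reduced with a warning.  For very large
#' inputs the optimisation runs on a deterministic quantile subsample
#' (`max_values`), which is standard practice for cartographic breaks.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes (default 10).
#' @param max_values subsample cap for the DP (default 4000).
#' @return Numeric vector of k+1 class boundaries (min, k-1 breaks, max);
#'   class i is `(b[i], b[i+1]]` with the first class closed on the left.
#' @export
jenks_breaks <- function(values, k = 10, max_values = 4000) {
  x <- sort(values[!is.na(values)])
  ux <- unique(x)
  if (length(ux) < k) {
    warning("fewer distinct values than classes; k reduced to ", length(ux))
    k <- length(ux)
  }
  if (k == 1) return(c(x[1], x[length(x)]))
  if (length(x) > max_values)
    x <- quantile(x, probs = seq(0, 1, length.out = max_values),
                  names = FALSE, type = 1)
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  ssd_vec <- function(i, j) {  # within-class SSD of x[i..j], vectorized in i
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    pmax(0, s2 - s^2 / (j - i + 1))
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  cost[1, ] <- pmax(0, cs2[-1] - cs[-1]^2 / seq_len(n))
  for (c in 2:k) for (j in c:n) {
    i <- c:j
    v <- cost[c - 1, i - 1] + ssd_vec(i, j)
    b <- which.min(v)
    cost[c, j] <- v[b]
    back[c, j] <- i[b]
  }
  breaks <- numeric(k + 1)
  breaks[k + 1] <- x[n]
  j <- n
  for (c in k:2) {
    i <- back[c, j]
    breaks[c] <- x[i - 1]
    j <- i - 1
  }
  breaks[1] <- x[1]
  breaks
}

#' Rescale a suitability model to 0-100 around a logistic threshold
#'
#' Cells at or above the threshold become 100; cells below it are rescaled
#' linearly: `100 - (threshold - v) * 100 / threshold` (equivalently
#' `100 * v / threshold`), so v = 0 maps to 0.  Monotone nondecreasing in v.
#'
#' @param model an `oak_raster` with values in \[0, 1\].
#' @param threshold logistic suitability threshold in (0, 1].
#' @return An `oak_raster` on the 0-100 scale.
#' @export
rescale_suitability <- function(model, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  v <- model$values
  out <- ifelse(v >= threshold, 100, 100 - (threshold - v) * 100 / threshold)
  raster_grid(out, model$xll, model$yll, model$cellsize, model$nodata)
}

#' Map TRI classes to suitability values
#'
#' Classifies TRI into `k` natural breaks and assigns suitability linearly
#' descending from 100 (flattest class) to 100/k (most rugged class).
#'
#' @param tri_raster an `oak_raster` of TRI values.
#' @param k number of classes (default 10: 100, 90, ..., 10).
#' @return An `oak_raster` on the 0-100 scale.
#' @export
tri_to_suitability <- function(tri_raster, k = 10) {
  v <- tri_raster$values
  br <- jenks_breaks(as.vector(v), k)
  k_eff <- length(br) - 1
  cls <- matrix(findInterval(v, br, rightmost.closed = TRUE,
                             all.inside = TRUE), nrow(v), ncol(v))
  suit <- (k_eff + 1 - cls) * (100 / k_eff)
  suit[is.na(v)] <- NA_real_
  raster_grid(suit, tri_raster$xll, tri_raster$yll, tri_raster$cellsize,
              tri_raster$nodata)
}

#' Combine climate and ruggedness layers into a habitat layer
#'
#' Weighted arithmetic mean of two aligned 0-100 layers (default equal
#' weights).  Nodata in either layer propagates.
#'
#' @param climate_layer,tri_class_layer aligned `oak_raster`s on 0-100.
#' @param weights length-2 nonnegative weights, renormalised to sum 1.
#' @return An `oak_raster` on the 0-100 scale.
#' @export
combine_habitat <- function(climate_layer, tri_class_layer,
                            weights = c(0.5, 0.5)) {
  stop_if_misaligned(climate_layer, tri_class_layer)
  w <- weights / sum(weights)
  out <- w[1] * climate_layer$values + w[2] * tri_class_layer$values
  raster_grid(out, climate_layer$xll, climate_layer$yll,
              climate_layer$cellsize, climate_layer$nodata)
}

#' Superficial area per elevation bin
#'
#' Accumulates cell areas into elevation bins `[b, b + bin)`; the bins
#' partition the valid cells so areas sum to the total valid area.
#'
#' @param dem an `oak_raster` DEM; cellsize is interpreted in km so cell
#'   area is `cellsize^2` km^2 (pass `cell_area_km2` to override).
#' @param bin bin width in elevation units (default 100 m).
#' @param range optional `c(lo, hi)` limiting the binned elevations.
#' @param mask optional logical matrix (e.g. one cordillera) selecting cells.
#' @param cell_area_km2 per-cell area; default `cellsize^2`.
#' @return Data frame: `elev_lo`, `elev_hi`, `n_cells`, `area_km2`.
#' @export
area_by_elevation_bin <- function(dem, bin = 100, range = NULL, mask = NULL,
                                  cell_area_km2 = NULL) {
  z <- dem$values
  if (!is.null(mask)) z[!mask] <- NA_real_
  z <- z[!is.na(z)]
  if (!is.null(range)) z <- z[z >= range[1] & z < range[2]]
  if (is.null(cell_area_km2)) cell_area_km2 <- dem$cellsize^2
  if (!length(z))
    return(data.frame(elev_lo = numeric(0), elev_hi = numeric(0),
                      n_cells = integer(0), area_km2 = numeric(0)))
  lo <- floor(min(z) / bin) * bin
  hi <- floor(max(z) / bin) * bin
  bins <- seq(lo, hi, by = bin)
  idx <- floor(z / bin) * bin
  n <- vapply(bins, function(b) sum(idx == b), integer(1))
  data.frame(elev_lo = bins, elev_hi = bins + bin, n_cells = n,
             area_km2 = n * cell_area_km2)
}
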