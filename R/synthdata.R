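# Synthetic data with known truth.
#
# Nuclear genotypes: a coalescent sample under the chosen demographic
# scenario provides the ancestral allele pool per locus; per-deme allele
# frequencies are then drawn by the Balding-Nichols construction, Dirichlet
# with concentration p * (1 - F) / F around the ancestral frequencies, so the
# expected Weir-Cockerham theta approximates the requested target_fst.
# Optionally demes are nested in three linear "cordilleras" with a region-
# level differentiation stage.  Chloroplast haplotypes: one fully linked
# haploid system per individual, drawn from a pooled linked coalescent pool
# with deme-biased sampling to create mild geographic sorting.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

bn_freqs <- function(p, fst) {
  if (fst <= 0) return(p)
  rdirichlet1(p * (1 - fst) / fst)
}

#' Simulate a two-marker dataset with sampling design and truth
#'
#' Emulates a typical Andean oak sampling design: `n_demes` sampling locations with 5-13
#' individuals each, arranged along three linear cordilleras, 10 diploid
#' nuclear loci and 9 fully linked haploid chloroplast loci, under a chosen
#' demographic scenario and a target among-deme FST.
#'
#' @param n_demes number of sampling locations (default 22).
#' @param n_per_deme integer range (or vector to sample from) of individuals
#'   per deme (default 5:13).
#' @param n_nssr diploid nuclear loci (default 10).
#' @param n_cpssr linked haploid chloroplast loci (default 9).
#' @param scenario a `scenario_spec` (default: scenario 3 with a x100
#'   bottleneck: current Ne 50000, bottleneck Ne 500 between 300 and 500
#'   generations ago, ancestral Ne 50000).
#' @param target_fst among-deme differentiation (default 0.07, a typical
#'   nuclear oak value).
#' @param region_fst optional extra region-level differentiation (default 0).
#' @param mu mutation rate per locus (default 5e-4).
#' @param seed master seed.
#' @return List: `nuclear` and `cp` (`genotype_table`s), `design`
#'   (sampling design data frame), `truth` (generator parameters).
#' @export
simulate_dataset <- function(n_demes = 22, n_per_deme = 5:13, n_nssr = 10,
                             n_cpssr = 9, scenario = NULL,
                             target_fst = 0.07, region_fst = 0, mu = 5e-4,
                             seed = 1) {
  set.seed(seed)
  if (is.null(scenario))
    scenario <- scenario_spec(3, data.frame(t = c(0, 300, 500),
                                            ne = c(50000, 500, 50000)))
  if (target_fst < 0 || target_fst >= 1)
    stop("infeasible target_fst (need 0 <= F < 1)")
  n_k <- rep_len(n_per_deme, n_demes)[sample.int(n_demes)]
  n_total <- sum(n_k)
  deme <- rep(seq_len(n_demes), n_k)
  region_of_deme <- rep(1:3, length.out = n_demes)
  # three linear cordilleras: parallel north-south lines
  lon0 <- c(-76.5, -75.5, -73.5)
  lat_d <- numeric(n_demes); lon_d <- numeric(n_demes)
  for (g in 1:3) {
    idx <- which(region_of_deme == g)
    lat_d[idx] <- seq(2, 7, length.out = length(idx)) +
      rnorm(length(idx), 0, 0.05)
    lon_d[idx] <- lon0[g] + rnorm(length(idx), 0, 0.05)
  }

  # --- nuclear: ancestral pool per locus, Balding-Nichols per deme ---
  pool <- simulate_coalescent_msat(2 * n_total, scenario, mu, n_nssr)
  nuc <- matrix(MISSING_ALLELE, n_total, 2 * n_nssr)
  for (l in seq_len(n_nssr)) {
    sizes <- sort(unique(pool[, l]))
    p_anc <- as.numeric(table(factor(pool[, l], levels = sizes))) /
      nrow(pool)
    reg_p <- lapply(1:3, function(g)
      if (region_fst > 0) bn_freqs(p_anc, region_fst) else p_anc)
    for (k in seq_len(n_demes)) {
      p_k <- bn_freqs(reg_p[[region_of_deme[k]]], target_fst)
      draws <- sample(sizes, 2 * n_k[k], replace = TRUE, prob = p_k)
      rows <- which(deme == k)
      nuc[rows, 2 * l - 1] <- draws[seq_len(n_k[k])]
      nuc[rows, 2 * l] <- draws[n_k[k] + seq_len(n_k[k])]
    }
  }
  ind <- sprintf("ind%03d", seq_len(n_total))
  loc <- sprintf("loc%02d", deme)
  region <- paste0("cordillera", region_of_deme[deme])
  nuclear <- genotype_table(ind, loc, region, nuc,
                            paste0("nssr", seq_len(n_nssr)), 2L,
                            lat = lat_d[deme] + rnorm(n_total, 0, 0.01),
                            lon = lon_d[deme] + rnorm(n_total, 0, 0.01))

  # --- chloroplast: pooled linked haplotype pool, deme-biased sampling ---
  cp_pool <- simulate_coalescent_msat(max(2 * n_demes, 2 * n_total),
                                      scenario, mu, n_cpssr, linked = TRUE)
  hap_key <- apply(cp_pool, 1, paste, collapse = ":")
  uh <- unique(hap_key)
  hap_mat <- cp_pool[match(uh, hap_key), , drop = FALSE]
  p_hap <- as.numeric(table(factor(hap_key, levels = uh))) /
    length(hap_key)
  cp <- matrix(MISSING_ALLELE, n_total, n_cpssr)
  for (k in seq_len(n_demes)) {
    p_k <- if (target_fst > 0) bn_freqs(p_hap, min(0.9, 2 * target_fst))
    else p_hap
    pick <- sample(length(uh), n_k[k], replace = TRUE, prob = p_k)
    cp[deme == k, ] <- hap_mat[pick, , drop = FALSE]
  }
  cp_table <- genotype_table(ind, loc, region, cp,
                             paste0("cpssr", seq_len(n_cpssr)), 1L,
                             lat = nuclear$lat, lon = nuclear$lon)

  truth <- list(scenario_id = scenario$id, epochs = scenario$epochs,
                n_demes = n_demes, n_per_deme = n_k,
                target_fst = target_fst, region_fst = region_fst,
                mu = mu, seed = seed)
  list(nuclear = nuclear, cp = cp_table, design = sampling_design(nuclear),
       truth = truth)
}

# Simple separable smoothing by repeated 3x3 box averaging.
smooth_field <- function(m, passes = 3) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    out <- m
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      out[i, j] <- mean(m[max(1, i - 1):min(nr, i + 1),
                          max(1, j - 1):min(nc, j + 1)])
    }
    m <- out
  }
  m
}

#' Simulate a DEM and per-period suitability rasters
#'
#' The DEM is a north-south ridge template plus a smoothed random field.
#' Suitability is a logistic band around a focal elevation whose width grows
#' by `growth` per period (emulating glacial-to-present habitat expansion),
#' so habitat cell counts - and the ECA computed on them - increase
#' monotonically across periods when `growth > 1`.
#'
#' @param rows,cols grid dimensions (>= 20 each).
#' @param n_periods number of periods, oldest first (default 3:
#'   LGM-like, mid-Holocene-like, present-day-like).
#' @param growth band-width growth factor per period (default 1.6).
#' @param cellsize_km cell size in km (default 1).
#' @param seed RNG seed.
#' @return List: `dem` (an `oak_raster`), `suitability` (list of
#'   `oak_raster`s on 0-1, oldest first), `truth`.
#' @export
simulate_landscape <- function(rows = 60, cols = 60, n_periods = 3,
                               growth = 1.6, cellsize_km = 1, seed = 1) {
  if (rows < 20 || cols < 20) stop("grid must be at least 20 x 20")
  set.seed(seed)
  ridge <- matrix(rep(1500 + 1200 * sin(seq(0, pi, length.out = cols)),
                      each = rows), rows, cols)
  noise <- smooth_field(matrix(rnorm(rows * cols, 0, 400), rows, cols), 4)
  dem <- raster_grid(ridge + noise, cellsize = cellsize_km)
  band_center <- 2000
  base_width <- 150
  suit <- lapply(seq_len(n_periods), function(p) {
    width <- base_width * growth^(p - 1)
    s <- 1 / (1 + ((dem$values - band_center) / width)^2)
    raster_grid(s, cellsize = cellsize_km)
  })
  truth <- list(rows = rows, cols = cols, n_periods = n_periods,
                growth = growth, band_center = band_center,
                base_width = base_width, seed = seed)
  list(dem = dem, suitability = suit, truth = truth)
}
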