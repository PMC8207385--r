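# Hierarchical analysis of molecular variance (AMOVA).
#
# Variance components are estimated from sums of squared inter-unit
# distances.  For haploid chloroplast data the unit is the individual
# (multilocus haplotype); for diploid nuclear data the units are gene copies,
# locus by locus, and variance components are summed across loci.  Under the
# IAM the squared distance between two copies is 0/1 allele identity; under
# the SMM it is the squared allele-size difference in motif units.
# Negative variance components are retained (not truncated) and flagged, and
# percentages are computed on the raw components.

# SSD within groups of a squared-distance matrix: sum over groups of
# (1/n_g) * sum_{i<j in g} d2_ij.
ssd_within <- function(d2, f) {
  f <- factor(f)
  m <- rowsum(d2, f)
  gg <- rowsum(t(m), f)
  n_g <- as.numeric(table(f))
  sum(diag(as.matrix(gg)) / (2 * n_g))
}

# Components for one locus given unit-level pop (and optional region) labels.
# Returns df, SS and sigma^2 for the available levels.
amova_components <- function(d2, pop, region = NULL) {
  N <- nrow(d2)
  pop <- factor(pop)
  P <- nlevels(pop)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- ssd_within(d2, pop)
  n_p <- as.numeric(table(pop))
  if (is.null(region)) {
    df_wp <- N - P
    df_ap <- P - 1
    ms_wp <- ss_wp / df_wp
    ms_ap <- (ss_total - ss_wp) / df_ap
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n_c
    list(df = c(among_locations = df_ap, within_locations = df_wp),
         ss = c(among_locations = ss_total - ss_wp,
                within_locations = ss_wp),
         sigma = c(among_locations = sig_b, within_locations = sig_c))
  } else {
    region <- factor(region)
    G <- nlevels(region)
    ss_wg <- ssd_within(d2, region)
    df_ag <- G - 1
    df_ap <- P - G
    df_wp <- N - P
    ms_ag <- (ss_total - ss_wg) / df_ag
    ms_ap <- (ss_wg - ss_wp) / df_ap
    ms_wp <- ss_wp / df_wp
    # region sizes and per-region sums of squared pop sizes
    reg_of_pop <- vapply(levels(pop), function(pp)
      as.character(region[pop == pp][1]), character(1))
    N_g <- as.numeric(table(region))
    sum_np2_g <- vapply(levels(region), function(g)
      sum(n_p[reg_of_pop == g]^2), numeric(1))
    n_b <- (N - sum(sum_np2_g / N_g)) / (P - G)
    n_a1 <- (sum(sum_np2_g / N_g) - sum(n_p^2) / N) / (G - 1)
    n_a2 <- (N - sum(N_g^2) / N) / (G - 1)
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n_b
    sig_a <- (ms_ag - sig_c - n_a1 * sig_b) / n_a2
    list(df = c(among_regions = df_ag, among_locations = df_ap,
                within_locations = df_wp),
         ss = c(among_regions = ss_total - ss_wg,
                among_locations = ss_wg - ss_wp,
                within_locations = ss_wp),
         sigma = c(among_regions = sig_a, among_locations = sig_b,
                   within_locations = sig_c))
  }
}

# Build per-locus unit descriptors for a genotype table: for each locus a
# list(sizes, ind) with missing copies dropped; haploid multilocus tables are
# a single pseudo-locus of complete individuals.
amova_units <- function(table) {
  if (table$ploidy == 1L) {
    keep <- missing_loci_count(table) == 0
    list(list(alleles = table$alleles[keep, , drop = FALSE],
              ind = which(keep), multilocus = TRUE))
  } else {
    lapply(seq_len(n_loci(table)), function(l) {
      g <- locus_alleles(table, l)
      sizes <- as.vector(t(g))
      ind <- rep(seq_len(n_ind(table)), each = 2L)
      keep <- sizes != MISSING_ALLELE
      list(alleles = matrix(sizes[keep], ncol = 1), ind = ind[keep],
           multilocus = FALSE)
    })
  }
}

unit_d2 <- function(alleles, model, motif_length) {
  if (model == "SMM") {
    as.matrix(dist(alleles / motif_length))^2
  } else {
    L <- ncol(alleles)
    d2 <- matrix(0, nrow(alleles), nrow(alleles))
    for (l in seq_len(L))
      d2 <- d2 + outer(alleles[, l], alleles[, l], "!=")
    d2
  }
}

sum_components <- function(comp_list) {
  lev <- names(comp_list[[1]]$sigma)
  out <- list(df = setNames(rep(0, length(lev)), lev),
              ss = setNames(rep(0, length(lev)), lev),
              sigma = setNames(rep(0, length(lev)), lev))
  for (cmp in comp_list) {
    out$df <- out$df + cmp$df
    out$ss <- out$ss + cmp$ss
    out$sigma <- out$sigma + cmp$sigma
  }
  out
}

phi_of <- function(sigma) {
  tot <- sum(sigma)
  if (length(sigma) == 3) {
    c(phi_CT = unname(sigma[1] / tot),
      phi_SC = unname(sigma[2] / (sigma[2] + sigma[3])),
      phi_ST = unname((sigma[1] + sigma[2]) / tot))
  } else {
    c(phi_ST = unname(sigma[1] / tot))
  }
}

#' Hierarchical AMOVA under IAM or SMM distances
#'
#' Decomposes molecular variance among regions, among sampling locations
#' within regions, and within locations (or two levels when `use_regions =
#' FALSE` or only one region is present).  Significance by permutation:
#' Phi_ST permutes individuals among locations, Phi_SC permutes individuals
#' among locations within their region, and Phi_CT permutes whole locations
#' among regions.
#'
#' @param table a `genotype_table` (haploid: multilocus haplotype units;
#'   diploid: per-locus gene copies, components summed over loci).
#' @param model `"IAM"` (0/1 identity) or `"SMM"` (squared size difference).
#' @param n_perm permutations (default 10000; use less for exploration).
#' @param seed RNG seed.
#' @param use_regions include the among-region level when >= 2 regions.
#' @param motif_length motif length for SMM step scaling.
#' @return An `amova_result`: `table` (df, SS, sigma^2, percent per level),
#'   `phi`, `p` (permutation p-values), `model`, `flags`.
#' @export
amova <- function(table, model = c("IAM", "SMM"), n_perm = 10000, seed = 1,
                  use_regions = TRUE, motif_length = 1) {
  model <- match.arg(model)
  set.seed(seed)
  if (length(unique(table$loc)) < 2) stop("need >= 2 locations")
  units <- amova_units(table)
  d2s <- lapply(units, function(u) unit_d2(u$alleles, model, motif_length))
  regions_on <- use_regions && length(unique(table$region)) >= 2
  flags <- character(0)
  if (regions_on) {
    locs_per_reg <- table(unique(data.frame(table$loc,
                                            table$region))[[2]])
    if (any(locs_per_reg < 2))
      flags <- c(flags, "region_with_single_location")
  }

  comp_for <- function(loc_of_ind, reg_of_ind) {
    sum_components(lapply(seq_along(units), function(i) {
      u <- units[[i]]
      amova_components(d2s[[i]], loc_of_ind[u$ind],
                       if (regions_on) reg_of_ind[u$ind] else NULL)
    }))
  }

  obs <- comp_for(table$loc, table$region)
  if (sum(obs$sigma) <= 0)
    flags <- c(flags, "zero_total_variance")
  phi <- if (sum(obs$sigma) > 0) phi_of(obs$sigma) else
    setNames(rep(NA_real_, if (regions_on) 3 else 1),
             if (regions_on) c("phi_CT", "phi_SC", "phi_ST") else "phi_ST")
  if (any(obs$sigma < 0)) flags <- c(flags, "negative_variance_component")

  p <- setNames(rep(NA_real_, length(phi)), paste0("p_", names(phi)))
  if (n_perm > 0 && sum(obs$sigma) > 0) {
    n <- n_ind(table)
    # Phi_ST: permute individuals among locations (regions follow locations)
    reg_of_loc <- vapply(unique(table$loc), function(l)
      table$region[match(l, table$loc)], character(1))
    st <- vapply(seq_len(n_perm), function(i) {
      sh <- sample.int(n)
      loc_p <- table$loc[sh]
      cmp <- comp_for(loc_p, reg_of_loc[loc_p])
      if (sum(cmp$sigma) <= 0) return(NA_real_)
      unname(phi_of(cmp$sigma)["phi_ST"])
    }, numeric(1))
    p["p_phi_ST"] <- perm_p(phi["phi_ST"], st[!is.na(st)])
    if (regions_on) {
      # Phi_SC: permute individuals among locations within regions
      sc <- vapply(seq_len(n_perm), function(i) {
        loc_p <- table$loc
        for (g in unique(table$region)) {
          idx <- which(table$region == g)
          loc_p[idx] <- loc_p[sample(idx)]
        }
        cmp <- comp_for(loc_p, table$region)
        if ((cmp$sigma[2] + cmp$sigma[3]) == 0) return(NA_real_)
        unname(phi_of(cmp$sigma)["phi_SC"])
      }, numeric(1))
      p["p_phi_SC"] <- perm_p(phi["phi_SC"], sc[!is.na(sc)])
      # Phi_CT: permute whole locations among regions
      locs <- unique(table$loc)
      ct <- vapply(seq_len(n_perm), function(i) {
        reg_l <- setNames(sample(reg_of_loc[locs]), locs)
        cmp <- comp_for(table$loc, unname(reg_l[table$loc]))
        if (sum(cmp$sigma) <= 0) return(NA_real_)
        unname(phi_of(cmp$sigma)["phi_CT"])
      }, numeric(1))
      p["p_phi_CT"] <- perm_p(phi["phi_CT"], ct[!is.na(ct)])
    }
  }

  pct <- 100 * obs$sigma / sum(obs$sigma)
  res <- list(table = data.frame(level = names(obs$sigma),
                                 df = as.numeric(obs$df),
                                 ss = as.numeric(obs$ss),
                                 sigma2 = as.numeric(obs$sigma),
                                 percent = as.numeric(pct),
                                 stringsAsFactors = FALSE, row.names = NULL),
              phi = phi, p = p, model = model, n_perm = n_perm,
              flags = flags)
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$model, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("Phi:", paste(names(x$phi), round(x$phi, 4), collapse = "  "), "\n")
  cat("p:  ", paste(names(x$p), signif(x$p, 3), collapse = "  "), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
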