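# Marker quality control.
#
# Permutation p-values use the add-one rule p = (1 + #{perm >= obs}) /
# (1 + n_perm) so they are never exactly zero.  The null-allele estimator is
# the EM of Dempster et al. as used by the ENA/FreeNA approach: observed
# homozygotes are a mixture of true homozygotes and null heterozygotes.

perm_p <- function(obs, perms) (1 + sum(perms >= obs - 1e-12)) /
  (1 + length(perms))

#' Hardy-Weinberg permutation test for one locus in one location
#'
#' Statistic: heterozygote deficit `uHe - Ho`.  The null distribution is
#' built by shuffling gene copies among individuals within the location.
#'
#' @param genotypes two-column integer matrix of allele sizes (one row per
#'   individual); missing copies are the sentinel and the row is dropped.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return List: `p`, `statistic` (uHe - Ho), `flag` (`"ok"`,
#'   `"monomorphic"` or `"too_few"`), `n_perm`.
#' @export
hwe_permutation_test <- function(genotypes, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- as.matrix(genotypes)
  ok <- genotypes[, 1] != MISSING_ALLELE & genotypes[, 2] != MISSING_ALLELE
  g <- genotypes[ok, , drop = FALSE]
  if (nrow(g) < 2)
    return(list(p = NA_real_, statistic = NA_real_, flag = "too_few",
                n_perm = 0L))
  pool <- as.vector(t(g))
  if (length(unique(pool)) == 1L)
    return(list(p = 1, statistic = 0, flag = "monomorphic", n_perm = 0L))
  stat <- function(copies) {
    m <- matrix(copies, ncol = 2, byrow = TRUE)
    n_cop <- length(copies)
    p <- as.numeric(table(copies)) / n_cop
    uhe <- n_cop / (n_cop - 1) * (1 - sum(p^2))
    uhe - mean(m[, 1] != m[, 2])
  }
  obs <- stat(pool)
  perms <- vapply(seq_len(n_perm), function(i) stat(sample(pool)), numeric(1))
  list(p = perm_p(obs, perms), statistic = obs, flag = "ok", n_perm = n_perm)
}

g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  i <- tab > 0
  2 * sum(tab[i] * log(tab[i] / e[i]))
}

#' Linkage-disequilibrium permutation test for a locus pair
#'
#' Statistic: G (log-likelihood ratio) on the two-locus genotype contingency
#' table; null built by permuting one locus's genotypes among individuals.
#'
#' @param geno1,geno2 two-column allele matrices for the two loci (same
#'   individuals).
#' @param n_perm permutations.
#' @param seed optional RNG seed.
#' @return List: `p`, `statistic`, `flag` (`"ok"`, `"degenerate"`,
#'   `"too_few"`), `n_perm`.
#' @export
ld_permutation_test <- function(geno1, geno2, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno1 <- as.matrix(geno1); geno2 <- as.matrix(geno2)
  ok <- geno1[, 1] != MISSING_ALLELE & geno1[, 2] != MISSING_ALLELE &
    geno2[, 1] != MISSING_ALLELE & geno2[, 2] != MISSING_ALLELE
  if (sum(ok) < 5)
    return(list(p = NA_real_, statistic = NA_real_, flag = "too_few",
                n_perm = 0L))
  gt <- function(g) apply(g, 1, function(r) paste(sort(r), collapse = "/"))
  a <- gt(geno1[ok, , drop = FALSE])
  b <- gt(geno2[ok, , drop = FALSE])
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    return(list(p = 1, statistic = 0, flag = "degenerate", n_perm = 0L))
  obs <- g_statistic(table(a, b))
  perms <- vapply(seq_len(n_perm), function(i)
    g_statistic(table(a, sample(b))), numeric(1))
  list(p = perm_p(obs, perms), statistic = obs, flag = "ok", n_perm = n_perm)
}

#' EM estimate of the null-allele frequency at one locus
#'
#' Alleles are modelled as visible classes plus one latent null allele under
#' Hardy-Weinberg proportions.  Observed homozygotes for allele i are a
#' mixture of true i/i homozygotes and i/null heterozygotes; individuals with
#' a completely missing locus may optionally be treated as null/null
#' homozygotes.
#'
#' @param genotypes two-column allele-size matrix for the locus, all
#'   individuals (sentinel for missing copies).
#' @param include_blanks treat fully missing rows as candidate null
#'   homozygotes (default FALSE: blanks carry no information).
#' @param tol convergence tolerance on the max allele-frequency change.
#' @param max_iter iteration cap.
#' @return List: `r` (null frequency), `p` (named visible allele
#'   frequencies, summing with `r` to 1), `converged`, `iterations`.
#' @export
null_allele_em <- function(genotypes, include_blanks = FALSE, tol = 1e-8,
                           max_iter = 10000) {
  g <- as.matrix(genotypes)
  miss <- g == MISSING_ALLELE
  blank <- miss[, 1] & miss[, 2]
  full <- !miss[, 1] & !miss[, 2]
  g2 <- g[full, , drop = FALSE]
  if (nrow(g2) < 1) stop("no complete genotypes at this locus")
  alleles <- sort(unique(as.vector(g2)))
  k <- length(alleles)
  het <- g2[, 1] != g2[, 2]
  # het allele tallies (each het contributes one copy of each allele)
  het_copies <- table(factor(as.vector(g2[het, , drop = FALSE]),
                             levels = alleles))
  hom_counts <- table(factor(g2[!het, 1], levels = alleles))
  n_blank <- if (include_blanks) sum(blank) else 0L
  N <- nrow(g2) + n_blank
  p <- rep(1 / (k + 1), k)
  r <- 1 / (k + 1)
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step: split observed i-homozygotes into i/i vs i/null
    denom <- p + 2 * r
    w_ii <- ifelse(denom > 0, p / denom, 1)
    e_ii <- as.numeric(hom_counts) * w_ii
    e_i0 <- as.numeric(hom_counts) * (1 - w_ii)
    # M-step
    p_new <- (2 * e_ii + as.numeric(het_copies) + e_i0) / (2 * N)
    r_new <- (sum(e_i0) + 2 * n_blank) / (2 * N)
    delta <- max(abs(c(p_new - p, r_new - r)))
    p <- p_new; r <- r_new
    if (delta < tol || it >= max_iter) break
  }
  list(r = r, p = setNames(p, alleles), converged = it < max_iter,
       iterations = it)
}

# Weir & Cockerham (1984) per-allele variance components at one locus.
# Returns the sums over alleles of a (among populations), b (among
# individuals within populations) and c (within individuals).
wc_components <- function(genotypes, pop) {
  g <- as.matrix(genotypes)
  ok <- g[, 1] != MISSING_ALLELE & g[, 2] != MISSING_ALLELE
  g <- g[ok, , drop = FALSE]
  pop <- factor(pop[ok])
  pops <- levels(pop)
  r <- length(pops)
  if (r < 2 || nrow(g) < 2) return(c(a = 0, b = 0, c = 0))
  n_i <- as.numeric(table(pop))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  alleles <- sort(unique(as.vector(g)))
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- vapply(pops, function(pp) {
      gg <- g[pop == pp, , drop = FALSE]
      mean(gg == al)
    }, numeric(1))
    h_i <- vapply(pops, function(pp) {
      gg <- g[pop == pp, , drop = FALSE]
      mean((gg[, 1] == al) != (gg[, 2] == al))
    }, numeric(1))
    pbar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

# Variance components from population allele frequencies only (used for the
# ENA-corrected route, where heterozygosity is taken at its Hardy-Weinberg
# expectation given the corrected frequencies).
wc_components_freq <- function(freqs, n_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  alleles <- Reduce(union, lapply(freqs, names))
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- vapply(freqs, function(f) if (al %in% names(f)) f[[al]] else 0,
                  numeric(1))
    pbar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    h_i <- 2 * p_i * (1 - p_i)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

#' Multilocus Weir-Cockerham FST, optionally ENA-corrected for null alleles
#'
#' Without correction, theta is the ratio-of-sums estimator over loci of the
#' Weir & Cockerham (1984) components computed from observed genotypes.  With
#' `ena = TRUE`, visible allele frequencies per locus and location are first
#' re-estimated by [null_allele_em()] and renormalised after excluding the
#' estimated null allele; theta is then computed from the corrected
#' frequencies with heterozygosity at its HWE expectation.  Confidence
#' intervals bootstrap loci.
#'
#' @param table diploid `genotype_table` with >= 2 locations.
#' @param ena apply the null-allele (ENA) correction.
#' @param n_boot bootstrap replicates over loci for the 95% CI (0 = none).
#' @param seed optional RNG seed for the bootstrap.
#' @return List: `theta`, `ci` (length-2 or NULL), `per_locus` components
#'   data frame, `fis` (multilocus Weir-Cockerham f, uncorrected route only),
#'   `flag`.
#' @export
fst_weir_cockerham <- function(table, ena = FALSE, n_boot = 0, seed = NULL) {
  if (table$ploidy != 2L) stop("fst_weir_cockerham needs a diploid table")
  if (length(unique(table$loc)) < 2) stop("need >= 2 locations")
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(table)
  comps <- matrix(0, L, 3, dimnames = list(table$loci, c("a", "b", "c")))
  for (l in seq_len(L)) {
    g <- locus_alleles(table, l)
    if (!ena) {
      comps[l, ] <- wc_components(g, table$loc)
    } else {
      ok <- g[, 1] != MISSING_ALLELE & g[, 2] != MISSING_ALLELE
      locs <- unique(table$loc)
      freqs <- list(); n_i <- numeric(0)
      for (pp in locs) {
        sel <- ok & table$loc == pp
        if (sum(sel) < 2) next
        em <- null_allele_em(g[sel, , drop = FALSE])
        vis <- em$p / sum(em$p)  # renormalise after excluding the null
        freqs[[length(freqs) + 1L]] <- vis
        n_i <- c(n_i, sum(sel))
      }
      if (length(freqs) >= 2)
        comps[l, ] <- wc_components_freq(freqs, n_i)
    }
  }
  theta_of <- function(idx) {
    s <- colSums(comps[idx, , drop = FALSE])
    if (sum(s) == 0) return(NA_real_)
    s["a"] / sum(s)
  }
  theta <- as.numeric(theta_of(seq_len(L)))
  s <- colSums(comps)
  fis <- if (!ena && (s["b"] + s["c"]) > 0)
    as.numeric(1 - s["c"] / (s["b"] + s["c"])) else NA_real_
  ci <- NULL; flag <- "ok"
  if (n_boot > 0) {
    if (L < 2) {
      flag <- "ci_unavailable_single_locus"
    } else {
      bt <- vapply(seq_len(n_boot), function(i)
        as.numeric(theta_of(sample.int(L, L, replace = TRUE))), numeric(1))
      ci <- as.numeric(quantile(bt, c(0.025, 0.975), na.rm = TRUE))
    }
  }
  list(theta = theta, ci = ci,
       per_locus = data.frame(locus = table$loci, comps,
                              stringsAsFactors = FALSE, row.names = NULL),
       fis = fis, flag = flag)
}

#' Locus quality-control report
#'
#' Runs HWE permutation tests per locus and location, the EM null-allele
#' estimator per locus (all individuals pooled), and multilocus
#' Weir-Cockerham theta with and without the ENA correction.
#'
#' @param table diploid `genotype_table`.
#' @param n_perm HWE permutations per locus/location.
#' @param n_boot bootstrap replicates for the theta CIs.
#' @param seed RNG seed.
#' @param bonferroni also report Bonferroni-adjusted HWE p-values.
#' @return List: `hwe` (locus x location data frame), `null_alleles`
#'   (per-locus r-hat), `fst` and `fst_ena` (as [fst_weir_cockerham()]),
#'   `fis`.
#' @export
qc_report <- function(table, n_perm = 999, n_boot = 100, seed = 1,
                      bonferroni = FALSE) {
  set.seed(seed)
  locs <- sort(unique(table$loc))
  hwe <- do.call(rbind, lapply(seq_len(n_loci(table)), function(l) {
    g <- locus_alleles(table, l)
    do.call(rbind, lapply(locs, function(pp) {
      r <- hwe_permutation_test(g[table$loc == pp, , drop = FALSE],
                                n_perm = n_perm)
      data.frame(locus = table$loci[l], loc = pp, p = r$p,
                 statistic = r$statistic, flag = r$flag,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (bonferroni) hwe$p_bonferroni <- pmin(1, hwe$p * nrow(hwe))
  nulls <- data.frame(
    locus = table$loci,
    r_hat = vapply(seq_len(n_loci(table)), function(l)
      null_allele_em(locus_alleles(table, l))$r, numeric(1)),
    stringsAsFactors = FALSE)
  fst <- fst_weir_cockerham(table, ena = FALSE, n_boot = n_boot)
  fst_ena <- fst_weir_cockerham(table, ena = TRUE, n_boot = n_boot)
  list(hwe = hwe, null_alleles = nulls, fst = fst, fst_ena = fst_ena,
       fis = fst$fis)
}
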