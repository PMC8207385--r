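# Shared in-code fixtures.

# Small diploid table: 3 locations x 2 regions, 2 loci, one individual with
# missing data.
toy_diploid <- function() {
  al <- rbind(
    c(100, 102, 200, 202),   # i1 het/het
    c(100, 100, 200, 200),   # i2 hom/hom
    c(102, 102, 202, 202),   # i3
    c(100, 102, 200, 200),   # i4
    c(104, 104, 204, 204),   # i5
    c(104, 106, 204, 206),   # i6
    c(-9,  -9,  204, 206),   # i7 missing locus 1
    c(106, 106, 206, 206))   # i8
  genotype_table(paste0("i", 1:8),
                 c("A", "A", "A", "B", "B", "B", "C", "C"),
                 c("r1", "r1", "r1", "r1", "r1", "r1", "r2", "r2"),
                 al, c("L1", "L2"), 2L,
                 lat = c(1, 1, 1, 2, 2, 2, 3, 3),
                 lon = c(10, 10, 10, 11, 11, 11, 12, 12))
}

# Haploid cp-like table with known haplotype structure.
toy_haploid <- function() {
  al <- rbind(c(10, 20), c(10, 20), c(11, 20), c(10, 22), c(11, 21),
              c(10, 20))
  genotype_table(paste0("h", 1:6),
                 c("A", "A", "A", "B", "B", "B"),
                 c("r1", "r1", "r1", "r2", "r2", "r2"),
                 al, c("c1", "c2"), 1L,
                 lat = c(1, 1, 1, 2, 2, 2), lon = c(5, 5, 5, 6, 6, 6))
}

# Brute-force oracles -------------------------------------------------------

# Gene diversity / ordered diversity by direct pair enumeration over gene
# copies: h = (pairs of distinct copies that differ) / C(n,2) scaled, i.e.
# the mean pairwise difference with the unbiased denominator.
brute_h <- function(counts) {
  copies <- rep(seq_along(counts), counts)
  n <- length(copies)
  if (n < 2) return(NA_real_)
  pr <- combn(n, 2)
  mean(copies[pr[1, ]] != copies[pr[2, ]]) * 1  # == n/(n-1)*(1-sum p^2)
}

brute_v <- function(counts, D) {
  copies <- rep(seq_along(counts), counts)
  n <- length(copies)
  pr <- combn(n, 2)
  mean(D[cbind(copies[pr[1, ]], copies[pr[2, ]])])
}

# Rarefaction by exhaustive enumeration of all C(n, g) subsamples.
brute_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# AMOVA sums of squares straight from the definition:
# SSD(group) = sum over groups of (1/n_g) sum_{i<j in g} d2_ij.
brute_amova <- function(d2, pop, region = NULL) {
  N <- nrow(d2)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ssw <- function(f) {
    s <- 0
    for (g in unique(f)) {
      ix <- which(f == g)
      if (length(ix) > 1)
        s <- s + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
    }
    s
  }
  ss_wp <- ssw(pop)
  pop <- factor(pop); P <- nlevels(pop)
  n_p <- as.numeric(table(pop))
  if (is.null(region)) {
    ms_wp <- ss_wp / (N - P)
    ms_ap <- (ss_tot - ss_wp) / (P - 1)
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n_c
    c(among = sig_b, within = sig_c)
  } else {
    region <- factor(region); G <- nlevels(region)
    ss_wg <- ssw(as.character(region))
    reg_of_pop <- vapply(levels(pop), function(pp)
      as.character(region[pop == pp][1]), character(1))
    N_g <- as.numeric(table(region))
    sum_np2_g <- vapply(levels(region), function(g)
      sum(n_p[reg_of_pop == g]^2), numeric(1))
    ms <- c((ss_tot - ss_wg) / (G - 1), (ss_wg - ss_wp) / (P - G),
            ss_wp / (N - P))
    n_b <- (N - sum(sum_np2_g / N_g)) / (P - G)
    n_a1 <- (sum(sum_np2_g / N_g) - sum(n_p^2) / N) / (G - 1)
    n_a2 <- (N - sum(N_g^2) / N) / (G - 1)
    sig_c <- ms[3]
    sig_b <- (ms[2] - sig_c) / n_b
    sig_a <- (ms[1] - sig_c - n_a1 * sig_b) / n_a2
    c(among_regions = sig_a, among_locations = sig_b,
      within_locations = sig_c)
  }
}

# All allele-count vectors with total n and at most k classes (for
# exhaustive n <= 8 diversity oracles).
count_vectors <- function(n, max_classes = n) {
  out <- list()
  recurse <- function(rem, maxpart, acc) {
    if (rem == 0) { out[[length(out) + 1L]] <<- acc; return() }
    if (length(acc) >= max_classes) return()
    for (p in min(rem, maxpart):1) recurse(rem - p, p, c(acc, p))
  }
  recurse(n, n, integer(0))
  out
}
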