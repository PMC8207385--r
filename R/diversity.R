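# Within-population diversity statistics.
#
# h is the unbiased gene diversity for unordered alleles and v its ordered
# (distance-weighted) analogue; both carry the n/(n-1) small-sample factor.
# Rarefied richness AR(g) is the hypergeometric expectation of the number of
# distinct alleles in a subsample of g gene copies.

#' Unbiased gene diversity (unordered alleles)
#'
#' `h = n/(n-1) * (1 - sum p_i^2)` over allele (or haplotype) counts of one
#' location.
#'
#' @param counts nonnegative integer vector of allele counts (zeros allowed,
#'   they are dropped).
#' @return `h`, or `NA` when fewer than 2 gene copies are available.
#' @export
gene_diversity_h <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nonstandardized ordered diversity (distance-weighted)
#'
#' `v = n/(n-1) * sum_{i != j} p_i p_j D_ij`, with `D` the inter-haplotype
#' step-distance matrix.  With a 0/1 distance matrix (off-diagonal ones) this
#' reduces exactly to [gene_diversity_h()].
#'
#' @param counts haplotype counts aligned with the rows of `D`.
#' @param D symmetric nonnegative distance matrix, zero diagonal.
#' @return `v`, or `NA` when fewer than 2 gene copies are available.
#' @export
ordered_diversity_v <- function(counts, D) {
  D <- as.matrix(D)
  if (length(counts) != nrow(D) || nrow(D) != ncol(D))
    stop("counts and distance matrix dimensions disagree")
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * as.numeric(t(p) %*% D %*% p)
}

#' Rarefied allelic (or haplotype) richness
#'
#' Expected number of distinct alleles in a hypergeometric subsample of `g`
#' gene copies: `AR(g) = sum_i [1 - C(n - n_i, g) / C(n, g)]`.
#'
#' @param counts allele counts (zeros dropped).
#' @param g standardized subsample size, `1 <= g <= n`.
#' @return `AR(g)`.
#' @export
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (g > n) stop("rarefaction size g exceeds sample size ", n)
  if (g < 1) stop("g must be >= 1")
  # lchoose keeps this stable for large n
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

allele_counts <- function(sizes) {
  sizes <- sizes[sizes != MISSING_ALLELE & !is.na(sizes)]
  if (!length(sizes)) return(integer(0))
  table(sizes)
}

#' Per-location and regional nuclear diversity summary
#'
#' Per unit (sampling location, and region) and per locus: allele count A,
#' effective allele number `Ae = 1/sum p^2`, observed heterozygosity Ho,
#' unbiased expected heterozygosity `uHe = 2n/(2n-1) (1 - sum p^2)` (n =
#' individuals, 2n = gene copies), and rarefied richness AR at a common g.
#' Values are averaged over loci.  Private alleles Ap count alleles absent
#' from every other unit at the same level.  Table-wide means are unweighted
#' across locations with `SE = sd/sqrt(n_locations)`.
#'
#' @param table diploid `genotype_table`.
#' @param rarefaction_g gene-copy subsample size for AR; default the smallest
#'   complete (non-missing) per-location gene-copy count over loci.
#' @return List with data frames `by_location`, `by_region`, and `overall`
#'   (mean and SE per statistic), plus the `rarefaction_g` used.
#' @export
nuclear_summary <- function(table, rarefaction_g = NULL) {
  if (table$ploidy != 2L) stop("nuclear_summary needs a diploid table")
  units_summary <- function(fac) {
    units <- sort(unique(fac))
    L <- n_loci(table)
    # counts[[locus]][[unit]] = named allele counts
    cnt <- lapply(seq_len(L), function(l) {
      a <- locus_alleles(table, l)
      lapply(units, function(u) allele_counts(a[fac == u, ]))
    })
    per_unit <- lapply(seq_along(units), function(ui) {
      A <- Ae <- Ho <- uHe <- rep(NA_real_, L)
      for (l in seq_len(L)) {
        cc <- cnt[[l]][[ui]]
        if (!length(cc)) next
        n_cop <- sum(cc)
        p <- as.numeric(cc) / n_cop
        A[l] <- length(cc)
        Ae[l] <- 1 / sum(p^2)
        if (n_cop >= 2) uHe[l] <- n_cop / (n_cop - 1) * (1 - sum(p^2))
        g2 <- locus_alleles(table, l)[fac == units[ui], , drop = FALSE]
        ok <- g2[, 1] != MISSING_ALLELE & g2[, 2] != MISSING_ALLELE
        if (any(ok)) Ho[l] <- mean(g2[ok, 1] != g2[ok, 2])
      }
      list(A = A, Ae = Ae, Ho = Ho, uHe = uHe)
    })
    # private alleles: present in this unit, absent in all others (any locus)
    Ap <- vapply(seq_along(units), function(ui) {
      tot <- 0L
      for (l in seq_len(L)) {
        mine <- names(cnt[[l]][[ui]])
        others <- unlist(lapply(seq_along(units)[-ui],
                                function(uj) names(cnt[[l]][[uj]])))
        tot <- tot + sum(!mine %in% others)
      }
      tot
    }, integer(1))
    list(units = units, cnt = cnt, per_unit = per_unit, Ap = Ap)
  }

  locs <- units_summary(table$loc)
  regs <- units_summary(table$region)
  L <- n_loci(table)

  if (is.null(rarefaction_g)) {
    gmin <- Inf
    for (l in seq_len(L)) for (cc in locs$cnt[[l]])
      if (length(cc)) gmin <- min(gmin, sum(cc))
    rarefaction_g <- max(2L, as.integer(gmin))
  }

  ar_of <- function(us) vapply(seq_along(us$units), function(ui) {
    vals <- vapply(seq_len(L), function(l) {
      cc <- us$cnt[[l]][[ui]]
      if (!length(cc) || sum(cc) < rarefaction_g) return(NA_real_)
      rarefied_richness(as.numeric(cc), rarefaction_g)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))

  frame_of <- function(us) {
    data.frame(unit = us$units,
               n = vapply(us$units, function(u)
                 sum((if (identical(us, locs)) table$loc else
                        table$region) == u), integer(1)),
               A = vapply(us$per_unit, function(z) mean(z$A, na.rm = TRUE),
                          numeric(1)),
               Ae = vapply(us$per_unit, function(z) mean(z$Ae, na.rm = TRUE),
                           numeric(1)),
               Ap = us$Ap,
               Ho = vapply(us$per_unit, function(z) mean(z$Ho, na.rm = TRUE),
                           numeric(1)),
               uHe = vapply(us$per_unit, function(z) mean(z$uHe, na.rm = TRUE),
                            numeric(1)),
               AR = ar_of(us),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  by_loc <- frame_of(locs)
  by_reg <- frame_of(regs)
  stats <- c("A", "Ae", "Ap", "Ho", "uHe", "AR")
  overall <- data.frame(
    statistic = stats,
    mean = vapply(stats, function(s) mean(by_loc[[s]], na.rm = TRUE),
                  numeric(1)),
    se = vapply(stats, function(s) {
      x <- by_loc[[s]][!is.na(by_loc[[s]])]
      sd(x) / sqrt(length(x))
    }, numeric(1)), row.names = NULL)
  list(by_location = by_loc, by_region = by_reg, overall = overall,
       rarefaction_g = rarefaction_g)
}

#' Per-location chloroplast (haplotype) diversity summary
#'
#' Computes, per sampling location, the haplotype count A, unbiased gene
#' diversity h on multilocus haplotypes, ordered diversity v using the
#' catalog's step distances, private haplotypes Ap, and rarefied haplotype
#' richness AR(g); plus unweighted means and SEs across locations.
#'
#' @param catalog a `haplotype_catalog`.
#' @param rarefaction_g subsample size for AR; default the smallest
#'   per-location sample size.
#' @return List with `by_location`, `overall`, `rarefaction_g`.
#' @export
cp_summary <- function(catalog, rarefaction_g = NULL) {
  cnts <- catalog$counts
  ns <- colSums(cnts)
  if (is.null(rarefaction_g)) rarefaction_g <- max(2L, min(ns))
  by_loc <- data.frame(
    unit = colnames(cnts),
    n = as.integer(ns),
    A = as.integer(colSums(cnts > 0)),
    Ap = vapply(seq_len(ncol(cnts)), function(j)
      sum(cnts[, j] > 0 &
            rowSums(cnts[, -j, drop = FALSE] > 0) == 0), integer(1)),
    h = apply(cnts, 2, gene_diversity_h),
    v = apply(cnts, 2, function(cc) ordered_diversity_v(cc, catalog$D)),
    AR = apply(cnts, 2, function(cc)
      if (sum(cc) >= rarefaction_g)
        rarefied_richness(cc, rarefaction_g) else NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  stats <- c("A", "Ap", "h", "v", "AR")
  overall <- data.frame(
    statistic = stats,
    mean = vapply(stats, function(s) mean(by_loc[[s]], na.rm = TRUE),
                  numeric(1)),
    se = vapply(stats, function(s) {
      x <- by_loc[[s]][!is.na(by_loc[[s]])]
      sd(x) / sqrt(length(x))
    }, numeric(1)), row.names = NULL)
  list(by_location = by_loc, overall = overall,
       rarefaction_g = rarefaction_g)
}
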