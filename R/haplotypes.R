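# Multilocus chloroplast haplotypes.
#
# cpSSR loci are haploid and fully linked, so the unit of analysis is the
# multilocus haplotype.  Inter-haplotype distance is the Manhattan distance
# in motif units (mononucleotide motifs: base pairs), i.e. the number of
# single-repeat mutational steps separating two haplotypes under the
# stepwise model.  This is the metric used by the ordered diversity v, by
# NST and by the haplotype network.

#' Enumerate multilocus haplotypes from a haploid table
#'
#' Individuals with any missing locus are excluded with a warning (complete
#' profiles only).  A haplotype is "unique" when it occurs in exactly one
#' sampling location, regardless of its count there.
#'
#' @param cp_table a haploid `genotype_table`.
#' @param motif_length repeat-motif length used to convert size differences
#'   to steps (mononucleotide cpSSR motifs: 1).
#' @return An object of class `haplotype_catalog`: haplotype allele matrix
#'   `haplotypes`, per-location count matrix `counts` (haplotype x location),
#'   `total` counts, step-distance matrix `D`, logical `unique_location`,
#'   and the region of each location.
#' @export
extract_haplotypes <- function(cp_table, motif_length = 1) {
  if (cp_table$ploidy != 1L) stop("extract_haplotypes needs a haploid table")
  miss <- missing_loci_count(cp_table) > 0
  if (any(miss)) {
    warning(sum(miss), " individual(s) with missing cpSSR loci excluded")
    cp_table <- subset_individuals(cp_table, !miss)
  }
  if (n_ind(cp_table) == 0) stop("no complete haploid profiles")
  al <- cp_table$alleles
  key <- apply(al, 1, paste, collapse = ":")
  uk <- unique(key)
  hap <- al[match(uk, key), , drop = FALSE]
  rownames(hap) <- paste0("H", seq_along(uk))
  locs <- sort(unique(cp_table$loc))
  tab <- table(factor(key, levels = uk),
               factor(cp_table$loc, levels = locs))
  counts <- matrix(as.integer(tab), nrow = length(uk),
                   dimnames = list(rownames(hap), locs))
  D <- as.matrix(dist(hap, method = "manhattan")) / motif_length
  dimnames(D) <- list(rownames(hap), rownames(hap))
  region_of <- vapply(locs, function(l)
    cp_table$region[match(l, cp_table$loc)], character(1))
  structure(list(haplotypes = hap, counts = counts,
                 total = rowSums(counts), D = D,
                 unique_location = rowSums(counts > 0) == 1L,
                 loci = cp_table$loci, locations = locs,
                 region_of = region_of),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat(sprintf("haplotype_catalog: %d haplotypes (%d unique to one location), %d individuals, %d locations\n",
              nrow(x$haplotypes), sum(x$unique_location), sum(x$total),
              length(x$locations)))
  invisible(x)
}

#' Export a haplotype catalog as JSON
#' @param catalog a `haplotype_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_catalog <- function(catalog, path) {
  obj <- list(loci = catalog$loci,
              locations = catalog$locations,
              haplotypes = lapply(seq_len(nrow(catalog$haplotypes)),
                                  function(i) list(
                id = rownames(catalog$haplotypes)[i],
                alleles = unname(catalog$haplotypes[i, ]),
                counts = as.list(setNames(catalog$counts[i, ],
                                          colnames(catalog$counts))),
                total = unname(catalog$total[i]),
                unique_location = unname(catalog$unique_location[i]))),
              distance = unname(apply(catalog$D, 1, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a JSON haplotype catalog
#' @param path JSON path produced by [write_haplotype_catalog()].
#' @return A `haplotype_catalog`.
#' @export
read_haplotype_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hap <- matrix(unlist(obj$haplotypes$alleles), byrow = TRUE,
                nrow = nrow(obj$haplotypes),
                dimnames = list(obj$haplotypes$id, obj$loci))
  counts <- as.matrix(obj$haplotypes$counts)
  rownames(counts) <- obj$haplotypes$id
  D <- matrix(unlist(obj$distance), byrow = TRUE, nrow = nrow(hap),
              dimnames = list(rownames(hap), rownames(hap)))
  structure(list(haplotypes = hap, counts = counts,
                 total = rowSums(counts), D = D,
                 unique_location = rowSums(counts > 0) == 1L,
                 loci = obj$loci, locations = obj$locations,
                 region_of = setNames(rep(NA_character_,
                                          length(obj$locations)),
                                      obj$locations)),
            class = "haplotype_catalog")
}
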