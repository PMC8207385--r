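# Phylogeographic permutation tests and the haplotype network.
#
# NST is the ordered-allele analogue of GST: both are (vT - vS)/vT with vS
# the unweighted mean within-location ordered diversity and vT the total
# diversity on unweighted mean haplotype frequencies (total-sample unbiased
# factor N/(N-1)).  GST uses the degenerate 0/1 distance matrix, so the
# identity "NST with 0/1 distances == GST" holds exactly by construction.
# Permuting haplotype identities in the distance matrix (pNST) erases the
# association between relatedness and co-occurrence: NST >> pNST (which
# approximates GST) indicates phylogeographic structure.

nst_statistic <- function(counts, D) {
  ok <- colSums(counts) >= 2
  counts <- counts[, ok, drop = FALSE]
  v_k <- apply(counts, 2, function(cc) ordered_diversity_v(cc, D))
  vS <- mean(v_k)
  freqs <- sweep(counts, 2, colSums(counts), "/")
  pbar <- rowMeans(freqs)
  N <- sum(counts)
  vT <- N / (N - 1) * as.numeric(t(pbar) %*% D %*% pbar)
  c(vS = vS, vT = vT, stat = (vT - vS) / vT)
}

#' NST / pNST phylogeographic permutation test (ordered haplotypes)
#'
#' @param catalog a `haplotype_catalog` (counts + step distances).
#' @param n_perm permutations of haplotype identities in the distance matrix.
#' @param seed RNG seed.
#' @return A `phylogeo_test`: `observed` (NST), `companion` (GST),
#'   `permuted_mean`/`permuted_sd` (pNST), `p`, `n_perm`, plus `vS`, `vT`.
#' @export
nst_test <- function(catalog, n_perm = 9999, seed = 1) {
  set.seed(seed)
  counts <- catalog$counts
  D <- catalog$D
  if (ncol(counts) < 2) stop("need >= 2 locations")
  if (nrow(counts) < 2) stop("need >= 2 haplotypes")
  obs <- nst_statistic(counts, D)
  D01 <- (D > 0) * 1
  gst <- nst_statistic(counts, D01)[["stat"]]
  perms <- vapply(seq_len(n_perm), function(i) {
    sh <- sample.int(nrow(D))
    nst_statistic(counts, D[sh, sh])[["stat"]]
  }, numeric(1))
  structure(list(observed = unname(obs[["stat"]]), companion = gst,
                 permuted_mean = mean(perms), permuted_sd = sd(perms),
                 p = perm_p(obs[["stat"]], perms), n_perm = n_perm,
                 vS = unname(obs[["vS"]]), vT = unname(obs[["vT"]]),
                 statistic = "NST", companion_name = "GST"),
            class = "phylogeo_test")
}

#' RST / pRST allele-size permutation test (nuclear stepwise signal)
#'
#' RST is Phi_ST from the SMM AMOVA across sampling locations.  The null
#' permutes, within each locus, the assignment of observed sizes to allelic
#' states (a random bijection among the distinct sizes) and recomputes RST;
#' under pure drift (no stepwise memory) RST is exchangeable with its
#' permuted version, which approximates FST.
#'
#' @param table diploid `genotype_table`, >= 2 locations.
#' @param n_perm size permutations.
#' @param seed RNG seed.
#' @param motif_length motif length in base pairs.
#' @return A `phylogeo_test`: `observed` (RST), `companion` (IAM Phi_ST,
#'   i.e. FST), `permuted_mean`/`permuted_sd` (pRST), one-sided `p`.
#' @export
rst_allele_size_test <- function(table, n_perm = 9999, seed = 1,
                                 motif_length = 1) {
  set.seed(seed)
  if (length(unique(table$loc)) < 2) stop("need >= 2 locations")
  units <- amova_units(table)
  excluded <- vapply(units, function(u)
    length(unique(u$alleles[, 1])) < 2, logical(1))
  if (any(excluded))
    message(sum(excluded), " monomorphic locus(i) excluded from permutation")
  rst_of <- function(us) {
    cmp <- sum_components(lapply(us, function(u)
      amova_components(unit_d2(u$alleles, "SMM", motif_length),
                       table$loc[u$ind])))
    unname(phi_of(cmp$sigma)["phi_ST"])
  }
  fst_cmp <- sum_components(lapply(units, function(u)
    amova_components(unit_d2(u$alleles, "IAM", motif_length),
                     table$loc[u$ind])))
  fst <- unname(phi_of(fst_cmp$sigma)["phi_ST"])
  obs <- rst_of(units[!excluded])
  perms <- vapply(seq_len(n_perm), function(i) {
    us <- lapply(units[!excluded], function(u) {
      sizes <- sort(unique(u$alleles[, 1]))
      remap <- setNames(sample(sizes), sizes)
      u$alleles[, 1] <- remap[as.character(u$alleles[, 1])]
      u
    })
    rst_of(us)
  }, numeric(1))
  structure(list(observed = obs, companion = fst,
                 permuted_mean = mean(perms), permuted_sd = sd(perms),
                 p = perm_p(obs, perms), n_perm = n_perm,
                 statistic = "RST", companion_name = "FST"),
            class = "phylogeo_test")
}

#' @export
print.phylogeo_test <- function(x, ...) {
  cat(sprintf("%s = %.4f; permuted %s = %.4f (SD %.4f); %s = %.4f; p = %.4g (%d perms)\n",
              x$statistic, x$observed, tolower(x$statistic),
              x$permuted_mean, x$permuted_sd, x$companion_name, x$companion,
              x$p, x$n_perm))
  invisible(x)
}

#' Minimum spanning network of haplotypes
#'
#' Kruskal's algorithm on step distances, retaining *all* co-minimal edges:
#' within a weight class, every edge joining two components that were
#' distinct when the class opened is kept, so equally parsimonious
#' alternative connections survive (a network, not a tree).  Edges that a
#' strict MST would drop are flagged `tie = TRUE`.
#'
#' @param catalog a `haplotype_catalog` with >= 2 haplotypes.
#' @return A `haplotype_network`: `nodes` (id, frequency, n_locations),
#'   `edges` (from, to, steps, tie), and `mst_weight` (Kruskal optimum).
#' @export
minimum_spanning_network <- function(catalog) {
  D <- catalog$D
  H <- nrow(D)
  if (H < 2) stop("need >= 2 haplotypes")
  ids <- rownames(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]

  parent <- seq_len(H)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- list()
  mst_weight <- 0
  for (wc in unique(w)) {
    in_class <- which(abs(w - wc) < 1e-9)
    snapshot <- vapply(seq_len(H), find, integer(1))
    for (k in in_class) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (snapshot[i] == snapshot[j]) next  # connected before this class
      tie <- find(i) == find(j)             # already joined within class
      edges[[length(edges) + 1L]] <-
        data.frame(from = ids[i], to = ids[j], steps = wc, tie = tie,
                   stringsAsFactors = FALSE)
      if (!tie) {
        mst_weight <- mst_weight + wc
        ri <- find(i); rj <- find(j)
        parent[ri] <- rj
      }
    }
  }
  edges <- do.call(rbind, edges)
  nodes <- data.frame(id = ids, frequency = as.integer(catalog$total),
                      n_locations = as.integer(rowSums(catalog$counts > 0)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, mst_weight = mst_weight),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges (%d ties), MST weight %.1f\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$tie), x$mst_weight))
  invisible(x)
}

#' Write a haplotype network as edge-list CSV (and optional GraphML)
#'
#' @param network a `haplotype_network`.
#' @param path edge-list CSV path.
#' @param graphml optional GraphML output path (via igraph).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml = NULL) {
  write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
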