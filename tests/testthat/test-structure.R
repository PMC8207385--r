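test_that("AMOVA trivial cases: identical data and fixed differences", {
  al <- matrix(10L, 8, 1)
  tb <- genotype_table(paste0("i", 1:8), rep(c("A", "B"), each = 4),
                       rep("r", 8), al, "c1", 1L)
  a <- amova(tb, "IAM", n_perm = 0)
  expect_true(all(a$table$sigma2 == 0))
  expect_true("zero_total_variance" %in% a$flags)
  al2 <- matrix(rep(c(10L, 20L), each = 4), 8, 1)
  a2 <- amova(tb <- genotype_table(paste0("i", 1:8),
                                   rep(c("A", "B"), each = 4), rep("r", 8),
                                   al2, "c1", 1L), "IAM", n_perm = 99,
              seed = 1)
  expect_equal(unname(a2$phi["phi_ST"]), 1)
  expect_equal(a2$table$percent[a2$table$level == "among_locations"], 100)
})

test_that("AMOVA matches the brute-force SSD decomposition on a 12-copy toy", {
  # 12 haploid copies, 3 locations in 2 regions, printed allele list
  sizes <- c(10, 12, 12, 14,   16, 16, 18, 12,   22, 24, 22, 10)
  loc <- rep(c("A", "B", "C"), each = 4)
  reg <- rep(c("r1", "r1", "r2"), each = 4)
  tb <- genotype_table(paste0("i", 1:12), loc, reg,
                       matrix(as.integer(sizes), 12, 1), "c1", 1L)
  for (model in c("IAM", "SMM")) {
    d2 <- if (model == "IAM") outer(sizes, sizes, "!=") * 1
    else outer(sizes, sizes, "-")^2
    want <- brute_amova(d2, loc, reg)
    got <- amova(tb, model, n_perm = 0)
    expect_equal(got$table$sigma2, unname(want), tolerance = 1e-10)
    expect_equal(sum(got$table$percent), 100, tolerance = 1e-6)
    expect_equal(sum(got$table$df), 11)
    # two-level design against the same oracle
    want2 <- brute_amova(d2, loc)
    tb2 <- tb; tb2$region <- rep("r", 12)
    got2 <- amova(tb2, model, n_perm = 0)
    expect_equal(got2$table$sigma2, unname(want2), tolerance = 1e-10)
  }
})

test_that("diploid AMOVA sums per-locus components; df = gene copies - 1", {
  d <- simulate_dataset(n_demes = 4, n_per_deme = 6, n_nssr = 3,
                        target_fst = 0.2, seed = 31)
  a <- amova(d$nuclear, "IAM", n_perm = 49, seed = 1)
  # complete data: sum of per-locus df = n_loci * (2n - 1)
  expect_equal(sum(a$table$df), 3 * (2 * n_ind(d$nuclear) - 1))
  expect_equal(sum(a$table$percent), 100, tolerance = 1e-6)
  expect_gt(a$phi["phi_ST"], 0)
  expect_true(all(a$p >= 0 & a$p <= 1, na.rm = TRUE))
})

test_that("IAM Phi_ST approximates Weir-Cockerham theta on balanced data", {
  d <- simulate_dataset(n_demes = 6, n_per_deme = 10, target_fst = 0.15,
                        seed = 37)
  a <- amova(d$nuclear, "IAM", n_perm = 0, use_regions = FALSE)
  th <- fst_weir_cockerham(d$nuclear)$theta
  expect_lt(abs(unname(a$phi["phi_ST"]) - th), 0.02)
})

test_that("NST: metric degeneracy, fixed distant haplotypes, invariances", {
  cat <- extract_haplotypes(toy_haploid())
  # 0/1 distances -> NST == GST exactly
  cat01 <- cat
  cat01$D <- (cat$D > 0) * 1
  r <- nst_test(cat01, n_perm = 99, seed = 1)
  expect_equal(r$observed, r$companion)
  # scaling D leaves NST unchanged
  cat10 <- cat
  cat10$D <- cat$D * 10
  expect_equal(nst_test(cat10, n_perm = 19, seed = 1)$observed,
               nst_test(cat, n_perm = 19, seed = 1)$observed)
  # two locations fixed for haplotypes 10 steps apart -> NST ~ 1
  al <- matrix(c(rep(10L, 5), rep(20L, 5)), 10, 1)
  tb <- genotype_table(paste0("i", 1:10), rep(c("A", "B"), each = 5),
                       rep(c("r1", "r2"), each = 5), al, "c1", 1L)
  catf <- extract_haplotypes(tb)
  rf <- nst_test(catf, n_perm = 99, seed = 1)
  expect_equal(rf$vS, 0)
  expect_gt(rf$observed, 0.95)
})

test_that("NST detects phylogeographic sorting; pNST approximates GST", {
  # locations fixed for clusters of RELATED haplotypes: steps within
  # location small, between locations large (3 clusters of 3 haplotypes so
  # that structure-preserving label permutations are rare)
  al <- matrix(c(rep(c(10L, 11L, 12L), 2), rep(c(30L, 31L, 32L), 2),
                 rep(c(50L, 51L, 52L), 2)), ncol = 1)
  tb <- genotype_table(paste0("i", 1:18), rep(c("A", "B", "C"), each = 6),
                       rep("r", 18), al, "c1", 1L)
  cat <- extract_haplotypes(tb)
  r <- nst_test(cat, n_perm = 999, seed = 2)
  expect_gt(r$observed, r$permuted_mean + 2 * r$permuted_sd)
  expect_lte(r$p, 0.05)
  # the permuted mean approximates GST (identity-only differentiation)
  expect_lt(abs(r$permuted_mean - r$companion), 0.25)
})

test_that("RST allele-size test: stepwise divergence detected, null sane", {
  # stepwise-diverged demes: sizes drift apart by deme index
  set.seed(41)
  n_deme <- 4; n_per <- 12
  al <- NULL
  for (k in seq_len(n_deme)) {
    center <- 100 + 6 * k
    a <- matrix(center + sample(-1:1, n_per * 2, TRUE), n_per, 2)
    al <- rbind(al, a)
  }
  tb <- genotype_table(paste0("i", seq_len(n_deme * n_per)),
                       rep(paste0("d", seq_len(n_deme)), each = n_per),
                       rep("r", n_deme * n_per), al, "L1", 2L)
  r <- rst_allele_size_test(tb, n_perm = 199, seed = 3)
  expect_gt(r$observed, r$permuted_mean)
  expect_lte(r$p, 0.05)
  # randomly assigned sizes: RST ~ pRST, p typically > 0.05
  set.seed(42)
  al2 <- matrix(sample(c(100L, 104L, 110L, 120L), n_deme * n_per * 2,
                       TRUE), n_deme * n_per, 2)
  tb2 <- genotype_table(tb$ind, tb$loc, tb$region, al2, "L1", 2L)
  r2 <- rst_allele_size_test(tb2, n_perm = 199, seed = 4)
  expect_gt(r2$p, 0.05)
  # single location errors
  tb3 <- tb; tb3$loc <- rep("one", n_ind(tb))
  expect_error(rst_allele_size_test(tb3), ">= 2 locations")
})

test_that("minimum spanning network: line, ties, MST optimality", {
  # 3 haplotypes in a line (d = 1, 1, 2): only the two 1-step edges
  mk_cat <- function(hapmat, counts) {
    al <- hapmat[rep(seq_len(nrow(hapmat)), counts), , drop = FALSE]
    tb <- genotype_table(paste0("i", seq_len(sum(counts))),
                         rep("A", sum(counts)), rep("r", sum(counts)),
                         al, paste0("c", seq_len(ncol(hapmat))), 1L)
    extract_haplotypes(tb)
  }
  cat <- mk_cat(matrix(c(10L, 11L, 12L), 3, 1), c(2, 2, 2))
  net <- minimum_spanning_network(cat)
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$steps == 1))
  expect_equal(net$mst_weight, 2)
  # square of haplotypes: four co-minimal 1-step edges, one of which a
  # strict MST would drop -> all retained, exactly one flagged as tie
  cat2 <- mk_cat(matrix(c(10L, 10L,
                          11L, 11L,
                          10L, 11L,
                          11L, 10L), 4, 2, byrow = TRUE), c(1, 1, 1, 1))
  net2 <- minimum_spanning_network(cat2)
  expect_equal(nrow(net2$edges), 4)
  expect_equal(sum(net2$edges$tie), 1)
  expect_true(all(net2$edges$steps == 1))
  expect_equal(net2$mst_weight, 3)
  g <- igraph::graph_from_data_frame(net2$edges, directed = FALSE,
                                     vertices = net2$nodes)
  expect_true(igraph::is_connected(g))
  # MST weight equals igraph's Kruskal optimum on a random catalog
  d <- simulate_dataset(n_demes = 4, n_per_deme = 8, seed = 43)
  cat3 <- extract_haplotypes(d$cp)
  net3 <- minimum_spanning_network(cat3)
  gg <- igraph::graph_from_adjacency_matrix(cat3$D, mode = "undirected",
                                            weighted = TRUE)
  expect_equal(net3$mst_weight,
               sum(igraph::E(igraph::mst(gg))$weight))
  # every non-tie edge set contains a spanning tree
  core <- net3$edges[!net3$edges$tie, ]
  gc <- igraph::graph_from_data_frame(core, directed = FALSE,
                                      vertices = net3$nodes)
  expect_true(igraph::is_connected(gc))
  expect_equal(nrow(core), nrow(net3$nodes) - 1)
})
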