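test_that("scenario_spec validates epochs and bottleneck constraints", {
  expect_error(scenario_spec(1, data.frame(t = 5, ne = 100)), "t = 0")
  expect_error(scenario_spec(1, data.frame(t = c(0, 0), ne = c(1, 1))),
               "strictly increasing")
  expect_error(scenario_spec(3, data.frame(t = c(0, 10, 20),
                                           ne = c(100, 500, 100))),
               "bottleneck")
  sp <- scenario_spec(3, data.frame(t = c(0, 10, 20),
                                    ne = c(1000, 10, 500)))
  expect_s3_class(sp, "scenario_spec")
})

test_that("coalescent simulator: monomorphic at mu = 0, theta scaling", {
  sp <- scenario_spec(1, data.frame(t = 0, ne = 1000))
  s <- simulate_coalescent_msat(20, sp, 0, 5, seed = 1)
  expect_true(all(s == 100))
  # pairwise E[(x1-x2)^2] = theta = 4*N*mu (TMRCA = 2N generations)
  set.seed(2)
  N <- 500; mu <- 1e-3
  s2 <- simulate_coalescent_msat(2, scenario_spec(1, data.frame(t = 0, ne = N)),
                                 mu, 4000)
  msd <- mean((s2[1, ] - s2[2, ])^2)
  expect_gt(msd, 4 * N * mu * 0.85)
  expect_lt(msd, 4 * N * mu * 1.15)
  expect_error(simulate_coalescent_msat(20, data.frame(t = c(0, 5, 5),
                                                       ne = c(1, 1, 1)),
                                        1e-3, 2),
               "increasing")
})

test_that("linked loci share one genealogy", {
  # for pairs of copies, |size difference| across linked loci co-varies
  # (shared TMRCA); unlinked loci do not
  sp <- scenario_spec(1, data.frame(t = 0, ne = 1000))
  reps <- 300
  d_linked <- d_free <- matrix(0, reps, 2)
  set.seed(3)
  for (i in seq_len(reps)) {
    a <- simulate_coalescent_msat(2, sp, 2e-3, 2, linked = TRUE)
    b <- simulate_coalescent_msat(2, sp, 2e-3, 2, linked = FALSE)
    d_linked[i, ] <- abs(a[1, ] - a[2, ])
    d_free[i, ] <- abs(b[1, ] - b[2, ])
  }
  expect_gt(cor(d_linked[, 1], d_linked[, 2]), 0.2)
  expect_lt(abs(cor(d_free[, 1], d_free[, 2])), 0.15)
})

test_that("summary_stats: hand case, monomorphic pattern, relabeling", {
  x <- matrix(rep(c(10L, 12L), each = 10), ncol = 1)
  st <- summary_stats(cbind(x, x))
  expect_equal(unname(st["mean_He"]), 20 / 19 * 0.5)
  expect_equal(unname(st["mean_V"]), 1)
  expect_equal(unname(st["mean_M"]), 2 / 3)
  mono <- matrix(100L, 10, 3)
  stm <- summary_stats(mono)
  expect_equal(unname(stm[c("mean_A", "mean_He", "mean_V", "mean_M")]),
               c(1, 0, 0, 1))
  expect_true(all(stm[c("var_A", "var_He", "var_V", "var_M")] == 0))
  set.seed(4)
  y <- matrix(sample(95:105, 60, TRUE), 20, 3)
  expect_equal(summary_stats(y), summary_stats(y[sample(20), ]))
})

test_that("reference table: determinism, prior bounds, scenario balance", {
  ref1 <- generate_reference_table(300, n_copies = 30, n_loci = 4, seed = 5)
  ref2 <- generate_reference_table(300, n_copies = 30, n_loci = 4, seed = 5)
  expect_identical(ref1, ref2)
  pri <- default_priors()
  expect_true(all(ref1$N1 >= pri$ne[1] & ref1$N1 <= pri$ne[2]))
  tt <- ref1$t1[!is.na(ref1$t1)]
  expect_true(all(tt >= pri$t[1] & tt <= pri$t[2]))
  i3 <- ref1$scenario == 3
  expect_true(all(ref1$N2[i3] < pmin(ref1$N1[i3], ref1$N3[i3])))
  expect_true(all(ref1$t1[i3] < ref1$t2[i3]))
  cnt <- table(ref1$scenario)
  expect_true(all(cnt > 60 & cnt < 140))  # multinomial around 100
  expect_error(generate_reference_table(10, 10, 2,
                                        priors = list(ne = c(-1, 5),
                                                      t = c(1, 2),
                                                      mu = c(1e-4, 1e-3))),
               "prior misspecification")
})

test_that("model choice: degenerate single-scenario table, small-table guard", {
  ref <- generate_reference_table(400, n_copies = 30, n_loci = 4,
                                  scenarios = 3, seed = 6)
  mc <- abc_model_choice(ref, as.numeric(ref[1, grep("^stat_", names(ref))]),
                         tolerance = 0.1, n_closest_direct = 50)
  expect_equal(unname(mc$direct), 1)
  expect_equal(unname(mc$logistic), 1)
  ref_small <- ref[1:20, ]
  ref_small$scenario <- rep(1:3, length.out = 20)  # 20 rows < 3 x 10
  expect_error(abc_model_choice(ref_small, rep(0, 8)), "too small")
})

test_that("posterior probabilities sum to 1 and resist stat rescaling", {
  ref <- generate_reference_table(1500, n_copies = 30, n_loci = 4, seed = 7)
  sc <- grep("^stat_", names(ref))
  obs <- as.numeric(ref[10, sc])
  mc <- abc_model_choice(ref[-10, ], obs, tolerance = 0.05,
                         n_closest_direct = 100)
  expect_equal(sum(mc$direct), 1)
  expect_equal(sum(mc$logistic), 1, tolerance = 1e-6)
  # rescaling a statistic leaves the standardized distances unchanged
  ref2 <- ref
  ref2[[sc[5]]] <- ref2[[sc[5]]] * 1000
  obs2 <- obs; obs2[5] <- obs2[5] * 1000
  mc2 <- abc_model_choice(ref2[-10, ], obs2, tolerance = 0.05,
                          n_closest_direct = 100)
  expect_equal(mc2$direct, mc$direct)
})

test_that("parameter estimation: prior at tolerance 1, generation time scaling", {
  ref <- generate_reference_table(3000, n_copies = 30, n_loci = 4,
                                  scenarios = 3, seed = 8)
  sc <- grep("^stat_", names(ref))
  obs <- as.numeric(ref[1, sc])
  est1 <- abc_parameter_estimation(ref, obs, scenario = 3, tolerance = 1)
  q <- quantile(ref$t2, c(0.05, 0.95))
  row <- est1[est1$parameter == "t2", ]
  expect_equal(row$q05, unname(q[1]), tolerance = 0.02)
  expect_equal(row$q95, unname(q[2]), tolerance = 0.02)
  expect_false(attr(est1, "adjusted"))
  # years rows are times x generation_time; generation_time = 1 -> equal
  est2 <- abc_parameter_estimation(ref, obs, scenario = 3, tolerance = 0.05,
                                   generation_time = 1)
  t2 <- est2[est2$parameter == "t2", -1]
  t2y <- est2[est2$parameter == "t2_years", -1]
  expect_equal(unname(unlist(t2)), unname(unlist(t2y)))
  est3 <- abc_parameter_estimation(ref, obs, scenario = 3, tolerance = 0.05,
                                   generation_time = 100)
  expect_equal(est3[est3$parameter == "t1_years", "mean"],
               100 * est3[est3$parameter == "t1", "mean"])
  expect_true(all(est3$q05 <= est3$mean & est3$mean <= est3$q95))
})

# hand-built reference tables with controlled stat geometry
fake_ref <- function(n_per, shift, seed = 1) {
  set.seed(seed)
  scen <- rep(1:3, each = n_per)
  stats <- matrix(rnorm(3 * n_per * 8), 3 * n_per, 8)
  stats <- stats + shift * (scen - 2)  # scenario-dependent mean shift
  colnames(stats) <- paste0("stat_", c("mean_A", "var_A", "mean_He",
                                       "var_He", "mean_V", "var_V",
                                       "mean_M", "var_M"))
  data.frame(scenario = scen, N1 = runif(3 * n_per, 10, 20),
             N2 = NA_real_, N3 = NA_real_, t1 = NA_real_, t2 = NA_real_,
             stats)
}

test_that("scenario_confidence: separable scenarios are error-free,
           identical scenarios give type I near 2/3", {
  ref_sep <- fake_ref(200, shift = 50)
  obs <- as.numeric(ref_sep[500, grep("^stat_", names(ref_sep))])
  conf <- scenario_confidence(ref_sep, obs, x = 3, n_pods = 60,
                              n_closest = 60, n_closest_direct = 50,
                              seed = 1)
  expect_equal(conf$posterior_error[1], 0)
  expect_equal(conf$type1[1], 0)
  expect_equal(conf$type2[1], 0)
  ref_same <- fake_ref(200, shift = 0)
  conf2 <- scenario_confidence(ref_same, obs, x = 3, n_pods = 100,
                               n_closest = 60, n_closest_direct = 50,
                               seed = 2)
  expect_gt(conf2$type1[1], 0.5)
  expect_lt(conf2$type1[1], 0.8)   # ~ 1 - 1/3
  expect_error(scenario_confidence(ref_same, obs, n_pods = 1e6), "exceeds")
})
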