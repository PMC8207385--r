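# Approximate Bayesian computation for single-population demography.
#
# Three scenarios are compared on nuclear microsatellites pooled as one
# population: (1) constant effective size; (2) expansion (a single stepwise
# size change, the usual discretisation of a progressive expansion); (3) a
# bottleneck followed by a recent expansion (backward in time: current size,
# then the bottleneck size, then the ancestral size, with the bottleneck
# smaller than both).  Loci follow the strict stepwise mutation model with
# per-locus rates drawn from a log-uniform prior on [1e-4, 1e-3].  Epoch
# times are in generations; a generation time (default 100 years for oaks)
# converts posterior times to years.

#' Scenario specification
#'
#' @param id scenario id: 1 (constant), 2 (expansion), 3
#'   (bottleneck + expansion).
#' @param epochs data frame with columns `t` (start time in generations,
#'   strictly increasing from 0) and `ne` (effective size during the epoch).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(id, epochs) {
  stopifnot(is.data.frame(epochs), all(c("t", "ne") %in% names(epochs)))
  if (epochs$t[1] != 0) stop("first epoch must start at t = 0")
  if (any(diff(epochs$t) <= 0)) stop("times must be strictly increasing")
  if (any(epochs$ne <= 0)) stop("Ne must be > 0")
  if (id == 3) {
    if (nrow(epochs) != 3) stop("scenario 3 needs 3 epochs")
    if (!(epochs$ne[2] < epochs$ne[1] && epochs$ne[2] < epochs$ne[3]))
      stop("scenario 3 bottleneck must be smaller than current and ancestral sizes")
  }
  structure(list(id = id, epochs = epochs), class = "scenario_spec")
}

#' Default priors for the three demographic scenarios
#'
#' Deliberately broad surrogate defaults for Andean tree microsatellites:
#' effective sizes log-uniform on \[1e2, 1e6\]; event times uniform on
#' \[10, 10000\] generations; per-locus mutation rate log-uniform on
#' \[1e-4, 1e-3\].
#'
#' @return Named list of prior ranges.
#' @export
default_priors <- function() {
  list(ne = c(1e2, 1e6), t = c(10, 10000), mu = c(1e-4, 1e-3))
}

runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Draw one scenario parameterisation from the priors
#'
#' Scenario 3 respects its constraints (t1 < t2 via sorting; the bottleneck
#' size is drawn log-uniformly below min(N_current, N_ancestral)).
#'
#' @param id scenario id (1, 2 or 3).
#' @param priors prior list as from [default_priors()].
#' @return A `scenario_spec` with a `params` attribute (named vector).
#' @export
draw_scenario <- function(id, priors = default_priors()) {
  ne <- priors$ne; tt <- priors$t
  if (id == 1) {
    n1 <- runif_log(1, ne[1], ne[2])
    sp <- scenario_spec(1, data.frame(t = 0, ne = n1))
    attr(sp, "params") <- c(N1 = n1)
  } else if (id == 2) {
    sizes <- sort(runif_log(2, ne[1], ne[2]))  # ancestral smaller: expansion
    t1 <- runif(1, tt[1], tt[2])
    sp <- scenario_spec(2, data.frame(t = c(0, t1),
                                      ne = c(sizes[2], sizes[1])))
    attr(sp, "params") <- c(N1 = sizes[2], N2 = sizes[1], t1 = t1)
  } else if (id == 3) {
    ncur <- runif_log(1, ne[1], ne[2])
    nanc <- runif_log(1, ne[1], ne[2])
    nbot <- runif_log(1, ne[1], min(ncur, nanc))
    ts <- sort(runif(2, tt[1], tt[2]))
    if (ts[2] - ts[1] < 1) ts[2] <- ts[1] + 1
    sp <- scenario_spec(3, data.frame(t = c(0, ts[1], ts[2]),
                                      ne = c(ncur, nbot, nanc)))
    attr(sp, "params") <- c(N1 = ncur, N2 = nbot, N3 = nanc,
                            t1 = ts[1], t2 = ts[2])
  } else stop("unknown scenario id ", id)
  sp
}

#' Simulate a microsatellite sample under the coalescent with SMM mutation
#'
#' Kingman coalescent with piecewise-constant effective size; mutations are
#' strict single-step with per-locus rate `mu`.  `linked = TRUE` (cpSSR)
#' places all loci on one shared genealogy; otherwise each locus draws an
#' independent genealogy.
#'
#' @param n_copies number of gene copies (>= 2).
#' @param scenario a `scenario_spec` (or data frame of epochs).
#' @param mu mutation rate(s) per locus per generation (recycled).
#' @param n_loci number of loci.
#' @param linked share one genealogy across loci.
#' @param ancestral ancestral allele size in motif units (default 100; all
#'   summary statistics are translation invariant).
#' @param seed optional RNG seed.
#' @return Integer matrix `n_copies x n_loci` of allele sizes.
#' @export
simulate_coalescent_msat <- function(n_copies, scenario, mu, n_loci,
                                     linked = FALSE, ancestral = 100,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  epochs <- if (inherits(scenario, "scenario_spec")) scenario$epochs
  else as.data.frame(scenario)
  mu <- rep_len(mu, n_loci)
  .sim_msat_cpp(as.integer(n_copies), as.numeric(epochs$t),
                as.numeric(epochs$ne), as.numeric(mu),
                as.integer(n_loci), isTRUE(linked), as.integer(ancestral))
}

#' Summary statistics of a microsatellite sample
#'
#' Mean and variance across loci of: allele count A, unbiased expected
#' heterozygosity He, allele-size variance (population variance), and
#' Garza-Williamson `M = A / (size range + 1)`.
#'
#' @param sample copies x loci integer matrix of allele sizes.
#' @return Named numeric vector of length 8.
#' @export
summary_stats <- function(sample) {
  .msat_stats_cpp(as.matrix(sample))
}

#' Generate an ABC reference table
#'
#' Rows of (scenario id, drawn parameters, summary statistics), scenarios
#' equiprobable a priori.  Fully reproducible from `seed`.
#'
#' @param n_sims number of simulated datasets.
#' @param n_copies gene copies per dataset (the observed design, pooled).
#' @param n_loci loci per dataset.
#' @param scenarios scenario ids to include (default 1:3).
#' @param priors prior list (validated before any simulation).
#' @param seed RNG seed.
#' @param progress_every log a progress line every this many simulations
#'   (0 = silent).
#' @return Data frame: `scenario`, parameter columns (NA where a scenario
#'   lacks the parameter), eight `stat_*` columns.
#' @export
generate_reference_table <- function(n_sims, n_copies, n_loci,
                                     scenarios = 1:3,
                                     priors = default_priors(), seed = 1,
                                     progress_every = 0) {
  stopifnot(n_sims >= 1)
  if (!all(c("ne", "t", "mu") %in% names(priors)))
    stop("prior misspecification: need ne, t and mu ranges")
  for (nmp in c("ne", "t", "mu")) {
    rng <- priors[[nmp]]
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] <= 0 ||
        rng[2] <= rng[1])
      stop("prior misspecification for '", nmp, "'")
  }
  set.seed(seed)
  pnames <- c("N1", "N2", "N3", "t1", "t2")
  scen <- scenarios[sample.int(length(scenarios), n_sims, replace = TRUE)]
  params <- matrix(NA_real_, n_sims, length(pnames),
                   dimnames = list(NULL, pnames))
  stats <- matrix(NA_real_, n_sims, 8)
  for (i in seq_len(n_sims)) {
    sp <- draw_scenario(scen[i], priors)
    pp <- attr(sp, "params")
    params[i, names(pp)] <- pp
    mu <- runif_log(n_loci, priors$mu[1], priors$mu[2])
    s <- simulate_coalescent_msat(n_copies, sp, mu, n_loci)
    stats[i, ] <- summary_stats(s)
    if (progress_every > 0 && i %% progress_every == 0)
      message("reference table: ", i, "/", n_sims)
  }
  colnames(stats) <- paste0("stat_", c("mean_A", "var_A", "mean_He",
                                       "var_He", "mean_V", "var_V",
                                       "mean_M", "var_M"))
  out <- data.frame(scenario = scen, params, stats)
  attr(out, "design") <- list(n_copies = n_copies, n_loci = n_loci,
                              priors = priors, seed = seed)
  out
}

stat_cols <- function(ref) grep("^stat_", names(ref), value = TRUE)

# Standardized Euclidean distances of reference rows from observed stats.
# Scale = MAD of each stat over the reference table, SD fallback.
abc_distances <- function(ref, observed_stats) {
  sc <- stat_cols(ref)
  S <- as.matrix(ref[, sc])
  obs <- as.numeric(observed_stats)[seq_along(sc)]
  scale <- apply(S, 2, mad)
  sdv <- apply(S, 2, sd)
  scale[scale <= 0] <- sdv[scale <= 0]
  scale[scale <= 0] <- 1
  Z <- sweep(S, 2, scale, "/")
  zobs <- obs / scale
  sqrt(rowSums(sweep(Z, 2, zobs)^2))
}

# Epanechnikov-weighted multinomial logistic regression evaluated at the
# observed point (stats standardized within the retained set; the observed
# point is the origin, so the fitted intercepts give the posterior logits).
logistic_posterior <- function(stats, scen, w, scenarios) {
  S <- length(scenarios)
  if (S == 1) return(setNames(1, scenarios))
  X <- cbind(1, stats)
  y <- match(scen, scenarios)
  k <- ncol(X)
  nll <- function(beta) {
    B <- matrix(beta, k, S - 1)
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    ll <- eta[cbind(seq_along(y), y)] - (m + log(rowSums(exp(eta - m))))
    -sum(w * ll)
  }
  grad <- function(beta) {
    B <- matrix(beta, k, S - 1)
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    P <- exp(eta - m) / rowSums(exp(eta - m))
    Y <- matrix(0, length(y), S)
    Y[cbind(seq_along(y), y)] <- 1
    -as.vector(t(X) %*% (w * (Y - P))[, -1, drop = FALSE])
  }
  fit <- optim(rep(0, k * (S - 1)), nll, grad, method = "BFGS",
               control = list(maxit = 500))
  B <- matrix(fit$par, k, S - 1)
  eta0 <- c(0, B[1, ])  # observed point is the origin
  p <- exp(eta0 - max(eta0))
  setNames(p / sum(p), scenarios)
}

#' ABC scenario choice (direct rejection + logistic regression)
#'
#' Distances are Euclidean on reference-standardized statistics.  The direct
#' estimate is the scenario frequency among the `n_closest_direct` nearest
#' rows; the logistic estimate fits an Epanechnikov-weighted multinomial
#' logistic regression of scenario on (centred) statistics over the
#' `tolerance` fraction and evaluates it at the observed point.  Optional
#' nonparametric bootstrap over retained rows gives 90% CIs.
#'
#' @param ref reference table from [generate_reference_table()].
#' @param observed_stats length-8 statistic vector of the observed data.
#' @param tolerance retained fraction for the logistic step (default 0.01).
#' @param n_closest_direct rows for the direct estimate (default 500).
#' @param n_boot bootstrap resamples for CIs (default 0 = none).
#' @param seed RNG seed (bootstrap only).
#' @return An `abc_model_choice`: `direct`, `logistic`, `ci_direct`,
#'   `ci_logistic` (or NULL), `best` (scenario id by logistic, direct as
#'   tie-break), `n_retained`.
#' @export
abc_model_choice <- function(ref, observed_stats, tolerance = 0.01,
                             n_closest_direct = 500, n_boot = 0, seed = 1) {
  if (!nrow(ref)) stop("empty reference table")
  scenarios <- sort(unique(ref$scenario))
  n_keep <- max(ceiling(tolerance * nrow(ref)), length(scenarios) * 10)
  if (nrow(ref) < length(scenarios) * 10)
    stop("reference table too small; simulate more rows")
  d <- abc_distances(ref, observed_stats)
  ord <- order(d)
  direct_of <- function(idx) {
    nd <- min(n_closest_direct, length(idx))
    tab <- table(factor(ref$scenario[idx[seq_len(nd)]], levels = scenarios))
    as.numeric(tab) / nd
  }
  direct <- setNames(direct_of(ord), scenarios)

  keep <- ord[seq_len(min(n_keep, nrow(ref)))]
  dmax <- max(d[keep])
  w <- 1 - (d[keep] / dmax)^2  # Epanechnikov
  w[w <= 0] <- 1e-8
  sc <- stat_cols(ref)
  S <- as.matrix(ref[keep, sc])
  scl <- apply(S, 2, mad)
  sdv <- apply(S, 2, sd)
  scl[scl <= 0] <- sdv[scl <= 0]; scl[scl <= 0] <- 1
  Z <- sweep(sweep(S, 2, as.numeric(observed_stats)[seq_along(sc)]), 2,
             scl, "/")
  logi <- logistic_posterior(Z, ref$scenario[keep], w, scenarios)

  ci_direct <- ci_logistic <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    bd <- matrix(NA_real_, n_boot, length(scenarios))
    bl <- matrix(NA_real_, n_boot, length(scenarios))
    nd <- min(n_closest_direct, length(ord))
    for (b in seq_len(n_boot)) {
      rs <- sample(seq_along(keep), length(keep), replace = TRUE)
      bl[b, ] <- tryCatch(
        logistic_posterior(Z[rs, , drop = FALSE],
                           ref$scenario[keep][rs], w[rs], scenarios),
        error = function(e) rep(NA_real_, length(scenarios)))
      rs_d <- sample(seq_len(nd), nd, replace = TRUE)
      tab <- table(factor(ref$scenario[ord[rs_d]], levels = scenarios))
      bd[b, ] <- as.numeric(tab) / nd
    }
    qs <- function(m) apply(m, 2, quantile, c(0.05, 0.95), na.rm = TRUE)
    ci_direct <- qs(bd); ci_logistic <- qs(bl)
    colnames(ci_direct) <- colnames(ci_logistic) <- scenarios
  }
  best <- scenarios[which.max(logi + 1e-9 * direct)]
  structure(list(direct = direct, logistic = logi, ci_direct = ci_direct,
                 ci_logistic = ci_logistic, best = best,
                 n_retained = length(keep), tolerance = tolerance),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (best:", x$best, ")\n")
  print(round(rbind(direct = x$direct, logistic = x$logistic), 4))
  invisible(x)
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[min(which(cw >= p))], numeric(1))
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Retains the `tolerance` fraction of rows of the best scenario closest to
#' the observed statistics, regresses each parameter on the standardized
#' statistics with Epanechnikov weights (Beaumont local-linear adjustment),
#' and reports weighted posterior mean and 5%/95% quantiles of the adjusted
#' values; times are also reported in years via `generation_time`.
#'
#' @param ref reference table filtered (or filterable) to one scenario.
#' @param observed_stats observed statistic vector.
#' @param scenario scenario id to condition on (default: the only one).
#' @param tolerance retained fraction (default 0.01; 1 returns the prior).
#' @param generation_time years per generation (default 100).
#' @param min_retained error below this many retained rows (default 50).
#' @return Data frame: parameter, mean, q05, q95, and `*_years` rows for
#'   time parameters; attribute `adjusted = FALSE` if the regression was
#'   singular and the unadjusted rejection posterior was used.
#' @export
abc_parameter_estimation <- function(ref, observed_stats, scenario = NULL,
                                     tolerance = 0.01,
                                     generation_time = 100,
                                     min_retained = 50) {
  if (is.null(scenario)) {
    scenario <- unique(ref$scenario)
    if (length(scenario) > 1)
      stop("reference table holds several scenarios; pass `scenario`")
  }
  sub <- ref[ref$scenario == scenario, , drop = FALSE]
  pnames <- c("N1", "N2", "N3", "t1", "t2")
  pnames <- pnames[colSums(!is.na(sub[, pnames, drop = FALSE])) > 0]
  if (tolerance >= 1) {
    # no-data limit: retaining everything with uniform weights and no
    # adjustment returns the prior sample
    keep <- seq_len(nrow(sub))
    w <- rep(1, nrow(sub))
  } else {
    d <- abc_distances(sub, observed_stats)
    n_keep <- max(ceiling(tolerance * nrow(sub)), 2)
    if (n_keep < min_retained)
      stop("fewer than ", min_retained, " retained rows; enlarge the table")
    keep <- order(d)[seq_len(min(n_keep, nrow(sub)))]
    dmax <- max(d[keep])
    w <- if (dmax > 0) 1 - (d[keep] / dmax)^2 else rep(1, length(keep))
    w[w <= 0] <- 1e-8
  }
  sc <- stat_cols(sub)
  S <- as.matrix(sub[keep, sc])
  scl <- apply(as.matrix(sub[, sc]), 2, mad)
  sdv <- apply(as.matrix(sub[, sc]), 2, sd)
  scl[scl <= 0] <- sdv[scl <= 0]; scl[scl <= 0] <- 1
  Z <- sweep(sweep(S, 2, as.numeric(observed_stats)[seq_along(sc)]), 2,
             scl, "/")
  # drop constant columns within the retained set
  keepcol <- apply(Z, 2, function(col) sd(col) > 1e-12)
  Zr <- Z[, keepcol, drop = FALSE]
  adjusted <- TRUE
  rows <- list()
  for (pn in pnames) {
    # parameters are positive and heavy-tailed: adjust on the log scale
    # (the DIYABC convention), back-transform for reporting
    theta <- log(sub[keep, pn])
    adj <- theta
    if (tolerance >= 1) {
      adjusted <- FALSE
    } else if (ncol(Zr) > 0) {
      X <- cbind(1, Zr)
      XtW <- t(X * w)
      fit <- tryCatch(solve(XtW %*% X, XtW %*% theta),
                      error = function(e) NULL)
      if (is.null(fit)) adjusted <- FALSE
      else adj <- theta - as.numeric(Zr %*% fit[-1])
    } else adjusted <- FALSE
    q <- exp(weighted_quantile(adj, w, c(0.05, 0.95)))
    rows[[pn]] <- data.frame(parameter = pn,
                             mean = exp(weighted.mean(adj, w)),
                             q05 = q[1], q95 = q[2])
  }
  out <- do.call(rbind, rows)
  tsel <- grepl("^t", out$parameter)
  if (any(tsel)) {
    yrs <- out[tsel, ]
    yrs$parameter <- paste0(yrs$parameter, "_years")
    yrs[, c("mean", "q05", "q95")] <-
      yrs[, c("mean", "q05", "q95")] * generation_time
    out <- rbind(out, yrs)
  }
  rownames(out) <- NULL
  attr(out, "adjusted") <- adjusted
  attr(out, "n_retained") <- length(keep)
  out
}

#' Scenario-choice error rates from pseudo-observed datasets
#'
#' Three error reports, all by re-running scenario choice with the pod's own
#' row left out of the reference: (i) posterior error rate over the
#' `n_closest` rows nearest to the observed statistics; (ii) type I error
#' for scenario `x`: fraction of scenario-x pods where x loses; (iii) type
#' II: fraction of other-scenario pods where x wins.  Computed for the
#' direct method and, when `logistic = TRUE`, the logistic method.
#'
#' @param ref reference table.
#' @param observed_stats observed statistics (posterior error rate pods).
#' @param x focal scenario id (default 3).
#' @param n_pods pods per error type (default 200; paper-scale is 1000).
#' @param n_closest pods for the posterior error rate (default 500).
#' @param tolerance,n_closest_direct passed to [abc_model_choice()].
#' @param logistic also compute the logistic-method rates (slower).
#' @param seed RNG seed.
#' @return Data frame: method, posterior_error, type1, type2.
#' @export
scenario_confidence <- function(ref, observed_stats, x = 3, n_pods = 200,
                                n_closest = 500, tolerance = 0.05,
                                n_closest_direct = 500, logistic = FALSE,
                                seed = 1) {
  if (n_pods > nrow(ref)) stop("n_pods exceeds reference-table rows")
  set.seed(seed)
  sc <- stat_cols(ref)
  scenarios <- sort(unique(ref$scenario))
  choice_for <- function(i) {
    refm <- ref[-i, , drop = FALSE]
    obs <- as.numeric(ref[i, sc])
    if (!logistic) {
      d <- abc_distances(refm, obs)
      nd <- min(n_closest_direct, nrow(refm))
      tab <- table(factor(refm$scenario[order(d)[seq_len(nd)]],
                          levels = scenarios))
      c(direct = as.numeric(names(tab)[which.max(tab)]),
        logistic = NA_real_)
    } else {
      mc <- abc_model_choice(refm, obs, tolerance = tolerance,
                             n_closest_direct = n_closest_direct)
      c(direct = as.numeric(names(which.max(mc$direct))),
        logistic = as.numeric(names(which.max(mc$logistic))))
    }
  }
  score <- function(idx) {
    wins <- t(vapply(idx, choice_for, numeric(2)))
    wins
  }
  d <- abc_distances(ref, observed_stats)
  pod_post <- order(d)[seq_len(min(n_closest, n_pods, nrow(ref)))]
  post_w <- score(pod_post)
  post_err <- colMeans(post_w != matrix(ref$scenario[pod_post],
                                        nrow(post_w), 2))
  idx_x <- which(ref$scenario == x)
  idx_o <- which(ref$scenario != x)
  pod_x <- sample(idx_x, min(n_pods, length(idx_x)))
  pod_o <- sample(idx_o, min(n_pods, length(idx_o)))
  wx <- score(pod_x)
  wo <- score(pod_o)
  type1 <- colMeans(wx != x)
  type2 <- colMeans(wo == x)
  methods <- if (logistic) c("direct", "logistic") else "direct"
  out <- data.frame(method = methods,
                    posterior_error = post_err[seq_along(methods)],
                    type1 = type1[seq_along(methods)],
                    type2 = type2[seq_along(methods)])
  rownames(out) <- NULL
  out
}
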