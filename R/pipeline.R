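# Pipeline orchestration: one config in, a directory of stage outputs plus a
# consolidated summary and a machine-readable manifest out.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage enabled and desk-
#' scale permutation/simulation settings.  Any subset can be overridden via
#' [run_pipeline()]'s `config` (R list, JSON or YAML file path).
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own seed from it.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = "oakphylo_run", seed = 1) {
  list(out_dir = out_dir, seed = seed,
       inputs = list(nuclear = NULL, cp = NULL),  # NULL => simulate
       simulate = list(enabled = TRUE, n_demes = 12, n_per_deme = 5:13,
                       target_fst = 0.07),
       qc = list(enabled = TRUE, n_perm = 199, n_boot = 50),
       diversity = list(enabled = TRUE),
       structure = list(enabled = TRUE, n_perm = 199),
       ancestry = list(enabled = TRUE, k_range = 1:4, replicates = 5,
                       lambda = 1),
       abc = list(enabled = TRUE, n_sims = 2000, tolerance = 0.05,
                  n_closest_direct = 200, generation_time = 100),
       connectivity = list(enabled = TRUE, rows = 40, cols = 40,
                           n_periods = 3, growth = 1.6, threshold = 0.5))
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  if (is.character(config) && file.exists(config)) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs")
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stop("config must be a list or an existing JSON/YAML file")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate/load -> qc ->
#' diversity -> structure -> ancestry -> abc -> connectivity), writing each
#' stage's outputs under its own subdirectory, a manifest with input hashes
#' and seeds, and a consolidated `summary.json` of headline numbers.
#'
#' @param config configuration list (merged over [default_config()]) or a
#'   JSON/YAML file path.
#' @return The summary list, invisibly; outputs on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(default_config(), read_config(config))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = cfg$seed)
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[", name, "] running")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  stage_dir <- function(name) {
    d <- file.path(cfg$out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }

  # --- data: load or simulate ---
  if (!is.null(cfg$inputs$nuclear)) {
    nuclear <- read_genotype_table(cfg$inputs$nuclear, ploidy = 2)
    cp <- if (!is.null(cfg$inputs$cp))
      read_genotype_table(cfg$inputs$cp, ploidy = 1) else NULL
  } else {
    sim <- t_stage("simulate", simulate_dataset(
      n_demes = cfg$simulate$n_demes,
      n_per_deme = cfg$simulate$n_per_deme,
      target_fst = cfg$simulate$target_fst, seed = cfg$seed))
    d <- stage_dir("simulate")
    write_genotype_table(sim$nuclear, file.path(d, "nuclear.csv"))
    write_genotype_table(sim$cp, file.path(d, "cp.csv"))
    jsonlite::write_json(sim$truth, file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    nuclear <- sim$nuclear
    cp <- sim$cp
  }
  nuclear <- filter_missing(nuclear, 1L)
  manifest$inputs <- list(n_nuclear = n_ind(nuclear),
                          n_cp = if (!is.null(cp)) n_ind(cp) else 0L)

  if (isTRUE(cfg$qc$enabled)) {
    qc <- t_stage("qc", qc_report(nuclear, n_perm = cfg$qc$n_perm,
                                  n_boot = cfg$qc$n_boot,
                                  seed = cfg$seed + 1))
    d <- stage_dir("qc")
    write.csv(qc$hwe, file.path(d, "hwe.csv"), row.names = FALSE)
    write.csv(qc$null_alleles, file.path(d, "null_alleles.csv"),
              row.names = FALSE)
    summary$fst <- qc$fst$theta
    summary$fst_ena <- qc$fst_ena$theta
    summary$fis <- qc$fis
  }

  catalog <- NULL
  if (!is.null(cp)) catalog <- extract_haplotypes(cp)

  if (isTRUE(cfg$diversity$enabled)) {
    div <- t_stage("diversity", nuclear_summary(nuclear))
    d <- stage_dir("diversity")
    write.csv(div$by_location, file.path(d, "nuclear_by_location.csv"),
              row.names = FALSE)
    write.csv(div$overall, file.path(d, "nuclear_overall.csv"),
              row.names = FALSE)
    summary$mean_uHe <- div$overall$mean[div$overall$statistic == "uHe"]
    summary$mean_AR <- div$overall$mean[div$overall$statistic == "AR"]
    if (!is.null(catalog)) {
      cps <- cp_summary(catalog)
      write.csv(cps$by_location, file.path(d, "cp_by_location.csv"),
                row.names = FALSE)
      summary$mean_h <- cps$overall$mean[cps$overall$statistic == "h"]
      summary$mean_v <- cps$overall$mean[cps$overall$statistic == "v"]
      summary$n_haplotypes <- nrow(catalog$haplotypes)
    }
  }

  if (isTRUE(cfg$structure$enabled)) {
    d <- stage_dir("structure")
    am_iam <- t_stage("structure_amova_iam",
                      amova(nuclear, "IAM", n_perm = cfg$structure$n_perm,
                            seed = cfg$seed + 2))
    am_smm <- amova(nuclear, "SMM", n_perm = cfg$structure$n_perm,
                    seed = cfg$seed + 2)
    write.csv(am_iam$table, file.path(d, "amova_nuclear_iam.csv"),
              row.names = FALSE)
    write.csv(am_smm$table, file.path(d, "amova_nuclear_smm.csv"),
              row.names = FALSE)
    summary$amova_iam_phi_st <- unname(am_iam$phi["phi_ST"])
    summary$amova_smm_phi_st <- unname(am_smm$phi["phi_ST"])
    rst <- t_stage("structure_rst",
                   rst_allele_size_test(nuclear,
                                        n_perm = cfg$structure$n_perm,
                                        seed = cfg$seed + 3))
    summary$rst <- rst$observed
    summary$p_rst <- rst$permuted_mean
    summary$rst_p_value <- rst$p
    if (!is.null(catalog)) {
      nst <- t_stage("structure_nst",
                     nst_test(catalog, n_perm = cfg$structure$n_perm,
                              seed = cfg$seed + 4))
      summary$nst <- nst$observed
      summary$p_nst <- nst$permuted_mean
      summary$gst <- nst$companion
      summary$nst_p_value <- nst$p
      msn <- minimum_spanning_network(catalog)
      write_network(msn, file.path(d, "haplotype_network.csv"))
    }
  }

  if (isTRUE(cfg$ancestry$enabled)) {
    X <- encode_genotypes(nuclear)
    coords <- cbind(nuclear$lat, nuclear$lon)
    cv <- t_stage("ancestry", select_k(
      X, coords, K_range = cfg$ancestry$k_range,
      replicates = cfg$ancestry$replicates,
      lambda = cfg$ancestry$lambda, seed = cfg$seed + 5))
    fit <- fit_ancestry(X, coords, cv$chosen_k,
                        lambda = cfg$ancestry$lambda,
                        seed = cfg$seed + 5)
    d <- stage_dir("ancestry")
    write.csv(data.frame(ind = nuclear$ind, fit$Q),
              file.path(d, "Q.csv"), row.names = FALSE)
    write.csv(data.frame(K = cv$K_range, median_rmse = cv$median),
              file.path(d, "cv_curve.csv"), row.names = FALSE)
    summary$chosen_k <- cv$chosen_k
    summary$cv_rmse <- unname(min(cv$median))
  }

  if (isTRUE(cfg$abc$enabled)) {
    d <- stage_dir("abc")
    pooled <- pooled_copies(nuclear)
    obs_stats <- summary_stats(pooled)
    ref <- t_stage("abc", generate_reference_table(
      n_sims = cfg$abc$n_sims, n_copies = nrow(pooled),
      n_loci = n_loci(nuclear), seed = cfg$seed + 6))
    write.csv(head(ref, 1000), file.path(d, "reference_head.csv"),
              row.names = FALSE)
    mc <- abc_model_choice(ref, obs_stats, tolerance = cfg$abc$tolerance,
                           n_closest_direct = cfg$abc$n_closest_direct)
    est <- abc_parameter_estimation(ref, obs_stats, scenario = mc$best,
                                    tolerance = cfg$abc$tolerance,
                                    generation_time =
                                      cfg$abc$generation_time,
                                    min_retained = 10)
    write.csv(est, file.path(d, "posterior.csv"), row.names = FALSE)
    summary$abc_best_scenario <- mc$best
    summary$abc_direct <- as.list(setNames(mc$direct,
                                           paste0("scenario",
                                                  names(mc$direct))))
    summary$abc_logistic <- as.list(setNames(mc$logistic,
                                             paste0("scenario",
                                                    names(mc$logistic))))
  }

  if (isTRUE(cfg$connectivity$enabled)) {
    d <- stage_dir("connectivity")
    land <- t_stage("connectivity", simulate_landscape(
      rows = cfg$connectivity$rows, cols = cfg$connectivity$cols,
      n_periods = cfg$connectivity$n_periods,
      growth = cfg$connectivity$growth, seed = cfg$seed + 7))
    write_ascii_grid(land$dem, file.path(d, "dem.asc"))
    ecas <- numeric(0)
    for (p in seq_along(land$suitability)) {
      st <- connectivity_stage(land$suitability[[p]], land$dem,
                               threshold = cfg$connectivity$threshold)
      write_ascii_grid(st$habitat, file.path(d, sprintf("habitat_p%d.asc",
                                                        p)))
      write.csv(st$patches$patches,
                file.path(d, sprintf("patches_p%d.csv", p)),
                row.names = FALSE)
      ecas <- c(ecas, if (!is.null(st$eca)) st$eca$eca else NA_real_)
    }
    summary$eca_by_period <- ecas
  }

  manifest$finished <- format(Sys.time())
  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest.json|summary.json", files)]
  manifest$files <- lapply(setNames(files, sub(paste0("^", cfg$out_dir,
                                                      "/?"), "", files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

# Pool the gene copies of a diploid table into one copies x loci matrix (the
# single-population ABC design).  Individuals with any missing locus are
# dropped so every locus keeps the same copy count.
pooled_copies <- function(table) {
  keep <- missing_loci_count(table) == 0
  al <- table$alleles[keep, , drop = FALSE]
  L <- n_loci(table)
  do.call(rbind, lapply(c(1, 2), function(copy)
    al[, (seq_len(L) - 1) * 2 + copy, drop = FALSE]))
}
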