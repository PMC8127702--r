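#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles everything [run_pipeline()] needs: the input (a phenotype CSV
#' path, an in-memory table, or a simulation specification), the trait list,
#' the MCMC schedule, permutation-null settings, comparison settings, the
#' output directory and the master seed. The master seed fans out to
#' per-stage sub-seeds in a fixed documented order (simulate, univariate,
#' nulls, multivariate, selection, skewers), so adding draws inside one
#' stage never perturbs another stage's stream.
#'
#' @param input Path to a phenotype CSV, a phenotype data frame, or a
#'   `sim_params` object (then `design` sizes are used to simulate).
#' @param design Named list of [make_design()] arguments used when `input`
#'   is a `sim_params`.
#' @param traits Trait columns to analyze; default: all trait columns of the
#'   input (or the simulated traits).
#' @param response_traits Traits entering breeder's-equation responses;
#'   default: all non-fitness-proxy traits (the first four defaults).
#' @param mcmc An [mcmc_config()] for the multivariate fits; the univariate
#'   fits reuse it with the univariate burn-in default.
#' @param n_null Number of permutation datasets.
#' @param null_chain_scale Chain-length scaling for null refits (default
#'   0.1: null chains run 10x shorter than observed-data chains, with a
#'   warning recorded in the manifest).
#' @param k Krzanowski retention (default half the traits).
#' @param n_skewers Skewer count.
#' @param fitness_proxies The two fitness-proxy columns (female, male).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (mandatory for any stochastic stage).
#' @param quiet Suppress progress messages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, design = list(), traits = NULL,
                            response_traits = NULL,
                            mcmc = mcmc_config(), n_null = 1000,
                            null_chain_scale = 0.1, k = NULL,
                            n_skewers = 1000,
                            fitness_proxies = c("seed_mass", "inflorescence_length"),
                            out_dir = "halfsibG_results", seed,
                            quiet = FALSE) {
  if (missing(seed)) stop("a master 'seed' is mandatory")
  stopifnot(inherits(mcmc, "mcmc_config"), n_null >= 1,
            null_chain_scale > 0, null_chain_scale <= 1)
  structure(list(input = input, design = design, traits = traits,
                 response_traits = response_traits, mcmc = mcmc,
                 n_null = as.integer(n_null),
                 null_chain_scale = null_chain_scale, k = k,
                 n_skewers = as.integer(n_skewers),
                 fitness_proxies = fitness_proxies,
                 out_dir = out_dir, seed = as.integer(seed), quiet = quiet),
            class = "pipeline_config")
}

# internal: scale an mcmc_config's chain lengths, keeping draw arithmetic valid
scale_config <- function(config, factor, seed) {
  n_post <- max(config$thin, round(config$post_burn_iterations * factor / config$thin) * config$thin)
  mcmc_config(burn_in = max(1, round(config$burn_in * factor)),
              post_burn_iterations = n_post, thin = config$thin,
              prior_scale_mode = config$prior_scale_mode,
              prior_df_offset = config$prior_df_offset, seed = seed)
}

#' Run the full half-sib analysis pipeline
#'
#' Executes the stages in order -- load/simulate phenotypes, standardize,
#' univariate heritabilities, permutation nulls, multivariate G matrices,
#' selection gradients, comparisons -- and writes per-stage artifacts plus a
#' machine-readable `summary.json` to the output directory. The summary
#' contains five result blocks: per-trait/per-population heritability with
#' HPD and null HPD; Krzanowski H eigenvalues with nulls; tensor variance
#' shares with nulls; predicted responses per population; R metric per
#' population. Re-running with the same config and seed reproduces the
#' summary byte-for-byte. A stage failure aborts with a stage-named error;
#' artifacts written so far are kept and `manifest.json` marks the run
#' incomplete.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!config$quiet) message(...)
  seeds <- derive_seeds(config$seed, 6L)
  names(seeds) <- c("simulate", "univariate", "nulls", "multivariate",
                    "selection", "skewers")
  manifest <- list(master_seed = config$seed, stage_seeds = as.list(seeds),
                   complete = FALSE, stages_done = character(0),
                   null_chain_scale = config$null_chain_scale)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    res <- tryCatch(force(expr), error = function(e) {
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages_done <<- c(manifest$stages_done, name)
    res
  }

  ## stage 1: input
  tab <- stage("input", {
    if (inherits(config$input, "sim_params")) {
      des <- do.call(make_design, config$design)
      t0 <- simulate_phenotypes(des, config$input)
      t0 <- apply_attrition(t0, config$input$attrition_rate,
                            config$input$missing_rate_per_trait,
                            seed = seeds[["simulate"]])
      write_phenotypes(t0, file.path(config$out_dir, "phenotypes.csv"))
      write_sim_params(config$input, file.path(config$out_dir, "sim_params.json"))
      t0
    } else if (is.character(config$input)) {
      read_phenotypes(config$input)
    } else {
      check_phenotype_table(config$input)
      config$input
    }
  })
  traits <- if (is.null(config$traits)) trait_columns(tab) else config$traits
  missing_tr <- setdiff(traits, names(tab))
  if (length(missing_tr) > 0L)
    stop("pipeline config references missing trait(s): ",
         paste(missing_tr, collapse = ", "))
  resp_traits <- config$response_traits
  if (is.null(resp_traits)) resp_traits <- setdiff(traits, config$fitness_proxies)
  pops <- sort(unique(tab$population))

  ## stage 2: standardization
  std <- stage("standardize", standardize_traits(tab, traits))
  sds <- trait_sd(std)

  ## stage 3: univariate heritabilities (observed)
  uni_cfg <- scale_config(config$mcmc, 1, seeds[["univariate"]])
  uni_cfg$burn_in <- min(uni_cfg$burn_in, config$mcmc$burn_in)
  h2_tab <- stage("univariate", {
    rows <- list()
    for (pop in pops) for (tr in traits) {
      fit <- fit_univariate(tab, tr, pop, uni_cfg)
      h <- hpd(fit$h2, 0.95)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, trait = tr, h2_mean = mean(fit$h2),
        hpd_low = h[[1L]], hpd_high = h[[2L]],
        V_S = mean(fit$V_S), V_D = mean(fit$V_D), V_E = mean(fit$V_E))
    }
    out <- do.call(rbind, rows)
    write.csv(out, file.path(config$out_dir, "heritability.csv"),
              row.names = FALSE)
    out
  })

  ## stage 4: permutation nulls (h2 nulls per trait/pop + null G posteriors)
  null_cfg_base <- scale_config(config$mcmc, config$null_chain_scale, 0L)
  nulls <- stage("nulls", {
    say("  null refits use chains scaled by ", config$null_chain_scale)
    sub_seeds <- derive_seeds(seeds[["nulls"]], config$n_null * 2L)
    h2_null <- array(NA_real_, c(config$n_null, length(pops), length(traits)),
                     dimnames = list(NULL, pops, traits))
    null_G <- vector("list", config$n_null)
    for (i in seq_len(config$n_null)) {
      perm <- permute_within_population(tab, sub_seeds[i])
      perm_std <- standardize_traits(perm, traits)
      fit_seed <- sub_seeds[config$n_null + i]
      gset <- list()
      for (ip in seq_along(pops)) {
        cfg_i <- null_cfg_base
        cfg_i$seed <- (fit_seed + ip) %% 2147483646L
        for (it in seq_along(traits)) {
          vc <- fit_univariate(perm, traits[it], pops[ip], cfg_i)
          h2_null[i, ip, it] <- mean(vc$h2)
        }
        gset[[pops[ip]]] <- suppressWarnings(
          fit_multivariate(perm_std, pops[ip], cfg_i, traits = traits))
      }
      null_G[[i]] <- gset
    }
    list(h2 = h2_null, G = null_G)
  })

  ## stage 5: multivariate G per population (on standardized traits)
  G_by_pop <- stage("multivariate", {
    out <- list()
    for (ip in seq_along(pops)) {
      cfg_i <- config$mcmc
      cfg_i$seed <- (seeds[["multivariate"]] + ip) %% 2147483646L
      out[[pops[ip]]] <- fit_multivariate(std, pops[ip], cfg_i, traits = traits)
      write_g_posterior(out[[pops[ip]]],
                        file.path(config$out_dir, paste0("G_", pops[ip])))
    }
    out
  })

  ## stage 6: selection gradients from global sire means
  beta <- stage("selection", {
    sm <- sire_means(tab)
    sm$composite <- composite_fitness(sm, config$fitness_proxies)
    b <- estimate_beta_point(sm, sm$composite, traits = resp_traits,
                             fitness_metric = "composite")
    write_selection_gradient(b, file.path(config$out_dir, "beta_composite"))
    b
  })

  ## stage 7: comparison suite
  comp <- stage("compare", {
    compare_populations(G_by_pop, beta, sds = sds, null_G = nulls$G,
                        k = config$k, n_skewers = config$n_skewers,
                        seed = seeds[["skewers"]])
  })

  ## summary (five result blocks)
  h2_block <- lapply(seq_len(nrow(h2_tab)), function(i) {
    r <- h2_tab[i, ]
    nl <- nulls$h2[, r$population, r$trait]
    nh <- if (length(nl) >= 2L) hpd(nl, 0.95) else c(NA_real_, NA_real_)
    list(population = r$population, trait = r$trait, h2 = r$h2_mean,
         hpd = c(r$hpd_low, r$hpd_high), null_hpd = unname(nh),
         exceeds_null = is.finite(nh[[2L]]) && r$h2_mean > nh[[2L]])
  })
  krz <- comp$krzanowski
  tens <- comp$tensor
  summary <- list(
    heritability = h2_block,
    krzanowski = list(k = krz$k, bound = krz$n_populations,
                      eigenvalues = unname(krz$eig_mean),
                      hpd_low = unname(krz$eig_hpd[1L, ]),
                      hpd_high = unname(krz$eig_hpd[2L, ]),
                      null_hpd_low = unname(krz$null_hpd[1L, ]),
                      null_hpd_high = unname(krz$null_hpd[2L, ]),
                      diverged = unname(krz$diverged)),
    tensor = list(alpha = unname(tens$alpha_mean),
                  hpd_low = unname(tens$alpha_hpd[1L, ]),
                  hpd_high = unname(tens$alpha_hpd[2L, ]),
                  null_hpd_low = unname(tens$null_alpha_hpd[1L, ]),
                  null_hpd_high = unname(tens$null_alpha_hpd[2L, ]),
                  significant = unname(tens$significant)),
    response = lapply(pops, function(p) {
      r <- comp$response[[p]]
      list(population = p, traits = resp_traits, delta_z = unname(r$mean),
           hpd_low = unname(r$hpd[1L, ]), hpd_high = unname(r$hpd[2L, ]),
           delta_z_sd_units = if (!is.null(r$mean_sd_units))
             unname(r$mean_sd_units) else NULL)
    }),
    r_metric = lapply(pops, function(p) {
      r <- comp$r_metric[[p]]
      list(population = p, R = r$mean, q05 = r$q05, q95 = r$q95)
    }),
    divergence_calls = as.list(comp$divergence_calls),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       digits = 15, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  manifest$complete <- TRUE
  write_manifest()
  say("pipeline complete: ", config$out_dir)
  invisible(summary)
}
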