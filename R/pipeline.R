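#' Pipeline configuration
#'
#' Assembles, validates and defaults the configuration of
#' [run_pipeline()]. Settings can also be loaded from a YAML file whose
#' keys mirror the arguments; explicitly passed arguments override file
#' values.
#'
#' @param out_dir output directory (created if missing).
#' @param stays optional path to an existing stay CSV; when `NULL` a
#'   synthetic registry is generated.
#' @param block_file optional block-table CSV (default: packaged WHO
#'   table when `n_blocks` = 131).
#' @param n_patients,n_blocks,n_latent_states,frac_healthy,mean_stays_per_year,diagnosis_noise
#'   synthetic-registry settings, see [registry_config()].
#' @param years registry calendar interval.
#' @param washout,observation cohort windows, see [cohort_spec()].
#' @param K number of clusters.
#' @param min_rate,min_count robustness thresholds, see
#'   [robustness_filter()].
#' @param bands,min_mean_age mortality-region settings, see
#'   [label_mortality_regions()].
#' @param risk_horizon lookahead for region-entry risks (years).
#' @param sim_n simulated cohort size for the model comparison.
#' @param seed master seed.
#' @param file optional YAML file to read settings from.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "mmtraj-output",
                            stays = NULL,
                            block_file = NULL,
                            n_patients = 20000L,
                            n_blocks = 131L,
                            n_latent_states = 6L,
                            frac_healthy = 0.25,
                            mean_stays_per_year = 0.3,
                            diagnosis_noise = 0.1,
                            years = c(1997L, 2014L),
                            washout = c(1997L, 2002L),
                            observation = c(2003L, 2014L),
                            K = 12L,
                            min_rate = 0.005,
                            min_count = 100L,
                            bands = list(low = c(0.002, 0.003),
                                         medium = c(0.003, 0.01),
                                         high = c(0.02, 0.11)),
                            min_mean_age = 55,
                            risk_horizon = 1L,
                            sim_n = 20000L,
                            seed = 1L,
                            file = NULL) {
  cfg <- as.list(environment())
  cfg$file <- NULL
  if (!is.null(file)) {
    if (!file.exists(file)) config_error("config file not found: ", file)
    fromfile <- yaml::read_yaml(file)
    passed <- names(match.call())[-1L]
    for (k in setdiff(names(fromfile), passed)) cfg[[k]] <- fromfile[[k]]
  }
  if (!is.null(cfg$stays) && !file.exists(cfg$stays))
    config_error("stays file not found: ", cfg$stays)
  if (!is.null(cfg$block_file) && !file.exists(cfg$block_file))
    config_error("block table file not found: ", cfg$block_file)
  assert_count(cfg$K, "K")
  assert_count(cfg$seed, "seed", min = 0L)
  structure(cfg, class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes registry generation (or ingestion), cohort selection,
#' health-state construction, clustering, transition-network estimation,
#' trajectory statistics, risk analysis and the model comparison, writing
#' every artifact plus a manifest (file list with MD5 checksums, parameter
#' echo, package version) into the output directory. Deterministic stages
#' reproduce identical checksums when rerun with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config_error("config must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()
  note <- list()

  blocks <- pipeline_stage("blocks", {
    if (!is.null(config$block_file)) read_block_table(config$block_file)
    else default_block_table(config$n_blocks)
  })

  stays <- pipeline_stage("gen-data", {
    if (!is.null(config$stays)) {
      s <- data.table::fread(config$stays)
      s[, admission_date := as.Date(admission_date)]
      s[, release_date := as.Date(release_date)]
      s
    } else {
      reg <- generate_registry(registry_config(
        n_patients = config$n_patients, years = config$years,
        n_blocks = config$n_blocks, n_latent_states = config$n_latent_states,
        seed = config$seed, frac_healthy = config$frac_healthy,
        mean_stays_per_year = config$mean_stays_per_year,
        diagnosis_noise = config$diagnosis_noise))
      data.table::fwrite(reg$stays, out("stays.csv"))
      jsonlite::write_json(
        list(states = reg$ground_truth$states,
             rates = reg$ground_truth$rates),
        out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
      files <- c(files, "stays.csv", "ground_truth.json")
      reg$stays
    }
  })
  data.table::fwrite(blocks, out("blocks.csv"))
  files <- c(files, "blocks.csv")

  spec <- cohort_spec(config$washout, config$observation)
  hs <- pipeline_stage("build-cohort", {
    cohort <- select_washout_cohort(stays, spec)
    build_health_states(stays, cohort, spec, blocks)
  })
  write_health_states(hs, out("health_states.csv"), format = "sparse")
  files <- c(files, "health_states.csv")
  note$cohort_size <- data.table::uniqueN(hs$index$patient_id)
  note$patient_years <- nrow(hs$index)

  model <- pipeline_stage("cluster", suppressWarnings(fit_divclus(hs, config$K)))
  profiles <- characterise_clusters(model, hs)
  data.table::fwrite(cluster_definitions(model, blocks), out("cluster_definitions.csv"))
  write_cluster_model(model, out("cluster_model.json"))
  data.table::fwrite(profiles, out("cluster_profiles.csv"))
  files <- c(files, "cluster_definitions.csv", "cluster_model.json",
             "cluster_profiles.csv")
  note$K <- model$K

  asg <- assign_states(hs, model)
  net <- pipeline_stage("network", estimate_transition_rates(asg, hs$deaths))
  data.table::fwrite(net$trans, out("transition_edges.csv"))
  coll <- collapse_layers(net)
  filtered <- robustness_filter(coll, config$min_rate, config$min_count)
  export_network(coll, graphml = out("network_collapsed.graphml"),
                 profiles = profiles)
  regions <- label_mortality_regions(profiles, config$bands, config$min_mean_age)
  data.table::fwrite(regions, out("mortality_regions.csv"))
  files <- c(files, "transition_edges.csv", "network_collapsed.graphml",
             "mortality_regions.csv")
  note$sinks <- find_sink_states(coll, filtered)
  note$acyclic <- acyclicity_check(coll)$pass

  pipeline_stage("trajectories", {
    data.table::fwrite(length_distribution(asg), out("reduced_length_distribution.csv"))
    data.table::fwrite(mean_length_by_age(asg), out("mean_length_by_age.csv"))
    write_trajectories(asg, out("trajectories.csv"), out("reduced_trajectories.csv"))
  })
  files <- c(files, "reduced_length_distribution.csv", "mean_length_by_age.csv",
             "trajectories.csv", "reduced_trajectories.csv")

  risk_tab <- pipeline_stage("risk", {
    high <- regions[region == "high", cluster]
    if (length(high) == 0L)
      high <- profiles[which.max(mortality), cluster]
    entries <- rank_entry_clusters(asg, high)
    data.table::fwrite(entries, out("region_entry_ranking.csv"))
    top <- head(setdiff(entries$cluster, 0L), 2L)
    grid <- data.table::CJ(source = top, sex = SEXES,
                           age_group = c("50-59", "60-69", "70-79"))
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      r <- region_entry_risk(asg, grid$source[i], high, grid$sex[i],
                             grid$age_group[i], horizon = config$risk_horizon)
      data.table::data.table(
        cluster = r$source, sex = grid$sex[i], age_group = grid$age_group[i],
        absolute_risk = r$absolute_risk, rr = r$rr,
        ci_lo = r$ci[1L], ci_hi = r$ci[2L])
    })
    data.table::rbindlist(rows)
  })
  data.table::fwrite(risk_tab, out("region_entry_risks.csv"))
  bias <- gender_biased_transitions(net)
  data.table::fwrite(bias, out("gender_bias.csv"))
  files <- c(files, "region_entry_ranking.csv", "region_entry_risks.csv",
             "gender_bias.csv")

  cmp <- pipeline_stage("compare", {
    models <- list(
      divclus = list(assignments = asg, net = net),
      most_recent = local({
        ba <- benchmark_assign(hs, stays, "most_recent")
        list(assignments = ba, net = estimate_transition_rates(ba, hs$deaths))
      }),
      least_frequent = local({
        ba <- benchmark_assign(hs, stays, "least_frequent")
        list(assignments = ba, net = estimate_transition_rates(ba, hs$deaths))
      }))
    compare_models(models, n_sim = config$sim_n, years = config$observation,
                   seed = config$seed, states = hs)
  })
  data.table::fwrite(cmp, out("model_comparison.csv"))
  files <- c(files, "model_comparison.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("mmtraj")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "bands")],
    bands = config$bands,
    notes = note,
    files = lapply(setNames(nm = sort(unique(files))), function(f)
      list(md5 = unname(tools::md5sum(out(f)))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
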