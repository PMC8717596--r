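# Pipeline orchestration: generate (or load) -> build cohort -> flag HACs
# -> comorbidity/complexity -> DEA benchmark -> peer network -> outcome
# models, with every stage output written to disk and a manifest recording
# seed, versions and content hashes.

#' Assemble a pipeline configuration
#'
#' Exactly one of `generator` (settings for the synthetic cohort) and
#' `inputs` (paths to episodes/diagnoses/hospitals/patients CSVs) must be
#' supplied.
#'
#' @param generator named list of overrides passed to
#'   [generator_config()], or `NULL`.
#' @param inputs named list of CSV paths (`episodes`, `diagnoses`,
#'   `hospitals`, `patients`), or `NULL`.
#' @param hac_mapping,charlson_map,charlson_hierarchy mapping file paths
#'   (defaults: shipped reference maps).
#' @param dea list: `rts` ("vrs"/"crs"), `bootstrap_B`, `alpha`,
#'   `epsilon_output`, `weights` ("episodes" or "uniform").
#' @param seed integer; propagated to every stochastic stage.
#' @param pseudonymise,salt pseudonymise exported hospital ids.
#' @return list of class `hacbench_pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), inputs = NULL,
                            hac_mapping = hacbench_extdata("hac_mapping.csv"),
                            charlson_map = hacbench_extdata("charlson_map.csv"),
                            charlson_hierarchy =
                              hacbench_extdata("charlson_hierarchy.csv"),
                            dea = list(), seed = 42L,
                            pseudonymise = FALSE, salt = "hacbench") {
  if (!is.null(generator) && !is.null(inputs))
    stop("supply either generator settings or input files, not both")
  if (is.null(generator) && is.null(inputs))
    stop("supply generator settings or input files")
  dea_defaults <- list(rts = "vrs", bootstrap_B = 1000L, alpha = 0.05,
                       epsilon_output = 0.1, weights = "episodes")
  dea <- utils::modifyList(dea_defaults, dea)
  structure(list(generator = generator, inputs = inputs,
                 hac_mapping = hac_mapping, charlson_map = charlson_map,
                 charlson_hierarchy = charlson_hierarchy, dea = dea,
                 seed = as.integer(seed), pseudonymise = pseudonymise,
                 salt = salt),
            class = "hacbench_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `hacbench_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_stage_csv <- function(df, dir, name) {
  f <- file.path(dir, name)
  utils::write.csv(df, f, row.names = FALSE)
  f
}

#' Run the full benchmarking pipeline
#'
#' Executes every stage and writes all outputs under `output_dir`:
#' `hospitals.csv`, `patients.csv`, `episodes.csv`, `diagnoses.csv`,
#' `truth.json` (generator runs only), `cohort.csv`,
#' `cohort_summary.json`, `hospital_aggregates.csv`, `dea_results.csv`,
#' `frontier_comparison.csv`, `group_means.csv`, `peer_edges.csv`,
#' `peer_graph.graphml`, `table1_rates.csv`, `table2_odds.csv`,
#' `table3_glm.csv` and a `manifest.json` with content hashes, versions
#' and the seed. Rerunning with the same config and seed reproduces
#' bit-identical stochastic outputs; rerunning onto existing outputs
#' without `force` is refused.
#'
#' @param config a `hacbench_pipeline_config` or path to a YAML file.
#' @param output_dir directory for stage outputs (created).
#' @param force overwrite an existing results bundle.
#' @return invisibly, a results bundle: all in-memory tables plus the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "hacbench_pipeline_config"))

  # pre-flight validation before any work
  for (f in c(config$hac_mapping, config$charlson_map,
              config$charlson_hierarchy))
    if (!file.exists(f)) stop("pre-flight: mapping file not found: ", f)
  if (!is.null(config$inputs))
    for (f in unlist(config$inputs))
      if (!file.exists(f)) stop("pre-flight: input file not found: ", f)
  manifest_path <- file.path(output_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("output directory already holds a results bundle; ",
         "use force = TRUE to overwrite")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  hac_map <- load_hac_mapping(config$hac_mapping)
  charlson <- load_charlson_map(config$charlson_map,
                                config$charlson_hierarchy)
  files <- character(0)

  if (!is.null(config$generator)) {
    gen_cfg <- do.call(generator_config,
                       utils::modifyList(list(seed = config$seed),
                                         config$generator))
    cohort <- generate_cohort(gen_cfg, hac_map, charlson)
    hospitals <- cohort$hospitals
    patients <- cohort$patients
    episodes <- cohort$episodes
    diagnoses <- cohort$diagnoses
    files["truth"] <- file.path(output_dir, "truth.json")
    export_truth(gen_cfg, hospitals, files["truth"])
  } else {
    hospitals <- utils::read.csv(config$inputs$hospitals,
                                 stringsAsFactors = FALSE)
    patients <- utils::read.csv(config$inputs$patients,
                                stringsAsFactors = FALSE)
    episodes <- utils::read.csv(config$inputs$episodes,
                                stringsAsFactors = FALSE)
    episodes$admit_date <- as.Date(episodes$admit_date)
    episodes$separation_date <- as.Date(episodes$separation_date)
    diagnoses <- utils::read.csv(config$inputs$diagnoses,
                                 stringsAsFactors = FALSE)
  }
  files["hospitals"] <- write_stage_csv(hospitals, output_dir,
                                        "hospitals.csv")
  files["patients"] <- write_stage_csv(patients, output_dir, "patients.csv")
  files["episodes"] <- write_stage_csv(episodes, output_dir, "episodes.csv")
  files["diagnoses"] <- write_stage_csv(diagnoses, output_dir,
                                        "diagnoses.csv")

  # cohort stage
  excl <- apply_exclusions(episodes, hospitals)
  cohort_eps <- derive_readmission(excl$episodes)

  # classification + comorbidity stage
  flagged <- flag_cohort(cohort_eps,
                         diagnoses[diagnoses$episode_id %in%
                                     cohort_eps$episode_id, , drop = FALSE],
                         hac_map)
  cohort_eps <- score_comorbidities(flagged$episodes, diagnoses, charlson)
  files["cohort"] <- write_stage_csv(cohort_eps, output_dir, "cohort.csv")
  summary <- summarize_cohort(cohort_eps, excl$summary)
  files["summary"] <- file.path(output_dir, "cohort_summary.json")
  jsonlite::write_json(summary, files["summary"], auto_unbox = TRUE,
                       digits = NA)

  # aggregation + DEA stage
  aggregates <- build_hospital_aggregates(
    cohort_eps, hospitals[hospitals$sector == "public", , drop = FALSE])
  files["aggregates"] <- write_stage_csv(aggregates, output_dir,
                                         "hospital_aggregates.csv")
  dea <- score_frontiers(aggregates, rts = config$dea$rts,
                         epsilon_output = config$dea$epsilon_output)
  files["dea"] <- write_stage_csv(dea$scores, output_dir, "dea_results.csv")
  files["comparison"] <- write_stage_csv(dea$comparison, output_dir,
                                         "frontier_comparison.csv")
  w <- if (identical(config$dea$weights, "episodes"))
    stats::setNames(aggregates$n_episodes, aggregates$hospital_id)
  else stats::setNames(rep(1, nrow(aggregates)), aggregates$hospital_id)
  gm <- rbind(
    cbind(frontier = "group",
          group_mean_scores(dea$scores, w, "group",
                            B = config$dea$bootstrap_B,
                            alpha = config$dea$alpha, seed = config$seed)),
    cbind(frontier = "meta",
          group_mean_scores(dea$scores, w, "meta",
                            B = config$dea$bootstrap_B,
                            alpha = config$dea$alpha, seed = config$seed)))
  files["group_means"] <- write_stage_csv(gm, output_dir, "group_means.csv")

  # peer network stage (regional frontier by default)
  graph <- build_peer_graph(dea$scores, dea$peers, frontier = "group")
  gfiles <- export_graph(graph, file.path(output_dir, "peer_graph"),
                         format = c("csv", "graphml"),
                         pseudonymise = config$pseudonymise,
                         salt = config$salt)
  files["peer_edges"] <- unname(gfiles["csv"])
  files["peer_graphml"] <- unname(gfiles["graphml"])

  # outcome model stage
  mf <- model_frame(cohort_eps)
  rt <- rate_table(cohort_eps)
  files["table1"] <- write_stage_csv(rt$rates, output_dir,
                                     "table1_rates.csv")
  fits <- list(
    hac = fit_logistic(mf, "hac",
                       setdiff(DEFAULT_MODEL_TERMS, character(0))),
    death = fit_logistic(mf, "died_in_hospital",
                         c("hac", DEFAULT_MODEL_TERMS)),
    readmit = fit_logistic(mf, "readmit30", c("hac", DEFAULT_MODEL_TERMS)),
    cost = fit_glm_log(mf, "cost", c("hac", DEFAULT_MODEL_TERMS)),
    los = fit_glm_log(mf, "los", c("hac", DEFAULT_MODEL_TERMS)))
  odds <- do.call(rbind, lapply(c("hac", "death", "readmit"), function(m)
    cbind(model = m, fits[[m]]$coefficients)))
  glms <- do.call(rbind, lapply(c("cost", "los"), function(m)
    cbind(model = m, fits[[m]]$coefficients)))
  files["table2"] <- write_stage_csv(odds, output_dir, "table2_odds.csv")
  files["table3"] <- write_stage_csv(glms, output_dir, "table3_glm.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("hacbench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    rts = config$dea$rts,
    pseudonymised = config$pseudonymise,
    files = lapply(files[file.exists(files)], function(f)
      list(path = basename(f),
           sha256 = digest::digest(file = f, algo = "sha256"))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(hospitals = hospitals, patients = patients,
                 episodes = episodes, cohort = cohort_eps,
                 summary = summary, group_freq = flagged$group_freq,
                 aggregates = aggregates, dea = dea, group_means = gm,
                 graph = graph, rate_table = rt, fits = fits,
                 manifest = manifest, files = files))
}

#' Per-hospital benchmarking brief report
#'
#' The four report items a benchmarking exercise owes each hospital:
#' 1) its technical efficiency against the regional and state frontiers,
#' 2) the projected input/output targets if it were fully efficient,
#' 3) its best-practice peers, and 4) their relative weights; plus the
#' methodological caveats (returns-to-scale assumption and complexity
#' index construction).
#'
#' @param hospital_id hospital to report on (original id even when the
#'   report itself is pseudonymised).
#' @param results bundle from [run_pipeline()] (needs `dea`,
#'   `aggregates`, `manifest`).
#' @param pseudonymise report under a salted pseudonym.
#' @param salt pseudonym salt.
#' @return list of class `hospital_report`; print method renders text,
#'   `jsonlite::toJSON` renders JSON.
#' @export
hospital_report <- function(hospital_id, results, pseudonymise = FALSE,
                            salt = "hacbench") {
  sc <- results$dea$scores
  row_g <- sc[sc$dmu_id == hospital_id & sc$frontier == "group", ,
              drop = FALSE]
  row_m <- sc[sc$dmu_id == hospital_id & sc$frontier == "meta", ,
              drop = FALSE]
  if (nrow(row_g) == 0) stop("unknown hospital: ", hospital_id)
  pe <- results$dea$peers
  pe <- pe[pe$dmu_id == hospital_id & pe$frontier == "group" &
             pe$peer_id != hospital_id, , drop = FALSE]
  id_out <- if (pseudonymise) pseudonymise_ids(hospital_id, salt)
            else hospital_id
  peer_ids <- if (pseudonymise) pseudonymise_ids(pe$peer_id, salt)
              else pe$peer_id
  structure(list(
    hospital_id = id_out,
    region = row_g$region,
    te_group_pct = row_g$te_pct,
    te_meta_pct = row_m$te_pct,
    is_efficient = row_g$is_efficient,
    targets = list(beds = row_g$target_beds,
                   simplicity = row_g$target_simplicity,
                   safety_rate = row_g$target_safety),
    peers = if (nrow(pe) > 0)
      data.frame(peer_id = peer_ids, weight = pe$lambda,
                 stringsAsFactors = FALSE)
    else NULL,
    caveats = c(
      paste0("returns to scale: ", row_g$rts),
      "complexity index: equal-weight capped mean-Charlson / ICU-rate average (stand-in construction)")),
    class = "hospital_report")
}

#' @export
print.hospital_report <- function(x, ...) {
  cat("Hospital safety benchmarking report —", x$hospital_id, "\n")
  cat(sprintf("  Region: %s\n", x$region))
  cat(sprintf("  1) Technical efficiency: %.1f%% (regional frontier), %.1f%% (state frontier)\n",
              x$te_group_pct, x$te_meta_pct))
  cat(sprintf("  2) Targets at full efficiency: safety rate %.2f%%, beds %.1f, simplicity %.3f\n",
              x$targets$safety_rate, x$targets$beds, x$targets$simplicity))
  if (x$is_efficient || is.null(x$peers)) {
    cat("  3) Peers: none — this hospital is on the best-practice frontier\n")
    cat("  4) Peer weights: not applicable\n")
  } else {
    cat("  3) Best-practice peers:", paste(x$peers$peer_id, collapse = ", "),
        "\n")
    cat("  4) Peer weights:",
        paste(sprintf("%s=%.3f", x$peers$peer_id, x$peers$weight),
              collapse = ", "), "\n")
  }
  cat("  Caveats:", paste(x$caveats, collapse = "; "), "\n")
  invisible(x)
}
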