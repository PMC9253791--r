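#' Build a scenario configuration
#'
#' Three scenarios ship with the package, mirroring the study design:
#' `"membranes"` (lipid counts near the protein for DAG-free, 1% and 5%
#' total-DAG membranes), `"fingerprint"` (per-residue species fingerprints
#' at L1/L2 plus paired wild-type vs G652A L2 occupancy; alias
#' `"wt_vs_g652a"`), and `"lipid_clamp"` (double-pulse and threshold
#' photocycling protocols with activation fits and Tau-ON sensitization).
#' Desk-scale defaults use reduced membranes; pass `membrane`/`schedule`
#' blocks to change problem size.
#'
#' @param scenario scenario name.
#' @param seed global seed.
#' @param membrane,schedule,binding,analysis,kinetics optional override
#'   blocks (named lists).
#' @return validated `lg_config` list.
#' @export
scenario_config <- function(scenario = c("membranes", "fingerprint",
                                         "wt_vs_g652a", "lipid_clamp"),
                            seed = 1, membrane = list(), schedule = list(),
                            binding = list(), analysis = list(),
                            kinetics = list()) {
  scenario <- match.arg(scenario)
  if (scenario == "wt_vs_g652a") scenario <- "fingerprint"
  config <- list(
    scenario = scenario, seed = as.integer(seed),
    membrane = modifyList(list(box = c(14, 14, 12), lipids_per_leaflet = 150,
                               dag_inner_pct = 2), membrane),
    schedule = modifyList(list(restrained_us = 5, total_us = 15,
                               frame_interval_ns = 0.1, compression = 1000,
                               n_repeats = 3), schedule),
    binding = modifyList(list(g652a_factor = 0.3), binding),
    analysis = modifyList(list(cutoff = 0.6, window_ns = 200), analysis),
    kinetics = modifyList(list(n_cells = 6, noise_sd = 1), kinetics))
  validate_config(config)
}

validate_config <- function(config) {
  need <- c("scenario", "seed", "membrane", "schedule", "binding",
            "analysis", "kinetics")
  missing_blocks <- setdiff(need, names(config))
  if (length(missing_blocks))
    stop_lg("config missing block(s): %s", paste(missing_blocks, collapse = ", "),
            class = "lipidgate_config_error")
  if (!config$scenario %in% c("membranes", "fingerprint", "lipid_clamp"))
    stop_lg("unknown scenario '%s'", config$scenario,
            class = "lipidgate_config_error")
  with(config$schedule, {
    if (restrained_us >= total_us)
      stop_lg("restrained phase must end before the total duration",
              class = "lipidgate_config_error")
  })
  if (config$analysis$cutoff <= 0 || config$analysis$window_ns <= 0)
    stop_lg("analysis cutoff and window must be > 0",
            class = "lipidgate_config_error")
  structure(config, class = "lg_config")
}

#' Read a scenario configuration from YAML
#' @param path YAML file with the blocks of [scenario_config()].
#' @return validated `lg_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scenario_config, raw)
}

pipeline_protein <- function(config) {
  box <- config$membrane$box
  protein_model(center = box[1:2] / 2, z_mid = box[3] / 2)
}

pipeline_schedule <- function(config)
  do.call(simulation_schedule, config$schedule)

pipeline_sim <- function(config, dag_inner_pct, g652a = FALSE, seed_offset = 0L) {
  comp <- membrane_composition(dag_inner_pct)
  spec <- membrane_spec(box = config$membrane$box,
                        lipids_per_leaflet = config$membrane$lipids_per_leaflet,
                        inner = comp$inner, outer = comp$outer)
  bm <- binding_model(g652a_factor = if (g652a) config$binding$g652a_factor else 1)
  simulate_membrane_scenario(spec = spec, protein = pipeline_protein(config),
                             binding = bm, schedule = pipeline_schedule(config),
                             seed = config$seed + seed_offset)
}

#' Run a shipped scenario end to end
#'
#' Simulates, analyses and reports into a deterministic directory layout:
#' `trajectories/`, `contacts/`, `density/`, `kinetics/`, `report.json`,
#' plus a manifest (config hash, seed, package version) and a log with
#' per-stage timings. Any stage failure aborts with the stage name; outputs
#' written so far are retained next to a `FAILED_<stage>` marker.
#'
#' @param config `lg_config` from [scenario_config()] /
#'   [read_scenario_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return `out_dir`, invisibly; `report.json` holds the scenario summary.
#' @export
run_scenario <- function(config, out_dir = tempfile("lipidgate_run_")) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("trajectories", "contacts", "density", "kinetics"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  report <- list(scenario = config$scenario, seed = config$seed)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, paste0("FAILED_", name)))
      stop_lg("stage '%s' failed: %s", name, conditionMessage(e),
              class = "lipidgate_stage_error")
    })
    log_line("stage %-12s %.2f s", name, proc.time()[3] - t0)
    res
  }

  if (config$scenario == "membranes") {
    series <- stage("simulate", {
      out <- list()
      for (pct in c(0, 2, 10)) {
        trajs <- pipeline_sim(config, pct, seed_offset = pct)
        write_trajectory(trajs[[1]], file.path(
          out_dir, "trajectories", sprintf("dag%02d_rep1.lgt", pct)))
        out[[sprintf("dag_total_%g_pct", pct / 2)]] <-
          contact_timeseries(trajs, metric_near_protein(config$analysis$cutoff),
                             window_ns = config$analysis$window_ns)
      }
      out
    })
    stage("contacts", {
      for (nm in names(series))
        write.csv(as.data.frame(series[[nm]]),
                  file.path(out_dir, "contacts", paste0(nm, ".csv")),
                  row.names = FALSE)
    })
    report$equilibration_onset_ns <- lapply(series, function(s)
      detect_equilibration(s$mean[, "PC"], s$time_ns))
    report$final_mean_counts <- lapply(series, function(s)
      as.list(round(s$mean[nrow(s$mean), ], 3)))
  }

  if (config$scenario == "fingerprint") {
    trajs_wt <- stage("simulate_wt", pipeline_sim(config, config$membrane$dag_inner_pct))
    trajs_mut <- stage("simulate_g652a",
                       pipeline_sim(config, config$membrane$dag_inner_pct,
                                    g652a = TRUE))
    fp <- stage("fingerprint", {
      fps <- lapply(c(L1 = "L1", L2 = "L2"), function(s)
        contact_fingerprint(trajs_wt, site_definition(s),
                            cutoff = config$analysis$cutoff))
      for (s in names(fps))
        write.csv(fps[[s]], file.path(out_dir, "contacts",
                                      paste0("fingerprint_", s, ".csv")),
                  row.names = FALSE)
      fps
    })
    occ <- stage("occupancy", {
      o <- lapply(list(WT = trajs_wt, G652A = trajs_mut), dag_occupancy,
                  cutoff = config$analysis$cutoff,
                  window_ns = config$analysis$window_ns)
      cmp <- data.frame(
        genotype = names(o),
        steady_occupancy = vapply(o, function(x)
          mean(x$mean[x$time_ns >= max(x$time_ns) / 2, "DAG"]), 1.0))
      write.csv(cmp, file.path(out_dir, "contacts", "occupancy_wt_vs_g652a.csv"),
                row.names = FALSE)
      cmp
    })
    stage("density", {
      g <- accumulate_density(trajs_wt, "DAG", edge = 0.2)
      write_dx(g, file.path(out_dir, "density", "dag_density.dx"))
    })
    dag_share <- function(f) {
      m <- attr(f, "matrix")
      100 * sum(m[, "DAG"]) / max(sum(m), 1)
    }
    report$dag_contact_share_pct <- lapply(fp, dag_share)
    report$occupancy <- setNames(as.list(occ$steady_occupancy), occ$genotype)
  }

  if (config$scenario == "lipid_clamp") {
    fits <- stage("kinetics", {
      proto <- photocycle_protocol(n_cycles = 2, uv_s = 10, blue_s = 10,
                                   pre_blue_s = 20)
      model <- trace_model(noise_sd = config$kinetics$noise_sd)
      res <- lapply(seq_len(config$kinetics$n_cells), function(cell) {
        tr <- simulate_current_trace(model, proto, seed = config$seed + cell)
        write_trace_csv(tr, file.path(out_dir, "kinetics",
                                      sprintf("cell%02d.csv", cell)))
        fit_photocycles(tr)
      })
      write_epochs_csv(proto, file.path(out_dir, "kinetics", "protocol.csv"))
      res
    })
    folds <- vapply(fits, function(f) f$sensitization$fold_change, 1.0)
    taus <- t(vapply(fits, function(f)
      c(first = unname(f$fits[[1]]$par["tau"]),
        second = unname(f$fits[[2]]$par["tau"])), c(first = 1.0, second = 1.0)))
    write.csv(data.frame(cell = seq_along(folds), tau_first = taus[, 1],
                         tau_second = taus[, 2], fold = folds),
              file.path(out_dir, "kinetics", "sensitization.csv"),
              row.names = FALSE)
    report$tau_on_fold_change <- list(mean = mean(folds), sd = sd(folds),
                                      n = length(folds))
  }

  manifest <- list(
    package = "lipidgate",
    version = as.character(utils::packageVersion("lipidgate")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
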