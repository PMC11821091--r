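## Orchestration and reporting: a single-system analysis pipeline driven
## by a YAML configuration, writing one TSV per stage plus a MANIFEST and
## a run log, and file-emitting front ends for the synthetic generators.

#' Run the full analysis pipeline on one system
#'
#' Executes shape -> conformation -> RDFs -> hydrogen bonds -> transport
#' on a trajectory, writing one TSV per stage into the output directory,
#' a `MANIFEST` marking which stages completed, and a `run.log` echoing
#' the configuration and every criterion value used.  Any stage error
#' leaves the earlier outputs in place, marks the stage `FAILED` in the
#' MANIFEST and re-raises the error.
#'
#' @param config a configuration list or the path to a YAML file with
#'   keys: `trajectory` (GRO path), `species_map` (YAML path),
#'   `output_dir`, `seed`, and optional per-stage blocks `shape`
#'   (`selection`), `conformation` (`triplet`), `rdf` (`bin_width`,
#'   `r_max`, `site_pairs`, `com_targets`), `hbonds` (`r_da_max`,
#'   `angle_max`), `msd` (`mode`, `max_lag_fraction`, `origin_stride`).
#'   Selections are lists of [select_atoms()] filters.
#' @return invisibly, a named list of the per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("trajectory", "species_map", "output_dir"))
    if (is.null(config[[key]]))
      stop("pipeline configuration lacks required key '", key, "'")
  if (!file.exists(config$species_map))
    stop("species map file not found: ", config$species_map)
  if (!file.exists(config$trajectory))
    stop("trajectory file not found: ", config$trajectory)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  label <- config$label %||% "system"

  traj <- read_gro(config$trajectory)
  traj <- assign_species(traj, read_species_map(config$species_map),
                         permissive = isTRUE(config$permissive))

  status <- c(shape = "PENDING", conformation = "PENDING", rdf = "PENDING",
              hbonds = "PENDING", transport = "PENDING")
  results <- list()
  log_lines <- c(
    paste0("micellr ", as.character(utils::packageVersion("micellr"))),
    paste0("seed: ", seed),
    paste0("config: ", gsub("\n", " | ", yaml::as.yaml(config))))
  log_add <- function(line) log_lines <<- c(log_lines, line)
  finish <- function() {
    writeLines(c("# stage\tstatus",
                 paste(names(status), status, sep = "\t")),
               file.path(config$output_dir, "MANIFEST"))
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  run_stage <- function(name, code) {
    r <- tryCatch(code, error = function(e) {
      status[name] <<- "FAILED"
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    status[name] <<- "OK"
    r
  }

  mic_sel <- do.call(select_atoms,
                     c(list(traj), config$shape$selection %||%
                         list(species = "Surf")))

  results$shape <- run_stage("shape", {
    sr <- shape_series(traj, mic_sel, burn_in = config$shape$burn_in %||% 0L)
    write_shape_report(stats::setNames(list(sr), label),
                       file.path(config$output_dir, "shape.tsv"))
    utils::write.table(
      data.frame(time_ps = sr$per_frame$time, rg_nm = round(sr$per_frame$rg, 6)),
      file.path(config$output_dir, "rg_series.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sr
  })

  results$conformation <- run_stage("conformation", {
    trip <- unlist(config$conformation$triplet %||% c("S1", "C6", "C12"))
    cr <- head_tail_metrics(traj, trip, sel = mic_sel)
    write_conformation_report(stats::setNames(list(cr), label),
                              file.path(config$output_dir, "conformation.tsv"))
    cr
  })

  results$rdf <- run_stage("rdf", {
    bw <- config$rdf$bin_width %||% 0.002
    rmax <- config$rdf$r_max
    curves <- list()
    for (pr in config$rdf$site_pairs %||% list()) {
      a <- do.call(select_atoms, c(list(traj), pr$a))
      b <- do.call(select_atoms, c(list(traj), pr$b))
      curves[[pr$name]] <- rdf_site_site(traj, a, b, bin_width = bw,
                                         r_max = rmax)
    }
    for (tg in config$rdf$com_targets %||%
           list(list(name = "head", site_role = "head"),
                list(name = "tail", site_role = "tail"))) {
      nm <- tg$name; tg$name <- NULL
      t_sel <- do.call(select_atoms, c(list(traj), tg))
      curves[[paste0("com-", nm)]] <-
        rdf_from_com(traj, mic_sel, t_sel, bin_width = bw, r_max = rmax)
    }
    log_add(sprintf("rdf: bin_width %g nm, r_max %s", bw,
                    if (is.null(rmax)) "half-box" else rmax))
    write_rdf(curves, file.path(config$output_dir, "rdf.tsv"))
    curves
  })

  results$hbonds <- run_stage("hbonds", {
    crit <- hbond_criterion(config$hbonds$r_da_max %||% 0.35,
                            config$hbonds$angle_max %||% 30)
    log_add(sprintf("hbonds: r_DA <= %g nm, angle <= %g deg",
                    crit$r_da_max, crit$angle_max))
    tb <- suppressWarnings(hbond_table(traj, crit))
    write_hbond_report(stats::setNames(list(tb), label),
                       file.path(config$output_dir, "hbonds.tsv"))
    tb
  })

  results$transport <- run_stage("transport", {
    mode <- config$msd$mode %||% "com"
    mr <- msd(traj, mic_sel, mode = mode,
              max_lag_fraction = config$msd$max_lag_fraction %||% 0.5,
              origin_stride = config$msd$origin_stride %||% 1L)
    log_add(sprintf("msd: mode %s, beta tolerance 0.1", mode))
    write_transport_report(stats::setNames(list(list(msd_result = mr)), label),
                           file.path(config$output_dir, "transport.tsv"))
    mr
  })

  finish()
  invisible(results)
}

#' Emit a synthetic micelle as GRO plus ground-truth sidecar
#'
#' @param dir output directory.
#' @param ... arguments to [build_micelle()].
#' @return invisibly, the paths written (`micelle.gro`, `truth.yaml`).
#' @export
simulate_micelle_files <- function(dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- build_micelle(...)
  gro <- file.path(dir, "micelle.gro")
  write_gro(traj, gro)
  truth <- file.path(dir, "truth.yaml")
  yaml::write_yaml(attr(traj, "micelle_spec"), truth)
  invisible(c(gro, truth))
}

#' Emit a Brownian trajectory as GRO plus ground-truth sidecar
#'
#' @param dir output directory.
#' @param ... arguments to [brownian_trajectory()].
#' @return invisibly, the paths written.
#' @export
simulate_brownian_files <- function(dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- brownian_trajectory(...)
  gro <- file.path(dir, "brownian.gro")
  write_gro(traj, gro)
  truth <- file.path(dir, "truth.yaml")
  yaml::write_yaml(list(d_true = attr(traj, "d_true")), truth)
  invisible(c(gro, truth))
}

#' Emit a harmonic FEP ladder as per-window files plus ground truth
#'
#' @param dir output directory.
#' @param ... arguments to [harmonic_fep_samples()].
#' @return invisibly, the paths written.
#' @export
simulate_fep_files <- function(dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ladder <- harmonic_fep_samples(...)
  paths <- write_fep_windows(ladder, dir)
  truth <- file.path(dir, "truth.yaml")
  yaml::write_yaml(ladder$truth, truth)
  invisible(c(paths, truth))
}
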