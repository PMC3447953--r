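# Declarative experiment configs, the end-to-end runner, and test fixtures.

#' Declarative experiment configuration
#'
#' Bundles the network, cell-population, light and simulation settings plus
#' the list of requested analyses into one serializable object that
#' round-trips losslessly through YAML ([read_experiment_config()] /
#' [write_experiment_config()]). Every run archives its effective
#' configuration beside the outputs as a JSON provenance record.
#'
#' @param network a [network_config()].
#' @param cells list: `model` (`"poincare"` or `"goodwin"`) plus sampler
#'   overrides passed to the population sampler.
#' @param light a [light_schedule()] or `NULL` for constant darkness.
#' @param sim a [sim_config()].
#' @param analyses character vector out of `"mean_field"`, `"shape"`,
#'   `"correlation"`, `"phases"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(network = network_config(),
                              cells = list(model = "poincare"),
                              light = light_schedule(),
                              sim = sim_config(),
                              analyses = c("mean_field", "shape",
                                           "correlation", "phases")) {
  stopifnot(inherits(network, "network_config"),
            is.null(light) || inherits(light, "light_schedule"),
            inherits(sim, "sim_config"))
  model <- cells$model %||% "poincare"
  if (!model %in% c("poincare", "goodwin"))
    stop_scn("cells$model must be 'poincare' or 'goodwin'")
  bad <- setdiff(analyses, c("mean_field", "shape", "correlation", "phases"))
  if (length(bad)) stop_scn("unknown analyses: %s", paste(bad, collapse = ", "))
  structure(list(network = network, cells = cells, light = light, sim = sim,
                 analyses = analyses),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @param config an [experiment_config()].
#' @return `read_experiment_config()` returns an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_config(
    network = do.call(network_config, y$network %||% list()),
    cells = y$cells %||% list(model = "poincare"),
    light = if (!is.null(y$light)) do.call(light_schedule, y$light),
    sim = do.call(sim_config, y$sim %||% list()),
    analyses = y$analyses %||% c("mean_field", "shape", "correlation",
                                 "phases"))
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  y <- list(network = unclass(config$network),
            cells = config$cells,
            light = if (!is.null(config$light)) unclass(config$light),
            sim = unclass(config$sim),
            analyses = config$analyses)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

# Sample the cell population matching an experiment config and network.
sample_population <- function(config) {
  net_cfg <- config$network
  model <- config$cells$model %||% "poincare"
  extra <- config$cells[setdiff(names(config$cells), "model")]
  seed <- scn_subseed(net_cfg$seed, "population")
  if (model == "poincare") {
    do.call(sample_poincare_population,
            c(list(n = net_cfg$N, f_nonrhythmic = net_cfg$f_vl, seed = seed),
              extra))
  } else {
    do.call(sample_goodwin_population,
            c(list(n = net_cfg$N, f_vl = net_cfg$f_vl, seed = seed), extra))
  }
}

#' Run a full build-simulate-analyze experiment
#'
#' Builds the network, samples the cell population, integrates the coupled
#' system under the configured light schedule, runs the requested analyses,
#' and writes all artifacts (CSV tables plus a JSON provenance record with
#' the effective configuration and seeds) into `outdir`.
#'
#' @param config an [experiment_config()] or a path to its YAML file.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   `trajectory`.
#' @export
run_experiment <- function(config, outdir) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  net <- build_network(config$network)
  pop <- sample_population(config)
  traj <- simulate_network(net, pop, config$light, config$sim)
  files <- list()
  write_network_csv(net, file.path(outdir, "network"))
  files$network <- file.path(outdir, paste0("network",
                                            c("_nodes.csv", "_edges.csv")))
  utils::write.csv(pop, file.path(outdir, "population.csv"),
                   row.names = FALSE)
  files$population <- file.path(outdir, "population.csv")
  mf <- mean_field(traj)
  if ("mean_field" %in% config$analyses) {
    utils::write.csv(data.frame(time = mf$times, value = mf$value),
                     file.path(outdir, "mean_field.csv"), row.names = FALSE)
    files$mean_field <- file.path(outdir, "mean_field.csv")
  }
  if ("shape" %in% config$analyses) {
    sh <- activity_width_height(mf)
    utils::write.csv(data.frame(w = sh$w, h = sh$h, w_sd = sh$w_sd,
                                h_sd = sh$h_sd),
                     file.path(outdir, "activity_shape.csv"),
                     row.names = FALSE)
    files$shape <- file.path(outdir, "activity_shape.csv")
  }
  if ("correlation" %in% config$analyses) {
    cm <- correlation_matrix(traj)
    m <- cm$matrix
    dimnames(m) <- list(net$cells$id, net$cells$id)
    utils::write.csv(m, file.path(outdir, "correlation_matrix.csv"))
    files$correlation <- file.path(outdir, "correlation_matrix.csv")
  }
  if ("phases" %in% config$analyses) {
    ph <- peak_phase_distribution(traj)
    utils::write.csv(data.frame(id = net$cells$id, peak_time = ph$peak_time),
                     file.path(outdir, "peak_phases.csv"), row.names = FALSE)
    files$phases <- file.path(outdir, "peak_phases.csv")
  }
  prov <- list(package = "scnsim",
               version = as.character(utils::packageVersion("scnsim")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"),
               config = list(network = unclass(config$network),
                             cells = config$cells,
                             light = if (!is.null(config$light))
                               unclass(config$light),
                             sim = unclass(config$sim),
                             analyses = config$analyses))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files$provenance <- file.path(outdir, "provenance.json")
  invisible(c(files, list(trajectory = traj)))
}

#' Deterministic fixtures for tests and examples
#'
#' * `tiny-network`: a 20-cell network written as GraphML and CSV.
#' * `toy-trajectory`: three synthetic sinusoidal cell traces (two in
#'   antiphase, one in phase with the first) with known correlation
#'   structure, as tidy CSV.
#' * `toy-graph`: the 3-node path graph (efficiency 5/6) as edge-list CSV.
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory.
#' @return Character vector of written file paths.
#' @export
make_fixture <- function(kind = c("tiny-network", "toy-trajectory",
                                  "toy-graph"),
                         seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "tiny-network") {
    net <- build_network(network_config(N = 20, delta = 0.1, seed = seed))
    p1 <- file.path(dir, "tiny_network.graphml")
    write_network_graphml(net, p1)
    p2 <- write_network_csv(net, file.path(dir, "tiny_network"))
    c(p1, p2)
  } else if (kind == "toy-trajectory") {
    tt <- seq(0, 96, by = 0.1)
    df <- rbind(
      data.frame(time = tt, cell_id = 1L, value = cos(2 * pi * tt / 24)),
      data.frame(time = tt, cell_id = 2L, value = -cos(2 * pi * tt / 24)),
      data.frame(time = tt, cell_id = 3L, value = cos(2 * pi * tt / 24)))
    p <- file.path(dir, "toy_trajectory.csv")
    utils::write.csv(df, p, row.names = FALSE)
    p
  } else {
    p <- file.path(dir, "toy_graph_edges.csv")
    utils::write.csv(data.frame(i = c(1L, 2L), j = c(2L, 3L), weight = 1,
                                class = "short"),
                     p, row.names = FALSE)
    p
  }
}
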