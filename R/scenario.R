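#' Read a simulation scenario from a YAML file
#'
#' A scenario is a complete in-silico experiment: which network file to
#' load, the stimulus levels of input nodes, an optional list of
#' perturbations, and the simulation settings. Recognized keys:
#' \preformatted{
#' network: models/v2_delays.tsv     # path, relative to the scenario file
#' stimulus: {PA: 2}                 # input node -> level
#' perturbations:                    # optional, applied in order
#'   - {kind: knockout_node, node: PKR}
#'   - {kind: clamp_node, node: PP1, level: 1}
#'   - {kind: delete_edge, source: Ca, target: CaM, sign: activate}
#'   - {kind: set_delay, source: PA, target: PERK, sign: activate, delay: 5}
#' n_runs: 5000
#' horizon: 40
#' p: 0.1                            # initial-state spread
#' seed: 1
#' }
#' Missing simulation settings fall back to the defaults shown above.
#'
#' @param path path to the YAML scenario file.
#' @return A `trinet_scenario` object (named list as above, with the
#'   network path resolved relative to the scenario file).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$network)) stop("scenario lacks a 'network' key: ", path)
  netpath <- y$network
  if (!file.exists(netpath)) {
    netpath <- file.path(dirname(path), y$network)
  }
  if (!file.exists(netpath)) {
    stop("scenario network file not found: ", y$network)
  }
  perts <- lapply(y$perturbations, function(p) {
    if (is.null(p$kind)) stop("perturbation without 'kind' in ", path)
    switch(p$kind,
           knockout_node = knockout_node(p$node),
           clamp_node = clamp_node(p$node, p$level),
           delete_edge = delete_edge(p$source, p$target, p$sign),
           set_delay = set_delay(p$source, p$target, p$sign, p$delay),
           stop("unknown perturbation kind: ", p$kind))
  })
  structure(list(network = netpath,
                 stimulus = y$stimulus,
                 perturbations = perts,
                 n_runs = if (is.null(y$n_runs)) 5000L else as.integer(y$n_runs),
                 horizon = if (is.null(y$horizon)) 40L else as.integer(y$horizon),
                 p = if (is.null(y$p)) 0.1 else as.numeric(y$p),
                 seed = if (is.null(y$seed)) 1 else y$seed,
                 name = sub("\\.ya?ml$", "", basename(path))),
            class = "trinet_scenario")
}

#' @export
print.trinet_scenario <- function(x, ...) {
  cat(sprintf("trinet scenario '%s': %s, %d runs x %d steps, p=%g, seed=%s\n",
              x$name, basename(x$network), x$n_runs, x$horizon, x$p,
              format(x$seed)))
  if (length(x$stimulus)) {
    cat("  stimulus:", paste(names(x$stimulus), unlist(x$stimulus),
                             sep = "=", collapse = " "), "\n")
  }
  for (pt in x$perturbations) { cat("  "); print(pt) }
  invisible(x)
}

#' Execute a scenario
#'
#' Loads the scenario's network, applies the stimulus levels to its input
#' nodes, applies the perturbation list, and runs the ensemble.
#'
#' @param scenario a `trinet_scenario`, or the path of a scenario YAML
#'   file.
#' @param master_seed optional override of the scenario's seed.
#' @param n_runs,horizon optional overrides of the scenario's settings
#'   (used to scale analyses up or down without editing files).
#' @return List with elements `network` (the perturbed network actually
#'   simulated), `ensemble` (a `trinet_ensemble`) and `scenario`.
#' @export
run_scenario <- function(scenario, master_seed = NULL, n_runs = NULL,
                         horizon = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "trinet_scenario"))
  net <- parse_network(scenario$network)
  for (nm in names(scenario$stimulus)) {
    net <- set_input(net, nm, scenario$stimulus[[nm]])
  }
  net <- apply_perturbations(net, scenario$perturbations)
  seed <- if (is.null(master_seed)) scenario$seed else master_seed
  nr <- if (is.null(n_runs)) scenario$n_runs else as.integer(n_runs)
  hz <- if (is.null(horizon)) scenario$horizon else as.integer(horizon)
  ens <- run_ensemble(net, n_runs = nr, horizon = hz, p = scenario$p,
                      master_seed = seed)
  list(network = net, ensemble = ens, scenario = scenario)
}
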