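#' Run an ensemble of randomized runs (an in-silico cell population)
#'
#' Performs `n_runs` independent asynchronous runs, each with its own
#' counter-based random substream derived from `(master_seed, run index)`,
#' covering both the initial-state draw and the per-step update orders.
#' Per-node, per-step means and standard deviations over the runs emulate
#' a population-averaged measurement (western blot, RT-PCR). Results are
#' reproducible bit-exactly from the master seed.
#'
#' @param net a `trinet_network`.
#' @param n_runs number of independent runs (default 5000, the population
#'   size used throughout the bundled analyses).
#' @param horizon number of passes per run (default 40; with the bundled
#'   calibration of 10 steps to roughly 6 h this spans ~24 h).
#' @param p initial-state spread: ordinary nodes start at 0 or 2 each with
#'   probability `p`, at control otherwise.
#' @param master_seed integer master seed.
#' @param keep_runs keep the individual trajectories (array
#'   `(horizon+1) x nodes x n_runs`); intended for small test networks.
#' @return `trinet_ensemble` object: list with `mean` and `sd` matrices
#'   (`(horizon+1) x nodes`, rows named `"0"..horizon`), `n_runs`,
#'   `master_seed`, `p`, `horizon`, and optionally `runs`.
#' @examples
#' net <- network_spec(
#'   data.frame(source = "PA", sign = "activate", target = "X"),
#'   inputs = c(PA = 2))
#' ens <- run_ensemble(net, n_runs = 100, horizon = 5, master_seed = 1)
#' round(ens$mean, 2)
#' @export
run_ensemble <- function(net, n_runs = 5000L, horizon = 40L, p = 0.1,
                         master_seed = 1L, keep_runs = FALSE) {
  validate_network(net)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (horizon < 1L) stop("horizon must be >= 1")
  stopifnot(p >= 0, p < 0.5)
  na <- .net_arrays(net)
  res <- .run_ensemble_cpp(na, as.integer(n_runs), as.integer(horizon),
                           as.double(p), as.double(master_seed),
                           isTRUE(keep_runs))
  dn <- list(0:horizon, net$nodes$name)
  dimnames(res$mean) <- dn
  dimnames(res$sd) <- dn
  out <- list(mean = res$mean, sd = res$sd, n_runs = as.integer(n_runs),
              master_seed = master_seed, p = p,
              horizon = as.integer(horizon), nodes = net$nodes$name)
  if (isTRUE(keep_runs)) {
    dimnames(res$runs) <- c(dn, list(NULL))
    out$runs <- res$runs
  }
  structure(out, class = "trinet_ensemble")
}

#' @export
print.trinet_ensemble <- function(x, ...) {
  cat(sprintf("trinet ensemble: %d runs, horizon %d, %d nodes, seed %s\n",
              x$n_runs, x$horizon, length(x$nodes),
              format(x$master_seed)))
  steps <- unique(round(seq(1, x$horizon + 1, length.out = 6)))
  print(round(x$mean[steps, , drop = FALSE], 3))
  invisible(x)
}

#' Replicate-to-replicate dispersion of ensemble means
#'
#' Runs `n_replicates` independent ensembles (distinct derived master
#' seeds) and returns the maximum over steps, nodes and replicate pairs of
#' the absolute difference between ensemble means. Dispersion shrinks
#' roughly like `1/sqrt(n_runs)`; at the default population size of 5000
#' runs the averaged response curves are insensitive to the sampled
#' initial states and update orders.
#'
#' @inheritParams run_ensemble
#' @param n_replicates number of independent ensembles, `>= 2`.
#' @return Numeric scalar: the max absolute deviation between replicate
#'   means. The per-replicate mean matrices are attached as attribute
#'   `"means"`.
#' @export
replicate_dispersion <- function(net, n_runs, horizon, p = 0.1,
                                 n_replicates = 2L, master_seed = 1L) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  means <- lapply(seq_len(n_replicates), function(j) {
    run_ensemble(net, n_runs = n_runs, horizon = horizon, p = p,
                 master_seed = .derive_seed(master_seed, j))$mean
  })
  worst <- 0
  for (i in seq_len(n_replicates - 1L)) {
    for (j in seq.int(i + 1L, n_replicates)) {
      worst <- max(worst, max(abs(means[[i]] - means[[j]])))
    }
  }
  structure(worst, means = means)
}

# distinct, reproducible sub-seeds for replicate ensembles; kept < 2^31
.derive_seed <- function(master_seed, j) {
  (as.double(master_seed) * 48271 + j * 65537) %% 2147483647
}

#' Export an ensemble to a delimited file
#'
#' Long format is TSV with columns `step`, `node`, `mean`, `sd`; wide
#' format is CSV with one column per node holding the mean. Both carry
#' `#` header comments recording run count, master seed, spread and (when
#' supplied) the network file and its MD5 hash, so outputs are
#' self-describing.
#'
#' @param ens a `trinet_ensemble`.
#' @param path output file path.
#' @param format `"long"` (TSV) or `"wide"` (CSV).
#' @param network_file optional path of the network the ensemble was run
#'   on, recorded (with its MD5) in the header.
#' @param scenario optional scenario name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, format = c("long", "wide"),
                           network_file = NULL, scenario = NULL) {
  format <- match.arg(format)
  hdr <- c(sprintf("# trinet ensemble: n_runs=%d horizon=%d p=%g seed=%s",
                   ens$n_runs, ens$horizon, ens$p, format(ens$master_seed)))
  if (!is.null(network_file)) {
    hdr <- c(hdr, sprintf("# network=%s md5=%s", network_file,
                          unname(tools::md5sum(network_file))))
  }
  if (!is.null(scenario)) hdr <- c(hdr, paste0("# scenario=", scenario))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "long") {
    df <- data.frame(step = rep(0:ens$horizon, times = length(ens$nodes)),
                     node = rep(ens$nodes, each = ens$horizon + 1L),
                     mean = as.vector(ens$mean),
                     sd = as.vector(ens$sd))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(step = 0:ens$horizon, ens$mean, check.names = FALSE)
    write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plot ensemble mean trajectories
#'
#' @param x a `trinet_ensemble`.
#' @param nodes node names to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.trinet_ensemble <- function(x, nodes = x$nodes, ...) {
  m <- x$mean[, nodes, drop = FALSE]
  graphics::matplot(0:x$horizon, m, type = "l", lty = 1, lwd = 2,
                    col = grDevices::hcl.colors(max(2, ncol(m)), "Dark 3"),
                    xlab = "time step", ylab = "mean state",
                    ylim = c(0, 2), ...)
  graphics::abline(h = 1, col = "grey70", lty = 3)
  graphics::legend("topright", legend = colnames(m), lty = 1, lwd = 2,
                   col = grDevices::hcl.colors(max(2, ncol(m)), "Dark 3"),
                   bty = "n", cex = 0.8)
  invisible(x)
}
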