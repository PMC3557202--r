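#' In-silico perturbations
#'
#' Constructors for the four perturbation kinds applied by
#' [apply_perturbations()]:
#' \describe{
#'   \item{`knockout_node(node)`}{models siRNA silencing by clamping the
#'     node at level 0 (below control); the graph stays intact so delayed
#'     edges and influence sums remain well defined.}
#'   \item{`clamp_node(node, level)`}{holds a node at a constant level,
#'     encoding posterior information such as an experimentally unchanged
#'     phosphatase (clamp at 1 severs its dynamic feedback).}
#'   \item{`delete_edge(source, target, sign)`}{removes a single
#'     interaction: pathway deletion, distinct from node knockout.}
#'   \item{`set_delay(source, target, sign, delay)`}{rewrites an
#'     interaction's delay, encoding measured response-time separations.}
#' }
#'
#' @param node,source,target node names.
#' @param level clamp level in `0:2`.
#' @param sign `"activate"` or `"inhibit"`.
#' @param delay non-negative integer delay in steps.
#' @return A `trinet_perturbation` object.
#' @name perturbations
NULL

.pert <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "trinet_perturbation")
}

#' @rdname perturbations
#' @export
knockout_node <- function(node) .pert("knockout_node", node = node)

#' @rdname perturbations
#' @export
clamp_node <- function(node, level) {
  if (!(level %in% 0:2)) stop("clamp level must be in 0:2")
  .pert("clamp_node", node = node, level = as.integer(level))
}

#' @rdname perturbations
#' @export
delete_edge <- function(source, target, sign) {
  stopifnot(sign %in% c("activate", "inhibit"))
  .pert("delete_edge", source = source, target = target, sign = sign)
}

#' @rdname perturbations
#' @export
set_delay <- function(source, target, sign, delay) {
  stopifnot(sign %in% c("activate", "inhibit"))
  if (is.na(delay) || delay < 0 || delay != round(delay)) {
    stop("delay must be a non-negative integer")
  }
  .pert("set_delay", source = source, target = target, sign = sign,
        delay = as.integer(delay))
}

#' @export
print.trinet_perturbation <- function(x, ...) {
  cat(switch(x$kind,
             knockout_node = sprintf("knockout %s (clamp at 0)", x$node),
             clamp_node = sprintf("clamp %s at %d", x$node, x$level),
             delete_edge = sprintf("delete edge %s %s %s", x$source,
                                   if (x$sign == "activate") "->" else "-|",
                                   x$target),
             set_delay = sprintf("set delay %s %s %s to %d", x$source,
                                 if (x$sign == "activate") "->" else "-|",
                                 x$target, x$delay)), "\n")
  invisible(x)
}

#' Apply a list of perturbations to a network
#'
#' Perturbations are applied in order to a copy of the network; the
#' original is never modified. A knockout clamps its node at 0; a clamp
#' sets the given level (turning an ordinary node into a clamped one);
#' edge deletions and delay edits must name an existing
#' (source, target, sign) interaction. Two perturbations clamping the same
#' node within one list conflict and raise an error rather than silently
#' applying last-wins.
#'
#' @param net a `trinet_network`.
#' @param perturbations a list of [perturbations] (a single perturbation
#'   is accepted).
#' @return A new, validated `trinet_network`.
#' @examples
#' net <- network_spec(
#'   data.frame(source = c("PA", "X"), sign = "activate",
#'              target = c("X", "Y")),
#'   inputs = c(PA = 2))
#' apply_perturbations(net, list(knockout_node("X")))
#' @export
apply_perturbations <- function(net, perturbations) {
  validate_network(net)
  if (inherits(perturbations, "trinet_perturbation")) {
    perturbations <- list(perturbations)
  }
  clamped_here <- character()
  for (pt in perturbations) {
    stopifnot(inherits(pt, "trinet_perturbation"))
    if (pt$kind %in% c("knockout_node", "clamp_node")) {
      i <- match(pt$node, net$nodes$name)
      if (is.na(i)) stop("perturbation targets unknown node: ", pt$node)
      if (pt$node %in% clamped_here) {
        stop("conflicting clamps on node ", pt$node,
             ": clamped more than once in one perturbation list")
      }
      clamped_here <- c(clamped_here, pt$node)
      net$nodes$role[i] <- "clamped"
      net$nodes$clamp_level[i] <-
        if (pt$kind == "knockout_node") 0L else pt$level
    } else {
      j <- which(net$edges$source == pt$source &
                 net$edges$target == pt$target &
                 net$edges$sign == pt$sign)
      if (length(j) != 1L) {
        stop("perturbation targets unknown edge: ", pt$source, " ",
             pt$sign, " ", pt$target)
      }
      if (pt$kind == "delete_edge") {
        net$edges <- net$edges[-j, , drop = FALSE]
        rownames(net$edges) <- NULL
      } else {
        net$edges$delay[j] <- pt$delay
        net$edges <- .canon_edges(net$edges)
      }
    }
  }
  validate_network(net)
  net
}

#' Difference between a perturbed and a reference ensemble
#'
#' Returns, for one node, the per-step difference of ensemble means
#' (perturbed minus reference) together with a pooled Monte-Carlo standard
#' error `sqrt(sd_ref^2/n_ref + sd_pert^2/n_pert)`. No hypothesis-testing
#' machinery is attached: the runs are simulations, so the standard error
#' only quantifies sampling noise of the two ensembles.
#'
#' @param ref,pert `trinet_ensemble` objects over the same horizon and
#'   node set.
#' @param node node name.
#' @return Data frame with columns `step`, `diff`, `se`.
#' @export
compare_ensembles <- function(ref, pert, node) {
  stopifnot(inherits(ref, "trinet_ensemble"),
            inherits(pert, "trinet_ensemble"))
  if (ref$horizon != pert$horizon || !identical(ref$nodes, pert$nodes)) {
    stop("ensembles are not comparable (different horizon or node sets)")
  }
  if (!(node %in% ref$nodes)) stop("unknown node: ", node)
  data.frame(step = 0:ref$horizon,
             diff = pert$mean[, node] - ref$mean[, node],
             se = sqrt(ref$sd[, node]^2 / ref$n_runs +
                       pert$sd[, node]^2 / pert$n_runs),
             row.names = NULL)
}
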