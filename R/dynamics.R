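#' Signed influence on a node
#'
#' The influence on a node is the sum, over its incoming edges, of
#' `sign * (regulator_state - 1)`, where `sign` is +1 for activation and
#' -1 for inhibition and the regulator state is read at the edge's delay:
#' delay 0 reads `current`, the in-pass working state vector; delay `d >= 1`
#' reads the history snapshot taken `d` steps before the pass being
#' computed (baseline 1 before the start of the simulation). A node with no
#' regulators has influence 0. An activator below control thus contributes
#' -1 and an inhibitor below control contributes +1 (de-repression): the
#' signed sum is the symmetric completion of the single-regulator
#' shift rules.
#'
#' @param node name of an ordinary node.
#' @param net a `trinet_network`.
#' @param current named integer vector: the working states during the
#'   current pass (updates already realized this pass included).
#' @param history integer matrix of step-boundary snapshots, one row per
#'   completed step (row 1 = initial state), columns named by node. Row
#'   `nrow(history)` is the last completed step; delay-d reads come from
#'   row `nrow(history) - d`, or baseline 1 when that row does not exist.
#' @return Integer influence (can be any signed integer).
#' @export
influence <- function(node, net, current, history) {
  ed <- net$edges
  inc <- ed[ed$target == node, , drop = FALSE]
  if (nrow(inc) == 0L) return(0L)
  tot <- 0L
  hrows <- nrow(history)
  for (i in seq_len(nrow(inc))) {
    d <- inc$delay[i]
    src <- inc$source[i]
    st <- if (d == 0L) {
      current[[src]]
    } else if (hrows - d >= 1L) {
      history[hrows - d, src]
    } else {
      .st_baseline
    }
    sgn <- if (inc$sign[i] == "activate") 1L else -1L
    tot <- tot + sgn * (st - .st_baseline)
  }
  as.integer(tot)
}

#' Single-node transition rule
#'
#' Positive influence shifts the state up one level (saturating at 2),
#' negative influence shifts it down one level (saturating at 0), and zero
#' influence decays the state one level toward the control state 1. Clamped
#' and input nodes never pass through this rule.
#'
#' @param current state in `0:2`.
#' @param infl signed integer influence.
#' @return The next state in `0:2`.
#' @examples
#' update_node(1, +1)  # 2: shift up
#' update_node(2, 0)   # 1: decay back to control
#' update_node(0, -1)  # 0: saturation at the floor
#' @export
update_node <- function(current, infl) {
  stopifnot(current %in% .st_states)
  if (infl > 0) return(min(current + 1L, 2L))
  if (infl < 0) return(max(current - 1L, 0L))
  if (current > 1L) return(current - 1L)
  if (current < 1L) return(current + 1L)
  1L
}

#' One asynchronous update pass
#'
#' Visits the ordinary nodes once each, in the given (or freshly drawn
#' uniform random) order, computing each node's influence and applying
#' [update_node()] with the result realized immediately: later nodes in
#' the same pass see the new state through their delay-0 edges. Delayed
#' reads always come from the step-boundary `history`, never from mid-pass
#' states. Clamped and input nodes keep their level.
#'
#' This is the reference R implementation of the engine's step semantics;
#' [simulate_run()] and [run_ensemble()] execute the same semantics in
#' compiled code.
#'
#' @param state named integer vector of current states (the last history
#'   row).
#' @param net a `trinet_network`.
#' @param history integer matrix of snapshots up to and including `state`
#'   (see [influence()]).
#' @param order character vector: a permutation of the ordinary node names.
#'   Drawn uniformly via `sample()` when omitted.
#' @return The named state vector after the pass.
#' @export
step <- function(state, net, history, order = NULL) {
  nd <- net$nodes
  ordinary <- nd$name[nd$role == "ordinary"]
  if (is.null(order)) {
    order <- if (length(ordinary) > 1L) sample(ordinary) else ordinary
  }
  stopifnot(setequal(order, ordinary), length(order) == length(ordinary))
  w <- state
  for (nm in order) {
    infl <- influence(nm, net, w, history)
    w[[nm]] <- update_node(w[[nm]], infl)
  }
  fixed <- nd$role != "ordinary"
  w[nd$name[fixed]] <- nd$clamp_level[fixed]
  w
}

#' Draw an initial state vector
#'
#' Ordinary nodes start at 0 with probability `p`, at 2 with probability
#' `p` and at the control state 1 otherwise, so the expected initial state
#' is exactly 1 and the population is centered at control. Input and
#' clamped nodes start at their level.
#'
#' @param net a `trinet_network`.
#' @param p spread probability in `[0, 0.5)`.
#' @return Named integer state vector.
#' @export
draw_initial_state <- function(net, p = 0.1) {
  stopifnot(p >= 0, p < 0.5)
  nd <- net$nodes
  s <- ifelse(nd$role == "ordinary",
              sample(c(0L, 2L, 1L), nrow(nd), replace = TRUE,
                     prob = c(p, p, 1 - 2 * p)),
              nd$clamp_level)
  names(s) <- nd$name
  s
}

#' Simulate one randomized run
#'
#' Runs `horizon` asynchronous passes from an initial state, recording the
#' trajectory. Pre-initial history is baseline 1 everywhere (cells are at
#' control before stimulation), so a delay-d edge from a stimulus leaves
#' its target at baseline for exactly the first d steps. The run is
#' deterministic given the network, initial state, seed and horizon; the
#' random stream is a counter-based generator derived from
#' `(master_seed, run_index)`, independent of R's global RNG.
#'
#' @param net a `trinet_network`.
#' @param init optional named initial state vector (validated against the
#'   network); when omitted it is drawn from the initial-state distribution
#'   with spread `p` using the run's random stream.
#' @param horizon number of passes, `>= 1`.
#' @param master_seed integer master seed.
#' @param run_index run counter within an ensemble (default 0).
#' @param orders optional integer matrix (`horizon` x number of ordinary
#'   nodes) of explicit update orders, each row a permutation of the
#'   ordinary node indices (in `net$nodes` order); used to drive the engine
#'   deterministically, e.g. to enumerate worst-case orders.
#' @param p initial-state spread used when `init` is omitted.
#' @return Integer matrix with `horizon + 1` rows (row `"0"` = initial
#'   state) and one named column per node, class `trinet_trajectory`.
#' @examples
#' net <- network_spec(
#'   data.frame(source = "PA", sign = "activate", target = "X"),
#'   inputs = c(PA = 2))
#' simulate_run(net, horizon = 3, master_seed = 1)
#' @export
simulate_run <- function(net, init = NULL, horizon = 40L, master_seed = 1L,
                         run_index = 0L, orders = NULL, p = 0.1) {
  validate_network(net)
  if (horizon < 1L) stop("horizon must be >= 1")
  na <- .net_arrays(net)
  nd <- net$nodes
  if (!is.null(init)) {
    if (!setequal(names(init), nd$name)) {
      stop("init must name every network node and no other")
    }
    init <- init[nd$name]
    if (!all(init %in% .st_states)) stop("init states must be in 0:2")
    fixed <- nd$role != "ordinary"
    if (!all(init[fixed] == nd$clamp_level[fixed])) {
      stop("init must hold clamped/input nodes at their level")
    }
    init <- as.integer(init)
  }
  if (!is.null(orders)) {
    orders <- as.matrix(orders)
    k <- length(na$ordinary)
    if (!all(dim(orders) == c(horizon, k))) {
      stop("orders must be a horizon x n_ordinary matrix")
    }
    ok <- apply(orders, 1, function(r) setequal(r, na$ordinary + 1L))
    if (!all(ok)) stop("each orders row must permute the ordinary nodes")
    storage.mode(orders) <- "integer"
    orders <- orders - 1L
  }
  traj <- .sim_run_cpp(na, init, as.integer(horizon),
                       as.double(master_seed), as.integer(run_index),
                       orders, as.double(p))
  dimnames(traj) <- list(0:horizon, nd$name)
  class(traj) <- c("trinet_trajectory", class(traj))
  traj
}
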