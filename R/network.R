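#' Construct a signed, delay-annotated interaction network
#'
#' A network holds a node table (name, role, clamp level) and an edge table
#' (source, sign, target, delay). Roles are `ordinary` (updated by the
#' dynamics), `input` (a stimulus held at a fixed level, typically set by a
#' scenario) and `clamped` (a posterior constraint or in-silico knockout,
#' held at a fixed level). Inputs and clamps must carry a level in `0:2`;
#' ordinary nodes must not. Delays are non-negative integers counted in
#' global time steps; a delay-0 edge reads its regulator's current state.
#'
#' The node set is the union of edge endpoints and any declared nodes.
#' Duplicate (source, target, sign) triples are rejected; a pair of
#' opposite-sign edges between the same nodes is allowed (each with its own
#' delay), which is how delayed attenuation of a stimulus arm is expressed.
#'
#' @param edges data frame (or NULL) with columns `source`, `sign`
#'   (`"activate"` or `"inhibit"`), `target` and optionally `delay`
#'   (defaults to 0).
#' @param inputs named integer vector of input nodes and their levels,
#'   e.g. `c(PA = 2)`.
#' @param clamps named integer vector of clamped nodes and their levels,
#'   e.g. `c(PP1 = 1)`.
#' @param nodes optional character vector of additional (isolated) ordinary
#'   node names.
#' @return An object of class `trinet_network` with elements `nodes` and
#'   `edges`, both canonically sorted so that structurally equal networks
#'   are `identical()`.
#' @examples
#' net <- network_spec(
#'   edges = data.frame(source = c("PA", "PACT"), sign = "activate",
#'                      target = c("PACT", "PKR")),
#'   inputs = c(PA = 2))
#' net
#' @export
network_spec <- function(edges = NULL, inputs = integer(), clamps = integer(),
                         nodes = character()) {
  edges <- .canon_edges(edges)
  declared <- c(names(inputs), names(clamps), nodes)
  all_names <- sort(unique(c(edges$source, edges$target, declared)))
  if (length(all_names) == 0L) stop("network has no nodes")
  role <- rep("ordinary", length(all_names))
  level <- rep(NA_integer_, length(all_names))
  role[all_names %in% names(clamps)] <- "clamped"
  role[all_names %in% names(inputs)] <- "input"
  lv <- c(clamps, inputs)
  level[match(names(lv), all_names)] <- as.integer(lv)
  node_df <- data.frame(name = all_names, role = role, clamp_level = level,
                        stringsAsFactors = FALSE)
  net <- structure(list(nodes = node_df, edges = edges),
                   class = "trinet_network")
  validate_network(net)
  net
}

.canon_edges <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(data.frame(source = character(), sign = character(),
                      target = character(), delay = integer(),
                      stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$delay)) edges$delay <- 0L
  edges <- edges[c("source", "sign", "target", "delay")]
  edges$source <- as.character(edges$source)
  edges$sign <- as.character(edges$sign)
  edges$target <- as.character(edges$target)
  edges$delay <- as.integer(edges$delay)
  ord <- order(edges$source, edges$target, edges$sign, edges$delay)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Validate a trinet network
#'
#' Checks every structural invariant: unique non-empty node names, clamp
#' levels present exactly for input/clamped roles and within `0:2`, edge
#' endpoints resolvable, signs in `activate`/`inhibit`, integer delays
#' `>= 0`, and no duplicate (source, target, sign) triples.
#'
#' @param net a `trinet_network`.
#' @return `net`, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "trinet_network"))
  nd <- net$nodes
  ed <- net$edges
  if (any(!nzchar(nd$name))) stop("node names must be non-empty")
  if (anyDuplicated(nd$name)) {
    stop("duplicate node name: ", nd$name[duplicated(nd$name)][1])
  }
  if (!all(nd$role %in% c("ordinary", "input", "clamped"))) {
    stop("unknown node role: ",
         setdiff(nd$role, c("ordinary", "input", "clamped"))[1])
  }
  fixed <- nd$role != "ordinary"
  if (any(fixed & is.na(nd$clamp_level))) {
    stop("clamp level missing for node declared input/clamped: ",
         nd$name[fixed & is.na(nd$clamp_level)][1])
  }
  if (any(!fixed & !is.na(nd$clamp_level))) {
    stop("ordinary node must not carry a clamp level: ",
         nd$name[!fixed & !is.na(nd$clamp_level)][1])
  }
  if (any(fixed & !(nd$clamp_level %in% 0:2))) {
    stop("clamp level must be in 0:2 for node: ",
         nd$name[fixed & !(nd$clamp_level %in% 0:2)][1])
  }
  if (nrow(ed)) {
    bad <- !(ed$source %in% nd$name) | !(ed$target %in% nd$name)
    if (any(bad)) stop("edge endpoint not a declared node: ",
                       ed$source[bad][1], " -> ", ed$target[bad][1])
    if (!all(ed$sign %in% c("activate", "inhibit"))) {
      stop("unknown sign token: ",
           setdiff(ed$sign, c("activate", "inhibit"))[1])
    }
    if (any(is.na(ed$delay) | ed$delay < 0L)) {
      stop("delay must be a non-negative integer (edge ",
           ed$source[is.na(ed$delay) | ed$delay < 0][1], " -> ",
           ed$target[is.na(ed$delay) | ed$delay < 0][1], ")")
    }
    key <- paste(ed$source, ed$target, ed$sign)
    if (anyDuplicated(key)) {
      stop("duplicate edge (same source, target and sign): ",
           key[duplicated(key)][1])
    }
  }
  invisible(net)
}

#' Read an interaction network from a tab-separated file
#'
#' The format is a TSV edge list with one interaction per line
#' (`source TAB sign TAB target [TAB delay]`), preceded by `#`-prefixed
#' header lines declaring node roles:
#' \preformatted{
#' # input PA 2
#' # clamp PP1 1
#' # node Orphan
#' PA	activate	PACT	0
#' }
#' `sign` is `activate` or `inhibit`; a missing delay field defaults to 0.
#' Other comment lines are ignored for the dynamics but preserved in the
#' `"comments"` attribute of the returned object.
#'
#' @param path path to the network file.
#' @return A validated [network_spec()] object.
#' @seealso [write_network()] for the canonical writer.
#' @export
parse_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  inputs <- integer()
  clamps <- integer()
  extra_nodes <- character()
  comments <- character()
  edat <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      tok <- strsplit(body, "[ \t]+")[[1]]
      if (length(tok) >= 1 && tok[1] %in% c("input", "clamp", "node")) {
        if (tok[1] == "node") {
          if (length(tok) != 2) {
            stop("line ", i, ": node declaration needs exactly a name: ", ln)
          }
          extra_nodes <- c(extra_nodes, tok[2])
        } else {
          if (length(tok) != 3 || is.na(suppressWarnings(as.integer(tok[3])))) {
            stop("line ", i, ": ", tok[1],
                 " declaration needs a name and a level in 0:2: ", ln)
          }
          lv <- as.integer(tok[3])
          if (tok[1] == "input") inputs[tok[2]] <- lv else clamps[tok[2]] <- lv
        }
      } else {
        comments <- c(comments, ln)
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (!(length(f) %in% c(3L, 4L))) {
      stop("line ", i, ": expected 3 or 4 tab-separated fields, got ",
           length(f), ": ", ln)
    }
    if (!(f[2] %in% c("activate", "inhibit"))) {
      stop("line ", i, ": unknown sign token '", f[2], "'")
    }
    delay <- 0L
    if (length(f) == 4L) {
      delay <- suppressWarnings(as.numeric(f[4]))
      if (is.na(delay) || delay < 0 || delay != round(delay)) {
        stop("line ", i, ": delay must be a non-negative integer, got '",
             f[4], "'")
      }
      delay <- as.integer(delay)
    }
    edat[[length(edat) + 1L]] <-
      data.frame(source = f[1], sign = f[2], target = f[3], delay = delay,
                 stringsAsFactors = FALSE)
  }
  edges <- if (length(edat)) do.call(rbind, edat) else NULL
  if (!is.null(edges)) {
    key <- paste(edges$source, edges$target, edges$sign)
    if (anyDuplicated(key)) {
      stop("duplicate edge (same source, target and sign): ",
           key[duplicated(key)][1])
    }
  }
  net <- network_spec(edges, inputs = inputs, clamps = clamps,
                      nodes = extra_nodes)
  attr(net, "comments") <- comments
  net
}

#' Write a network to its canonical tab-separated representation
#'
#' Emits role declarations (inputs, clamps, isolated ordinary nodes) sorted
#' by name, then edges sorted lexicographically by source, target, sign and
#' delay, with the delay field always present. Two structurally equal
#' networks therefore serialize to byte-identical files, and
#' `parse_network(write_network(net))` returns a network `identical()` to
#' `net` (comments are not written).
#'
#' @param net a `trinet_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  validate_network(net)
  nd <- net$nodes
  ed <- net$edges
  lines <- character()
  for (i in seq_len(nrow(nd))) {
    if (nd$role[i] == "input") {
      lines <- c(lines, sprintf("# input %s %d", nd$name[i], nd$clamp_level[i]))
    } else if (nd$role[i] == "clamped") {
      lines <- c(lines, sprintf("# clamp %s %d", nd$name[i], nd$clamp_level[i]))
    } else if (!(nd$name[i] %in% c(ed$source, ed$target))) {
      lines <- c(lines, sprintf("# node %s", nd$name[i]))
    }
  }
  if (nrow(ed)) {
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d",
                              ed$source, ed$sign, ed$target, ed$delay))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.trinet_network <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("trinet network: %d nodes, %d edges\n", nrow(nd), nrow(x$edges)))
  fixed <- nd$role != "ordinary"
  if (any(fixed)) {
    cat("  fixed:", paste(sprintf("%s[%s=%d]", nd$name[fixed],
                                  substr(nd$role[fixed], 1, 5),
                                  nd$clamp_level[fixed]), collapse = " "), "\n")
  }
  if (nrow(x$edges)) {
    arrow <- ifelse(x$edges$sign == "activate", "->", "-|")
    lab <- sprintf("%s %s %s (d=%d)", x$edges$source, arrow,
                   x$edges$target, x$edges$delay)
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

# node names in canonical (row) order
.node_names <- function(net) net$nodes$name

# prepare 0-based arrays for the C++ core
.net_arrays <- function(net) {
  nd <- net$nodes
  ed <- net$edges
  idx <- function(nm) match(nm, nd$name) - 1L
  list(src = idx(ed$source),
       tgt = idx(ed$target),
       sgn = ifelse(ed$sign == "activate", 1L, -1L),
       del = ed$delay,
       clamped = nd$role != "ordinary",
       clamp_level = ifelse(is.na(nd$clamp_level), -1L, nd$clamp_level),
       ordinary = which(nd$role == "ordinary") - 1L)
}

#' Set the level of an input node
#'
#' Scenario stimuli (e.g. palmitate at level 2) are expressed by setting
#' the level of a node declared `input` in the network file. Unlike
#' [clamp_node()] perturbations this is the intended mechanism for driving
#' a model, so overriding the file's default input level is not an error.
#'
#' @param net a `trinet_network`.
#' @param node name of a node with role `input`.
#' @param level state in `0:2` to hold the input at.
#' @return A new network with the input level set.
#' @export
set_input <- function(net, node, level) {
  validate_network(net)
  i <- match(node, net$nodes$name)
  if (is.na(i)) stop("unknown node: ", node)
  if (net$nodes$role[i] != "input") {
    stop("node is not an input: ", node, " (role ", net$nodes$role[i], ")")
  }
  if (!(level %in% 0:2)) stop("input level must be in 0:2")
  net$nodes$clamp_level[i] <- as.integer(level)
  net
}
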