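# Small networks built in code for the tests.

edge_df <- function(source, sign, target, delay = 0L) {
  data.frame(source = source, sign = sign, target = target, delay = delay,
             stringsAsFactors = FALSE)
}

# PA (input at `level`) -> N1 -> N2 -> ... -> Nk, all activating
chain_net <- function(k, level = 2, delays = 0L) {
  nodes <- c("PA", paste0("N", seq_len(k)))
  edge <- edge_df(head(nodes, -1), "activate", nodes[-1], delays)
  network_spec(edge, inputs = c(PA = level))
}

# random small network for property-style tests (uses R's RNG; callers seed)
random_net <- function(n_ordinary = 3, n_edges = 4) {
  nodes <- paste0("X", seq_len(n_ordinary))
  src <- c("IN", nodes)
  e <- unique(edge_df(sample(src, n_edges, replace = TRUE),
                      sample(c("activate", "inhibit"), n_edges, replace = TRUE),
                      sample(nodes, n_edges, replace = TRUE),
                      sample(0:2, n_edges, replace = TRUE)))
  key <- paste(e$source, e$target, e$sign)
  e <- e[!duplicated(key), ]
  network_spec(e, inputs = c(IN = sample(0:2, 1)), nodes = nodes)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

traj_key <- function(mat) paste(as.vector(t(mat)), collapse = "")
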