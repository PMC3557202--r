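test_that("update_node reproduces the single-regulator shift/decay rules", {
  # shift up: 0 -> 1 -> 2, saturating
  expect_identical(update_node(0L, +1L), 1L)
  expect_identical(update_node(1L, +1L), 2L)
  expect_identical(update_node(2L, +1L), 2L)
  # shift down, saturating
  expect_identical(update_node(2L, -1L), 1L)
  expect_identical(update_node(1L, -1L), 0L)
  expect_identical(update_node(0L, -1L), 0L)
  # decay back to control from either side
  expect_identical(update_node(2L, 0L), 1L)
  expect_identical(update_node(0L, 0L), 1L)
  expect_identical(update_node(1L, 0L), 1L)
})

test_that("influence is the signed sum of regulator deviations", {
  net <- network_spec(
    edge_df(c("A", "B", "C"), c("activate", "inhibit", "activate"),
            c("T", "T", "T")),
    nodes = "T")
  hist <- matrix(1L, 1, 5, dimnames = list(NULL, c("A", "B", "C", "T", "X")))
  cur <- c(A = 2L, B = 1L, C = 1L, T = 1L, X = 1L)
  expect_identical(influence("T", net, cur, hist), 1L)      # activator at 2
  cur["B"] <- 2L
  expect_identical(influence("T", net, cur, hist), 0L)      # terms cancel
  cur <- c(A = 1L, B = 0L, C = 1L, T = 1L, X = 1L)
  expect_identical(influence("T", net, cur, hist), 1L)      # de-repression
  cur["C"] <- 0L                                            # activator below
  expect_identical(influence("T", net, cur, hist), 0L)
  expect_identical(influence("X", net, cur, hist), 0L)      # no regulators
})

test_that("delayed influence reads history snapshots, baseline before t0", {
  net <- network_spec(edge_df("A", "activate", "T", 2L))
  hist1 <- matrix(c(2L, 1L), 1, 2, dimnames = list(NULL, c("A", "T")))
  cur <- c(A = 2L, T = 1L)
  # only one completed row: lag 2 predates the simulation -> baseline 1
  expect_identical(influence("T", net, cur, hist1), 0L)
  hist3 <- rbind(hist1, c(0L, 1L), c(2L, 1L))
  # lag 2 from the last completed row = row 1 (A was 2)
  expect_identical(influence("T", net, cur, hist3), 1L)
})

test_that("asynchronous updates are realized immediately within a pass", {
  net <- network_spec(edge_df(c("A", "B"), "activate", c("B", "C")),
                      inputs = c(A = 2))
  s0 <- c(A = 2L, B = 1L, C = 1L)
  hist <- matrix(s0, 1, dimnames = list(NULL, names(s0)))
  downstream_last <- step(s0, net, hist, order = c("B", "C"))
  expect_identical(downstream_last[c("B", "C")], c(B = 2L, C = 2L))
  downstream_first <- step(s0, net, hist, order = c("C", "B"))
  expect_identical(downstream_first[c("B", "C")], c(C = 1L, B = 2L)[c("B", "C")])
  # compiled engine agrees when driven with the same explicit orders
  idx <- function(nm) match(nm, net$nodes$name)
  tr1 <- simulate_run(net, init = s0, horizon = 1,
                      orders = matrix(idx(c("B", "C")), 1))
  expect_identical(tr1["1", c("B", "C")], c(B = 2L, C = 2L))
  tr2 <- simulate_run(net, init = s0, horizon = 1,
                      orders = matrix(idx(c("C", "B")), 1))
  expect_identical(tr2["1", c("B", "C")], c(B = 2L, C = 1L))
})

test_that("a network of only clamped nodes is a fixed point", {
  net <- network_spec(edge_df("A", "activate", "B"),
                      inputs = c(A = 2), clamps = c(B = 0))
  tr <- simulate_run(net, horizon = 4, master_seed = 7)
  expect_true(all(tr[, "A"] == 2L))
  expect_true(all(tr[, "B"] == 0L))
  s0 <- c(A = 2L, B = 0L)
  expect_identical(step(s0, net, matrix(s0, 1, dimnames = list(NULL, names(s0)))),
                   s0)
})

test_that("an activating chain saturates within k steps for every order", {
  net <- chain_net(3)  # PA -> N1 -> N2 -> N3
  perms <- all_perms(match(paste0("N", 1:3), net$nodes$name))
  init <- c(PA = 2L, N1 = 1L, N2 = 1L, N3 = 1L)[net$nodes$name]
  for (o1 in perms) for (o2 in perms) for (o3 in perms) {
    tr <- simulate_run(net, init = init, horizon = 3,
                       orders = rbind(o1, o2, o3))
    expect_equal(unname(tr[4, "N3"]), 2L)
    # monotone-path property: once a node reaches 2 it stays there
    for (nd in paste0("N", 1:3)) {
      col <- tr[, nd]
      first2 <- match(2L, col)
      if (!is.na(first2)) expect_true(all(col[first2:length(col)] == 2L))
    }
  }
})

test_that("an edge with delay d holds its target at baseline for d steps", {
  for (d in c(1L, 2L, 3L, 5L)) {
    net <- network_spec(edge_df("PA", "activate", "T", d),
                        inputs = c(PA = 2))
    tr <- simulate_run(net, init = c(PA = 2L, T = 1L), horizon = d + 2L,
                       master_seed = 1)
    expect_true(all(tr[1:(d + 1L), "T"] == 1L), info = paste("d =", d))
    expect_equal(unname(tr[d + 2L, "T"]), 2L, info = paste("d =", d))
  }
})

test_that("runs are deterministic in the seed and vary across run indices", {
  net <- random_net(4, 6)
  a <- simulate_run(net, horizon = 10, master_seed = 11, run_index = 0)
  b <- simulate_run(net, horizon = 10, master_seed = 11, run_index = 0)
  expect_identical(a, b)
  many <- sapply(0:19, function(r) {
    traj_key(simulate_run(net, horizon = 10, master_seed = 11, run_index = r))
  })
  expect_gt(length(unique(many)), 1L)
})

test_that("trajectories stay in the state alphabet with clamps constant", {
  set.seed(99)
  for (i in 1:10) {
    net <- random_net(n_ordinary = sample(2:4, 1), n_edges = sample(2:7, 1))
    tr <- simulate_run(net, horizon = 12, master_seed = i, p = 0.3)
    expect_true(all(tr %in% 0:2))
    fixed <- net$nodes$role != "ordinary"
    for (j in which(fixed)) {
      expect_true(all(tr[, net$nodes$name[j]] == net$nodes$clamp_level[j]))
    }
  }
})

test_that("engine trajectory distribution matches exhaustive enumeration", {
  nets <- list(
    inhibited_pair = network_spec(
      edge_df(c("IN", "X1"), c("inhibit", "activate"), c("X1", "X2")),
      inputs = c(IN = 2)),
    delayed_loop = network_spec(
      edge_df(c("IN", "X1", "X2"), c("activate", "activate", "inhibit"),
              c("X1", "X2", "X1"), c(0L, 1L, 0L)),
      inputs = c(IN = 2)))
  n <- 6000
  for (nm in names(nets)) {
    net <- nets[[nm]]
    dist <- oracle_distribution(net, horizon = 3, p = 0.1)
    expect_equal(sum(dist), 1, tolerance = 1e-12)
    ens <- run_ensemble(net, n_runs = n, horizon = 3, p = 0.1,
                        master_seed = 5, keep_runs = TRUE)
    p <- oracle_chisq_p(ensemble_keys(ens), dist)
    expect_gt(p, 1e-4)
    exact <- oracle_mean(dist, length(net$nodes$name), 3)
    se <- pmax(ens$sd / sqrt(n), 1e-9)
    expect_true(all(abs(ens$mean - exact) <= 3 * se + 1e-9), info = nm)
  }
})
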