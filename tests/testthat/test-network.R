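test_that("a plain three-edge file parses into four nodes with zero delays", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PA\tactivate\tPACT", "PACT\tactivate\tPKR",
               "PKR\tactivate\teIF2a"), f)
  net <- parse_network(f)
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$delay == 0L))
  expect_true(all(net$nodes$role == "ordinary"))
})

test_that("a header-only file yields a one-node, zero-edge network", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# input PA 2", f)
  net <- parse_network(f)
  expect_equal(net$nodes,
               data.frame(name = "PA", role = "input", clamp_level = 2L))
  expect_equal(nrow(net$edges), 0L)
})

test_that("write_network emits a canonical file that round-trips", {
  net <- network_spec(
    edge_df(c("B", "A", "A"), c("activate", "inhibit", "activate"),
            c("C", "B", "B"), c(2L, 0L, 5L)),
    inputs = c(A = 2), clamps = c(D = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- parse_network(f)
  attributes(back) <- attributes(back)[c("names", "class")]
  expect_identical(back, net)
})

test_that("structurally equal networks serialize byte-identically", {
  e1 <- edge_df(c("A", "B"), "activate", c("B", "C"), c(1L, 0L))
  e2 <- e1[2:1, ]  # same edges, different row order
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(network_spec(e1, inputs = c(A = 2)), f1)
  write_network(network_spec(e2, inputs = c(A = 2)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("parse/write is the identity on randomly generated networks", {
  set.seed(42)
  for (i in 1:25) {
    net <- random_net(n_ordinary = sample(2:5, 1), n_edges = sample(1:8, 1))
    f <- tempfile()
    write_network(net, f)
    back <- parse_network(f)
    attributes(back) <- attributes(back)[c("names", "class")]
    expect_identical(back, net)
    unlink(f)
  }
})

test_that("single-field corruptions of a valid file are each rejected", {
  good <- c("# input PA 2", "PA\tactivate\tX\t1", "X\tinhibit\tY\t0")
  bad <- list(
    sign_typo   = sub("activate", "activates", good),
    neg_delay   = sub("X\t1", "X\t-1", good),
    frac_delay  = sub("X\t1", "X\t1.5", good),
    word_delay  = sub("X\t1", "X\tslow", good),
    two_fields  = sub("X\tinhibit\tY\t0", "X\tinhibit", good),
    clamp_nolvl = c("# clamp PP1", good),
    dup_edge    = c(good, "PA\tactivate\tX\t3")
  )
  for (nm in names(bad)) {
    f <- tempfile()
    writeLines(bad[[nm]], f)
    expect_error(parse_network(f), info = nm)
    unlink(f)
  }
})

test_that("validation enforces role/level and edge invariants", {
  expect_error(network_spec(edge_df("A", "activate", "B"),
                            inputs = c(A = 3)), "0:2")
  expect_error(network_spec(edge_df(c("A", "A"), "activate", c("B", "B"))),
               "duplicate")
  # opposite-sign pair between the same nodes is legal (delayed attenuation)
  net <- network_spec(edge_df(c("A", "A"), c("activate", "inhibit"),
                              c("B", "B"), c(0L, 5L)))
  expect_equal(nrow(net$edges), 2L)
  # hand-tampered objects are caught
  net$nodes$clamp_level[net$nodes$name == "B"] <- 2L
  expect_error(validate_network(net), "ordinary")
})

test_that("comments are preserved on read but not written", {
  f <- withr::local_tempfile()
  writeLines(c("# a free comment", "# input PA 2", "PA\tactivate\tX"), f)
  net <- parse_network(f)
  expect_equal(attr(net, "comments"), "# a free comment")
  f2 <- withr::local_tempfile()
  write_network(net, f2)
  expect_false(any(grepl("free comment", readLines(f2))))
})

test_that("set_input changes input levels and refuses other roles", {
  net <- network_spec(edge_df("PA", "activate", "X"), inputs = c(PA = 2))
  expect_equal(set_input(net, "PA", 0)$nodes$clamp_level[1], 0L)
  expect_error(set_input(net, "X", 2), "not an input")
  expect_error(set_input(net, "PA", 5), "0:2")
})
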