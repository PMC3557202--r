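test_that("bundled model files match their programmatic reconstruction", {
  for (v in palmitate_versions()) {
    shipped <- palmitate_model(v)
    attributes(shipped) <- attributes(shipped)[c("names", "class")]
    built <- trinet:::.build_version(v)
    expect_identical(shipped, built, info = v)
  }
})

test_that("the version ladder differs by the documented refinements", {
  v1 <- palmitate_model("v1_literature")
  v2 <- palmitate_model("v2_delays")
  # same interactions, only delays differ
  expect_identical(v1$edges[c("source", "sign", "target")],
                   v2$edges[c("source", "sign", "target")])
  expect_identical(v1$nodes, v2$nodes)
  changed <- v1$edges$delay != v2$edges$delay
  expect_equal(sum(changed), 6L)
  # v3 additionally clamps PP1 at control
  v3 <- palmitate_model("v3_pp1_const")
  expect_identical(v3$edges, v2$edges)
  expect_equal(v3$nodes$role[v3$nodes$name == "PP1"], "clamped")
  expect_equal(v3$nodes$clamp_level[v3$nodes$name == "PP1"], 1L)
  # the feedback variants add exactly one transcriptional edge each
  for (v in c("v4_feedback_creb1", "v4_feedback_atf4")) {
    v4 <- palmitate_model(v)
    extra <- setdiff(do.call(paste, v4$edges), do.call(paste, v3$edges))
    expect_length(extra, 1)
    expect_match(extra, "ATF4 2$")
  }
  # the essential model has no phosphatase branch
  v5 <- palmitate_model("v5_essential")
  expect_false(any(c("GADD34", "PP1", "PP2A") %in% v5$nodes$name))
  expect_false(any(v5$edges$source %in% c("p38", "Ras") &
                   v5$edges$target == "CREB1"))
})

test_that("trajectory classification separates the four response classes", {
  flat <- rep(1, 41)
  expect_equal(classify_trajectory(flat)$label, "unchanged")
  up_then_down <- c(seq(1, 1.8, length.out = 6), seq(1.8, 0.95, length.out = 35))
  tl <- classify_trajectory(up_then_down)
  expect_equal(tl$label, "transient")
  expect_true(tl$elevated)
  up_hold <- c(seq(1, 1.9, length.out = 6), rep(1.9, 35))
  expect_equal(classify_trajectory(up_hold)$label, "sustained")
  down <- c(seq(1, 0.3, length.out = 41))
  tl2 <- classify_trajectory(down)
  expect_equal(tl2$label, "suppressed")
  expect_false(tl2$elevated)
  expect_equal(tl2$peak_step, 40L)
  expect_error(classify_trajectory(rep(1, 4)), "too short")
  # exactly one label under any series (mutual exclusivity)
  set.seed(7)
  for (i in 1:30) {
    s <- pmin(2, pmax(0, 1 + cumsum(rnorm(41, 0, 0.15))))
    expect_true(classify_trajectory(s)$label %in%
                c("unchanged", "transient", "sustained", "suppressed"))
  }
})

test_that("a reduced-size figure suite reproduces every expected label", {
  out <- withr::local_tempdir()
  rep <- run_figure_suite(out_dir = out, n_runs = 250, horizon = 40,
                          master_seed = 2)
  expect_true(all(rep$checks$pass))
  expect_true(rep$knockout$ok)
  expect_true(rep$ok)
  expect_true(file.exists(file.path(out, "suite_report.json")))
  js <- jsonlite::read_json(file.path(out, "suite_report.json"))
  expect_true(isTRUE(js$ok))
  expect_true(file.exists(file.path(out, "fig4b_delays.tsv")))
  # step <-> time calibration is reporting metadata only
  expect_equal(rep$steps_per_hour, 10 / 6)
})
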