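test_that("build_design enumerates the full 3x2x2 factorial once, in canonical order", {
  d <- build_design()
  expect_equal(nrow(d), 12L)
  expect_equal(anyDuplicated(d$cell), 0L)
  expect_equal(as.vector(table(d$content)), rep(4L, 3))
  expect_equal(as.vector(table(d$source)), rep(6L, 2))
  expect_equal(as.vector(table(d$incentive)), rep(6L, 2))
  # canonical order: content slowest, incentive fastest
  expect_equal(d$cell[1], "combat:oef_list:usd20")
  expect_equal(d$cell[2], "combat:oef_list:usd40")
  expect_equal(d$cell[12], "lifetime:claims_list:usd40")
})

test_that("cell keys serialize and parse stably", {
  d <- build_design()
  back <- parse_cell_key(d$cell)
  expect_equal(back$content, d$content)
  expect_equal(back$source, d$source)
  expect_equal(back$incentive, d$incentive)
  expect_error(parse_cell_key("combat:oef_list"), "malformed")
  expect_error(parse_cell_key("combat:oef_list:usd25"), "unknown factor level")
})

test_that("blocked randomization partitions each block into equal cells", {
  frame <- tiny_frame(n_cell = 40L)  # 480 per block, the trial's dimensions
  plan <- randomize_blocked(frame, seed = 20160201)
  tab <- table(plan$block, plan$cell)
  expect_equal(dim(tab), c(2L, 12L))
  expect_true(all(tab == 40L))
  # partition: every subject exactly once
  expect_setequal(plan$subject_id, frame$subject_id)
  expect_equal(anyDuplicated(plan$subject_id), 0L)
})

test_that("randomization is deterministic per seed and varies across seeds", {
  frame <- tiny_frame(n_cell = 2L)
  p1 <- randomize_blocked(frame, seed = 11)
  p2 <- randomize_blocked(frame, seed = 11)
  p3 <- randomize_blocked(frame, seed = 12)
  expect_identical(p1, p2)
  expect_false(identical(p1$cell[order(p1$subject_id)],
                         p3$cell[order(p3$subject_id)]))
})

test_that("minimal block of 12 gets one subject per cell and bad sizes error", {
  frame <- tiny_frame(n_cell = 1L, blocks = "men")
  plan <- randomize_blocked(frame, seed = 3)
  expect_true(all(table(plan$cell) == 1L))
  bad <- data.frame(subject_id = sprintf("B%02d", 1:13), block = "men")
  expect_error(randomize_blocked(bad, seed = 1), "invalid design")
})

test_that("over many seeds each subject lands in every cell uniformly", {
  frame <- tiny_frame(n_cell = 1L, blocks = "men")
  cells <- build_design()$cell
  picks <- vapply(1:600, function(s) {
    plan <- randomize_blocked(frame, seed = s)
    plan$cell[plan$subject_id == "T0001"]
  }, character(1))
  counts <- table(factor(picks, levels = cells))
  gof <- stats::chisq.test(counts)
  expect_gt(gof$p.value, 0.001)
})
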