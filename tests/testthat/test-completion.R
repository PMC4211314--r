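test_that("a unique consistent route reconstructs the original", {
  net <- hypernetwork(4, topology = "line")
  cfg <- edge_config("fixed", k = 2)
  encode(net, c("1", "2", "3", "4"), cfg)
  r <- complete_pattern(net, c("1", "2", NA, "4"), cfg,
                        truth = c("1", "2", "3", "4"))
  expect_true(r$complete)
  expect_true(r$expected)
  expect_equal(r$n_completions, 1L)
  expect_equal(unname(r$completions[[1]][1, ]), c("1", "2", "3", "4"))
})

test_that("recombined chains yield all consistent completions", {
  net <- hypernetwork(4, topology = "line")
  cfg <- edge_config("fixed", k = 2)
  encode(net, c("1", "2", "3", "4"), cfg)
  encode(net, c("5", "2", "3", "6"), cfg)
  r <- complete_pattern(net, c("1", "2", "3", NA), cfg,
                        truth = c("1", "2", "3", "4"))
  expect_true(r$complete)
  expect_true(r$expected)
  comp <- r$completions[[1]]
  expect_equal(nrow(comp), 2L)
  expect_setequal(apply(comp, 1, paste, collapse = ","),
                  c("1,2,3,4", "1,2,3,6"))
})

test_that("an observed value never encoded blocks completion", {
  net <- hypernetwork(4, topology = "line")
  cfg <- edge_config("fixed", k = 2)
  encode(net, c("1", "2", "3", "4"), cfg)
  r <- complete_pattern(net, c("9", "2", NA, "4"), cfg)
  expect_false(r$complete)
  expect_equal(r$n_completions, 0L)
})

test_that("completion validates the probe shape", {
  net <- hypernetwork(4)
  cfg <- edge_config("fixed", k = 2)
  encode(net, c("1", "2", "3", "4"), cfg)
  expect_error(complete_pattern(net, c("1", "2", "3", "4"), cfg),
               "missing value")
  expect_error(complete_pattern(net, rep(NA_character_, 4), cfg),
               "observed value")
})

test_that("completions agree with the probe and are themselves judged old", {
  set.seed(55)
  cfg <- edge_config("fixed", k = 2)
  for (case in 1:20) {
    d <- sample(4:6, 1)
    net <- hypernetwork(d)
    stream <- random_instances(sample.int(8, 1), d)
    encode(net, stream, cfg)
    probe <- unlist(random_instances(1, d))
    miss <- sample.int(d, sample.int(d - 1, 1))
    partial <- replace(probe, miss, NA)
    r <- complete_pattern(net, partial, cfg)
    if (r$n_completions == 0L) next
    comp <- r$completions[[1]]
    for (row in seq_len(nrow(comp))) {
      full <- comp[row, ]
      expect_identical(unname(full[-miss]), unname(probe[-miss]))
      expect_true(judge(net, full, cfg)$old)
    }
  }
})

test_that("the existence-only flags agree with full enumeration", {
  set.seed(66)
  for (case in 1:30) {
    d <- sample(4:6, 1)
    cfg_list <- list(edge_config("fixed", k = 2),
                     edge_config("random_order", order_range = c(2, 3)))
    cfg <- cfg_list[[sample.int(2, 1)]]
    net <- hypernetwork(d)
    encode(net, random_instances(sample.int(10, 1), d), cfg)
    truth <- unlist(random_instances(1, d))
    miss <- sample.int(d, sample.int(d - 1, 1))
    partial <- replace(truth, miss, NA)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    full <- complete_pattern(net, partial, cfg, truth = truth)
    codes_t <- hypermem:::code_instance(net, truth)
    codes_p <- hypermem:::code_instance(net, partial)
    cc <- hypermem:::config_code(cfg)
    set.seed(seed)
    flags <- hypermem:::hn_complete_flags(net$ptr, codes_p, cc[1], cc[2],
                                          cc[2], cc[3], 0L, 10000L, codes_t)
    expect_identical(flags$complete, full$complete)
    expect_identical(flags$expected, as.logical(full$expected))
  }
})

test_that("an evidence-free probe edge does not veto completion at low fixed order", {
  # d = 4, k = 2, mask two adjacent attributes: the probe edge covering both
  # carries no evidence; the route is still completed from memory
  net <- hypernetwork(4)
  cfg <- edge_config("fixed", k = 2)
  encode(net, c("1", "2", "3", "4"), cfg)
  r <- complete_pattern(net, c("1", NA, NA, "4"), cfg,
                        truth = c("1", "2", "3", "4"))
  expect_true(r$complete)
  expect_true(r$expected)
})
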