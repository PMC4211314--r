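test_that("a single repeated instance is new once and old ever after", {
  st <- tibble::tibble(a = rep("x", 10), b = rep("y", 10),
                       c = rep("z", 10), d = rep("w", 10))
  res <- incremental_judgment(st, edge_config("fixed", k = 2),
                              section_size = 5, seed = 1)
  expect_identical(res$events$old, c(FALSE, rep(TRUE, 9)))
  expect_identical(res$events$truth, c(FALSE, rep(TRUE, 9)))
  expect_equal(sum(res$sections$misses), 0L)
  expect_equal(sum(res$sections$false_alarms), 0L)
  expect_equal(res$sections$hit_rate[2], 1)
})

test_that("pairwise-orthogonal instances are all judged new", {
  # no two events share any value, so nothing ever activates across events
  st <- tibble::tibble(a = paste0("a", 1:12), b = paste0("b", 1:12),
                       c = paste0("c", 1:12), d = paste0("d", 1:12))
  res <- incremental_judgment(st, edge_config("fixed", k = 2),
                              section_size = 6, seed = 1)
  expect_false(any(res$events$old))
  expect_equal(sum(res$sections$false_alarms), 0L)
})

test_that("judge-then-encode: a probe never sees its own trace", {
  set.seed(31)
  st <- random_instances(25, 5, alphabet = 3)
  cfg <- edge_config("fixed", k = 2)  # deterministic sampling
  res <- incremental_judgment(st, cfg, section_size = 25, seed = 1)
  # two-pass reference: judge event i against a fresh network of events < i
  for (i in c(1, 7, 19, 25)) {
    ref <- hypernetwork(5)
    if (i > 1) encode(ref, st[seq_len(i - 1), ], cfg)
    expect_identical(res$events$old[i], judge(ref, st[i, ], cfg)$old)
  }
})

test_that("experiments are bit-reproducible under a seed", {
  st <- small_stream(150, seed = 9)
  cfg <- edge_config("random_order", order_range = c(2, 4))
  a <- incremental_judgment(st, cfg, section_size = 50, seed = 5)
  b <- incremental_judgment(st, cfg, section_size = 50, seed = 5)
  expect_identical(a$events, b$events)
  ca <- completion_experiment(st, cfg, n_missing = 3, seed = 5)
  cb <- completion_experiment(st, cfg, n_missing = 3, seed = 5)
  expect_identical(ca$events, cb$events)
})

test_that("miss counts are identically zero across harnesses", {
  st <- small_stream(200, seed = 17)
  for (cfg in list(edge_config("fixed", k = 3),
                   edge_config("random_order", order_range = c(2, 5)))) {
    res <- incremental_judgment(st, cfg, section_size = 100, seed = 2)
    expect_equal(sum(res$sections$misses), 0L)
  }
})

test_that("fixed-mode repetition multiplies counts but changes nothing else", {
  st <- random_instances(15, 5, alphabet = 3)
  cfg1 <- edge_config("fixed", k = 2, repetitions = 1)
  cfg5 <- edge_config("fixed", k = 2, repetitions = 5)
  n1 <- hypernetwork(5); encode(n1, st, cfg1)
  n5 <- hypernetwork(5); encode(n5, st, cfg5)
  expect_equal(tidy(n1), tidy(n5))
  l1 <- network_links(n1); l5 <- network_links(n5)
  expect_equal(l5$count, 5L * l1$count)
  probes <- random_instances(20, 5, alphabet = 3)
  expect_identical(judge(n1, probes, cfg1)$old, judge(n5, probes, cfg5)$old)
})

test_that("the sweep table reports scale, judgment and completion per configuration", {
  st <- small_stream(150, seed = 3)
  cfgs <- list(k2 = edge_config("fixed", k = 2),
               k4 = edge_config("fixed", k = 4),
               ro = edge_config("random_order", order_range = c(2, 4)))
  res <- configuration_sweep(st, cfgs, n_missing = 3, seed = 1)
  expect_equal(res$config, c("k2", "k4", "ro"))
  expect_true(all(res$n_edges > 0))
  expect_equal(res$n_links / res$n_edges, res$connectivity)
  expect_true(all(res$hit_rate == 1))
  expect_true(res$n_edges[1] < res$n_edges[2])          # scale grows with k
  expect_true(res$connectivity[1] > res$connectivity[2]) # density falls with k
  expect_true(all(res$completeness_rate >= res$expectation_rate))
})

test_that("the default configuration grid has the 13 reference categories", {
  grid <- default_config_grid(8)
  expect_length(grid, 13L)
  expect_equal(sum(vapply(grid, function(g) g$mode == "fixed", logical(1))), 6L)
})

test_that("observation count changes judgment only: completions and memory are untouched", {
  st <- small_stream(150, seed = 21)
  cfg <- edge_config("random_order", order_range = c(2, 3))
  res <- study_duration_experiment(st, cfg, encodings = 1L,
                                   observations = c(1L, 5L),
                                   n_missing = 3, seed = 4)
  expect_equal(res$completeness_rate[1], res$completeness_rate[2])
  expect_equal(res$expectation_rate[1], res$expectation_rate[2])
  expect_equal(res$n_edges[1], res$n_edges[2])
  expect_equal(res$n_links[1], res$n_links[2])
  expect_lte(res$fa_rate[res$observations == 5],
             res$fa_rate[res$observations == 1])
  expect_true(all(res$hit_rate == 1))
})

test_that("repeated random-order encodings enrich the memory", {
  st <- small_stream(150, seed = 23)
  cfg <- edge_config("random_order", order_range = c(2, 3))
  res <- study_duration_experiment(st, cfg, encodings = c(1L, 5L),
                                   observations = 1L, n_missing = 3, seed = 4)
  expect_gt(res$connectivity[res$encodings == 5],
            res$connectivity[res$encodings == 1])
  expect_gt(res$n_edges[res$encodings == 5], res$n_edges[res$encodings == 1])
})

test_that("a unit update interval makes offline identical to online", {
  st <- small_stream(120, seed = 6)
  cfg <- edge_config("random_order", order_range = c(2, 3))
  res <- online_offline_expectation(st, cfg, update_interval = 1,
                                    n_missing = 3, seed = 2)
  on <- res$events[res$events$variant == "online", ]
  off <- res$events[res$events$variant == "offline", ]
  expect_identical(on$expected, off$expected)
  expect_equal(res$final_online, res$final_offline)
})

test_that("on a stationary repeating stream the update-policy gap shrinks", {
  # without drift the offline lag carries no lasting penalty: the cumulative
  # expectation gap narrows as the frozen blocks catch up
  st <- small_stream(800, seed = 13, drift_strength = Inf,
                     novelty_schedule = 0)
  cfg <- edge_config("random_order", order_range = c(2, 3))
  res <- online_offline_expectation(st, cfg, update_interval = 200,
                                    n_missing = 3, seed = 2)
  expect_gte(res$final_online, res$final_offline)
  ev <- res$events
  gap <- abs(ev$cum_expectation[ev$variant == "online"] -
             ev$cum_expectation[ev$variant == "offline"])
  expect_lt(gap[800], gap[200] / 2)
})
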