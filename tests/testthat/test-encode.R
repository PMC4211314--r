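test_that("one instance in an empty ring yields d edges and d unit links", {
  net <- hypernetwork(4)
  rep1 <- encode(net, c("1", "2", "3", "4"), edge_config("fixed", k = 2))
  expect_equal(rep1$new_edges, 4L)
  expect_equal(rep1$new_links, 4L)
  lk <- network_links(net)
  expect_equal(nrow(lk), 4L)
  expect_true(all(lk$count == 1L))
  expect_equal(connectivity(net), 1)
})

test_that("re-encoding accumulates counts without creating edges", {
  net <- hypernetwork(4)
  cfg <- edge_config("fixed", k = 2)
  encode(net, c("1", "2", "3", "4"), cfg)
  rep2 <- encode(net, c("1", "2", "3", "4"), cfg)
  expect_equal(rep2$new_edges, 0L)
  expect_equal(rep2$new_links, 0L)
  expect_true(all(network_links(net)$count == 2L))
})

test_that("encoding refuses incomplete instances and wrong dimensions", {
  net <- hypernetwork(4)
  cfg <- edge_config("fixed", k = 2)
  expect_error(encode(net, c("1", NA, "3", "4"), cfg), "missing")
  expect_error(encode(net, c("1", "2", "3"), cfg), "does not match")
})

test_that("the store only grows: edges and per-link counts are monotone", {
  set.seed(5)
  net <- hypernetwork(5)
  cfg <- edge_config("random_order", order_range = c(2, 3))
  prev_edges <- 0
  prev_counts <- integer(0)
  for (i in 1:30) {
    encode(net, random_instances(1, 5), cfg)
    g <- glance(net)
    expect_gte(g$n_edges, prev_edges)
    lk <- network_links(net)
    counts <- setNames(lk$count, paste(lk$from, lk$to))
    old_names <- names(prev_counts)
    expect_true(all(counts[old_names] >= prev_counts))
    prev_edges <- g$n_edges
    prev_counts <- counts
  }
})

test_that("random-order repetition enriches memory as the draw enumeration predicts", {
  # one instance, orders in {2, 3} per anchor per pass, 5 passes, d = 8 ring:
  # each anchor contributes E[#distinct orders seen] = 2 - 2 * (1/2)^5
  # distinct edges, so the expected total is 8 * (2 - 2/32) = 15.5 > 8
  expected <- 8 * (2 - 2 * (1 / 2)^5)
  x <- as.character(1:8)
  cfg <- edge_config("random_order", order_range = c(2, 3), repetitions = 5)
  set.seed(19)
  totals <- replicate(300, {
    net <- hypernetwork(8)
    encode(net, x, cfg)
    glance(net)$n_edges
  })
  expect_gt(mean(totals), 8)
  expect_lt(abs(mean(totals) - expected), 0.5)
})

test_that("stored edges never exceed the capacity bound of the observed alphabets", {
  set.seed(3)
  for (k in c(2, 3)) {
    net <- hypernetwork(4)
    events <- random_instances(40, 4)
    encode(net, events, edge_config("fixed", k = k))
    alphabets <- vapply(events, function(col) length(unique(col)), integer(1))
    bound <- capacity_bound(alphabets, k = k)$edge_bound
    expect_lte(glance(net)$n_edges, bound)
  }
})

test_that("fixed-mode encoding is deterministic; random modes reproduce under a seed", {
  events <- random_instances(20, 5)
  cfg_f <- edge_config("fixed", k = 3)
  n1 <- hypernetwork(5); encode(n1, events, cfg_f)
  n2 <- hypernetwork(5); encode(n2, events, cfg_f)
  expect_identical(network_digest(n1), network_digest(n2))

  cfg_r <- edge_config("random_order", order_range = c(2, 4))
  n3 <- hypernetwork(5); set.seed(99); encode(n3, events, cfg_r)
  n4 <- hypernetwork(5); set.seed(99); encode(n4, events, cfg_r)
  expect_identical(network_digest(n3), network_digest(n4))
})

test_that("connectivity equals links per edge and falls with the fixed order", {
  set.seed(21)
  diffs <- replicate(10, {
    stream <- random_instances(100, 8, alphabet = 5)
    conn <- vapply(c(2L, 6L), function(k) {
      net <- hypernetwork(8)
      encode(net, stream, edge_config("fixed", k = k))
      g <- glance(net)
      expect_equal(g$connectivity, g$n_links / g$n_edges)
      g$connectivity
    }, numeric(1))
    conn[1] - conn[2]
  })
  expect_true(all(diffs > 0))
})
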