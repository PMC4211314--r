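# Experiment harnesses. All of them follow the judge-then-encode protocol:
# each event is probed against the memory built from strictly earlier events
# before being encoded itself, so a probe never sees its own trace.
#
# Reproducibility uses per-event sub-seeds drawn once from the experiment
# seed, with separate sub-streams for masking/completion, judgment, and
# encoding. This makes runs bit-reproducible and lets paired settings (e.g.
# 1 vs 5 observations) share identical masks and encoding draws, so a
# manipulation affects only the stage it belongs to.

new_subseeds <- function(seed, n, streams = 3L) {
  set.seed(seed)
  bases <- sample.int(2147483646L, streams)
  lapply(bases, function(b) {
    set.seed(b)
    sample.int(2147483646L, n)
  })
}

judge_coded <- function(ptr, v, cc, observations, n_m, max_routes) {
  old <- TRUE; s <- 0
  for (obs in seq_len(observations)) {
    r <- hn_judge(ptr, v, cc[1], cc[2], cc[2], cc[3], n_m, max_routes, FALSE)
    old <- old && r$old
    s <- max(s, r$similarity)
  }
  list(old = old, similarity = s)
}

stream_network <- function(stream, topology, C) {
  nm <- names(stream)[!startsWith(names(stream), ".")]
  hypernetwork(nm, topology = topology, C = C)
}

section_summary <- function(events) {
  grouped <- dplyr::group_by(events, .data$section)
  out <- dplyr::group_modify(grouped, function(x, key) {
    cc <- confusion_counts(x$old, x$truth)
    cc$auc <- tryCatch(roc_curve(x$similarity, x$truth)$auc,
                       error = function(e) NA_real_)
    cc$n <- nrow(x)
    cc
  })
  dplyr::ungroup(out)
}

#' Incremental judge-then-encode experiment
#'
#' Feeds a complete event stream through the memory in order: each event is
#' judged old/new against the memory of all earlier events, then encoded.
#' Performance is aggregated over consecutive sections of `section_size`
#' events, so the first section is judged against an initially (almost)
#' empty memory and later sections against an ever larger store — the
#' temporal-consistency view of lifelong learning.
#'
#' @param stream Data frame of complete events (attribute columns plus
#'   optional dot-prefixed metadata).
#' @param config An [edge_config()].
#' @param section_size Events per evaluation section.
#' @param topology,C Passed to [hypernetwork()].
#' @param n_m,max_routes Passed to the judgment core; see [judge()].
#' @param observations Repeated judgments per probe (default from `config`).
#' @param seed Experiment seed (bit-reproducible runs).
#' @return An `hm_incremental` object: list with `events` (per-event tibble:
#'   `.event`, `section`, `truth`, `old`, `similarity`), `sections`
#'   (per-section confusion counts, rates and AUC) and the final `network`.
#' @export
incremental_judgment <- function(stream, config, section_size = 1000,
                                 topology = c("ring", "line"), C = 10,
                                 n_m = 0L, max_routes = 10000L,
                                 observations = NULL, seed = 1L) {
  topology <- match.arg(topology)
  if (section_size < 1) stop("`section_size` must be >= 1", call. = FALSE)
  net <- stream_network(stream, topology, C)
  validate_config(config, net$d)
  if (is.null(observations)) observations <- config$observations
  m <- instance_matrix(net, stream)
  if (anyNA(m)) stop("stream must be complete", call. = FALSE)
  codes <- code_matrix(net, m, register = TRUE)
  truth <- truth_labels(stream)
  cc <- config_code(config)
  n <- nrow(codes)
  seeds <- new_subseeds(seed, n)
  old <- logical(n); sim <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seeds[[2]][i])
    r <- judge_coded(net$ptr, codes[i, ], cc, observations, n_m, max_routes)
    old[i] <- r$old; sim[i] <- r$similarity
    set.seed(seeds[[3]][i])
    hn_encode(net$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
              config$repetitions)
  }
  events <- tibble::tibble(
    .event = seq_len(n),
    section = (seq_len(n) - 1L) %/% as.integer(section_size) + 1L,
    truth = truth, old = old, similarity = sim
  )
  structure(list(events = events, sections = section_summary(events),
                 network = net, config = config, seed = seed),
            class = "hm_incremental")
}

#' @export
print.hm_incremental <- function(x, ...) {
  cat("<hm_incremental> ", nrow(x$events), " events in ",
      nrow(x$sections), " sections\n", sep = "")
  print(x$sections)
  invisible(x)
}

#' @method tidy hm_incremental
#' @export
tidy.hm_incremental <- function(x, ...) x$events

#' @method glance hm_incremental
#' @export
glance.hm_incremental <- function(x, ...) {
  dplyr::bind_cols(
    confusion_counts(x$events$old, x$events$truth),
    tibble::tibble(
      auc = tryCatch(roc_curve(x$events$similarity, x$events$truth)$auc,
                     error = function(e) NA_real_),
      connectivity = connectivity(x$network))
  )
}

#' @method autoplot hm_incremental
#' @export
autoplot.hm_incremental <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$sections[c("section", "hit_rate", "fa_rate", "auc")],
    -"section", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$section, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "section", y = NULL,
                  title = "Judgment performance per section") +
    ggplot2::theme_minimal()
}

#' Pattern-completion experiment over a stream
#'
#' For each event, `n_missing` uniformly chosen attributes are masked, the
#' partial probe is completed against the memory of all earlier events, and
#' the full event is then encoded (judge-then-encode order). Two rates
#' summarise performance: *completeness* (a fully linked completion exists)
#' and *expectation* (the original event is among the completions).
#'
#' @inheritParams incremental_judgment
#' @param n_missing Number of attributes masked per probe, in `[1, d - 1]`.
#' @return An `hm_completion` object: list with `events` (per-event
#'   `complete`/`expected` flags), the final `network`, and the two rates.
#' @export
completion_experiment <- function(stream, config, n_missing = 3,
                                  topology = c("ring", "line"), C = 10,
                                  n_m = 0L, max_routes = 10000L, seed = 1L) {
  topology <- match.arg(topology)
  net <- stream_network(stream, topology, C)
  validate_config(config, net$d)
  if (n_missing < 1 || n_missing > net$d - 1)
    stop("`n_missing` must lie in [1, d-1]", call. = FALSE)
  m <- instance_matrix(net, stream)
  if (anyNA(m)) stop("stream must be complete", call. = FALSE)
  codes <- code_matrix(net, m, register = TRUE)
  cc <- config_code(config)
  n <- nrow(codes)
  seeds <- new_subseeds(seed, n)
  complete <- logical(n); expected <- logical(n)
  for (i in seq_len(n)) {
    set.seed(seeds[[1]][i])
    v <- codes[i, ]
    v[sample.int(net$d, n_missing)] <- NA_integer_
    r <- hn_complete_flags(net$ptr, v, cc[1], cc[2], cc[2], cc[3], n_m,
                           max_routes, codes[i, ])
    complete[i] <- r$complete
    expected[i] <- r$expected
    set.seed(seeds[[3]][i])
    hn_encode(net$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
              config$repetitions)
  }
  events <- tibble::tibble(.event = seq_len(n), complete = complete,
                           expected = expected)
  structure(list(events = events, network = net, config = config,
                 n_missing = n_missing,
                 completeness_rate = mean(complete),
                 expectation_rate = mean(expected), seed = seed),
            class = "hm_completion")
}

#' @export
print.hm_completion <- function(x, ...) {
  cat("<hm_completion> ", nrow(x$events), " probes, ", x$n_missing,
      " masked: completeness = ", signif(x$completeness_rate, 4),
      ", expectation = ", signif(x$expectation_rate, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy hm_completion
#' @export
tidy.hm_completion <- function(x, ...) x$events

#' @method glance hm_completion
#' @export
glance.hm_completion <- function(x, ...)
  tibble::tibble(completeness_rate = x$completeness_rate,
                 expectation_rate = x$expectation_rate,
                 n = nrow(x$events), connectivity = connectivity(x$network))

#' Default grid of 13 edge configurations
#'
#' A reconstruction of a representative sweep over the three edge families:
#' fixed orders `k = 2..min(7, d-1)`, random orders `(2,3) (2,4) (2,5)
#' (2,6)`, and random combinations `(2,4) (2,6) (2,d-1)` (ranges clipped to
#' `d - 1`). For `d = 8` this yields 13 categories.
#'
#' @param d Attribute dimension.
#' @return A named list of [edge_config()] objects.
#' @export
default_config_grid <- function(d = 8) {
  grid <- list()
  for (k in 2:min(7, d - 1))
    grid[[paste0("fixed_k", k)]] <- edge_config("fixed", k = k)
  for (r2 in c(3, 4, 5, 6)) {
    if (r2 > d - 1) next
    grid[[paste0("random_order_2_", r2)]] <-
      edge_config("random_order", order_range = c(2, r2))
  }
  for (r2 in unique(pmin(c(4, 6, d - 1), d - 1))) {
    grid[[paste0("random_comb_2_", r2)]] <-
      edge_config("random_combination", order_range = c(2, r2))
  }
  grid
}

#' Edge-configuration sweep
#'
#' Runs the full judge-then-encode protocol — familiarity judgment, pattern
#' completion of a masked copy, then encoding — once per edge configuration
#' on the same stream, with identical per-event masks and seeds across
#' configurations so that differences are attributable to the configuration
#' alone. Reports memory scale (edges, links, connectivity) together with
#' judgment (hit/false-alarm rates, AUC) and completion (completeness,
#' expectation) performance.
#'
#' @inheritParams completion_experiment
#' @param configs Named list of [edge_config()]s; defaults to
#'   [default_config_grid()].
#' @return A tibble with one row per configuration.
#' @export
configuration_sweep <- function(stream, configs = NULL, n_missing = 3,
                                topology = c("ring", "line"), C = 10,
                                n_m = 0L, max_routes = 10000L, seed = 1L) {
  topology <- match.arg(topology)
  d <- sum(!startsWith(names(stream), "."))
  if (is.null(configs)) configs <- default_config_grid(d)
  if (is.null(names(configs)) || any(names(configs) == ""))
    names(configs) <- paste0("config_", seq_along(configs))
  truth <- truth_labels(stream)
  rows <- lapply(names(configs), function(label) {
    config <- configs[[label]]
    net <- stream_network(stream, topology, C)
    validate_config(config, net$d)
    m <- instance_matrix(net, stream)
    codes <- code_matrix(net, m, register = TRUE)
    cc <- config_code(config)
    n <- nrow(codes)
    seeds <- new_subseeds(seed, n)
    old <- logical(n); sim <- numeric(n)
    complete <- logical(n); expected <- logical(n)
    for (i in seq_len(n)) {
      set.seed(seeds[[2]][i])
      r <- judge_coded(net$ptr, codes[i, ], cc, config$observations, n_m,
                       max_routes)
      old[i] <- r$old; sim[i] <- r$similarity
      set.seed(seeds[[1]][i])
      v <- codes[i, ]
      v[sample.int(net$d, n_missing)] <- NA_integer_
      comp <- hn_complete_flags(net$ptr, v, cc[1], cc[2], cc[2], cc[3], n_m,
                                max_routes, codes[i, ])
      complete[i] <- comp$complete
      expected[i] <- comp$expected
      set.seed(seeds[[3]][i])
      hn_encode(net$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
                config$repetitions)
    }
    info <- glance(net)
    mode_chr <- config$mode
    rng <- config$order_range
    dplyr::bind_cols(
      tibble::tibble(config = label, mode = mode_chr,
                     r1 = rng[1], r2 = rng[2]),
      info[c("n_edges", "n_links", "connectivity")],
      confusion_counts(old, truth)[c("hit_rate", "fa_rate")],
      tibble::tibble(
        auc = tryCatch(roc_curve(sim, truth)$auc, error = function(e) NA_real_),
        completeness_rate = mean(complete),
        expectation_rate = mean(expected))
    )
  })
  dplyr::bind_rows(rows)
}

#' Study-duration experiment
#'
#' Varies the two sides of study duration independently on the same stream:
#' `encodings` (sampling passes per encoded instance — enriches a
#' random-edge memory) and `observations` (repeated judgments per probe —
#' tightens verdicts via the unanimity rule). Masks, completion draws and
#' encoding draws use matched per-event sub-seeds across settings, so
#' changing `observations` leaves the encoded memory and the completion
#' results bit-identical, isolating its effect on judgment.
#'
#' @inheritParams completion_experiment
#' @param encodings Integer vector of repetition counts to test.
#' @param observations Integer vector of observation counts to test.
#' @return A tibble with one row per (encodings, observations) setting:
#'   memory scale, judgment and completion metrics.
#' @export
study_duration_experiment <- function(stream, config, encodings = c(1L, 5L),
                                      observations = c(1L, 5L), n_missing = 3,
                                      topology = c("ring", "line"), C = 10,
                                      n_m = 0L, max_routes = 10000L,
                                      seed = 1L) {
  topology <- match.arg(topology)
  truth <- truth_labels(stream)
  grid <- expand.grid(encodings = as.integer(encodings),
                      observations = as.integer(observations))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    enc <- grid$encodings[g]; obs <- grid$observations[g]
    net <- stream_network(stream, topology, C)
    validate_config(config, net$d)
    m <- instance_matrix(net, stream)
    codes <- code_matrix(net, m, register = TRUE)
    cc <- config_code(config)
    n <- nrow(codes)
    seeds <- new_subseeds(seed, n)
    old <- logical(n); sim <- numeric(n)
    complete <- logical(n); expected <- logical(n)
    for (i in seq_len(n)) {
      set.seed(seeds[[1]][i])
      v <- codes[i, ]
      v[sample.int(net$d, n_missing)] <- NA_integer_
      comp <- hn_complete_flags(net$ptr, v, cc[1], cc[2], cc[2], cc[3], n_m,
                                max_routes, codes[i, ])
      complete[i] <- comp$complete
      expected[i] <- comp$expected
      set.seed(seeds[[2]][i])
      r <- judge_coded(net$ptr, codes[i, ], cc, obs, n_m, max_routes)
      old[i] <- r$old; sim[i] <- r$similarity
      set.seed(seeds[[3]][i])
      hn_encode(net$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3], enc)
    }
    info <- glance(net)
    dplyr::bind_cols(
      tibble::tibble(encodings = enc, observations = obs),
      info[c("n_edges", "n_links", "connectivity")],
      confusion_counts(old, truth)[c("hit_rate", "fa_rate")],
      tibble::tibble(
        auc = tryCatch(roc_curve(sim, truth)$auc, error = function(e) NA_real_),
        completeness_rate = mean(complete),
        expectation_rate = mean(expected))
    )
  })
  dplyr::bind_rows(rows)
}

#' Online versus offline expectation
#'
#' Compares two update policies for context expectation on the same stream.
#' Both mask `n_missing` attributes of each event and score whether pattern
#' completion recovers the original (the expectation flag). The *online*
#' memory encodes every event immediately after probing it; the *offline*
#' memory is frozen within each block of `update_interval` events and
#' batch-encodes the block only at its boundary, so probes inside a block
#' are completed against a stale store. Masks, probe sampling and encoding
#' draws are matched event-for-event across the two variants.
#'
#' @inheritParams completion_experiment
#' @param update_interval Block length of the offline variant (>= 1);
#'   `update_interval = 1` makes the two variants identical.
#' @return An `hm_expectation` object: list with `events` (per event and
#'   variant: `expected`, `cum_expectation`) and the final rates.
#' @export
online_offline_expectation <- function(stream, config, update_interval = 1000,
                                       n_missing = 3,
                                       topology = c("ring", "line"), C = 10,
                                       n_m = 0L, max_routes = 10000L,
                                       seed = 1L) {
  topology <- match.arg(topology)
  if (update_interval < 1) stop("`update_interval` must be >= 1", call. = FALSE)
  run_variant <- function(offline) {
    net <- stream_network(stream, topology, C)
    validate_config(config, net$d)
    if (n_missing < 1 || n_missing > net$d - 1)
      stop("`n_missing` must lie in [1, d-1]", call. = FALSE)
    m <- instance_matrix(net, stream)
    if (anyNA(m)) stop("stream must be complete", call. = FALSE)
    codes <- code_matrix(net, m, register = TRUE)
    cc <- config_code(config)
    n <- nrow(codes)
    seeds <- new_subseeds(seed, n)
    expected <- logical(n)
    pending <- integer(0)
    encode_i <- function(i) {
      set.seed(seeds[[3]][i])
      hn_encode(net$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
                config$repetitions)
    }
    for (i in seq_len(n)) {
      set.seed(seeds[[1]][i])
      v <- codes[i, ]
      v[sample.int(net$d, n_missing)] <- NA_integer_
      r <- hn_complete_flags(net$ptr, v, cc[1], cc[2], cc[2], cc[3], n_m,
                             max_routes, codes[i, ])
      expected[i] <- r$expected
      if (offline) {
        pending <- c(pending, i)
        if (i %% update_interval == 0L) {
          for (j in pending) encode_i(j)
          pending <- integer(0)
        }
      } else {
        encode_i(i)
      }
    }
    expected
  }
  on_exp <- run_variant(offline = FALSE)
  off_exp <- run_variant(offline = TRUE)
  n <- length(on_exp)
  events <- dplyr::bind_rows(
    tibble::tibble(.event = seq_len(n), variant = "online", expected = on_exp,
                   cum_expectation = cumsum(on_exp) / seq_len(n)),
    tibble::tibble(.event = seq_len(n), variant = "offline", expected = off_exp,
                   cum_expectation = cumsum(off_exp) / seq_len(n))
  )
  structure(list(events = events,
                 final_online = mean(on_exp), final_offline = mean(off_exp),
                 update_interval = update_interval, n_missing = n_missing,
                 config = config, seed = seed),
            class = "hm_expectation")
}

#' @export
print.hm_expectation <- function(x, ...) {
  cat("<hm_expectation> final expectation rate: online ",
      signif(100 * x$final_online, 3), "%, offline ",
      signif(100 * x$final_offline, 3), "% (interval ",
      x$update_interval, ")\n", sep = "")
  invisible(x)
}

#' @method tidy hm_expectation
#' @export
tidy.hm_expectation <- function(x, ...) x$events

#' @method glance hm_expectation
#' @export
glance.hm_expectation <- function(x, ...)
  tibble::tibble(final_online = x$final_online,
                 final_offline = x$final_offline,
                 update_interval = x$update_interval,
                 n_missing = x$n_missing)

#' @method autoplot hm_expectation
#' @export
autoplot.hm_expectation <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(.data$.event, .data$cum_expectation,
                               colour = .data$variant,
                               linetype = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "instances", y = "cumulative expectation rate",
                  title = "Online vs offline context expectation") +
    ggplot2::theme_minimal()
}
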