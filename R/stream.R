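#' Specification of a synthetic nonstationary event stream
#'
#' Describes a generative model for multivariate categorical event streams
#' with the three statistical signatures of long-horizon behavioural logs:
#' a cumulative old-instance ratio that grows towards roughly one third as
#' routines repeat, per-section drift of the attribute distributions, and
#' never-before-seen category tokens appearing mid-stream.
#'
#' The mechanism is section-wise: each of `n_sections` sections holds one
#' categorical distribution per attribute, re-drawn at every boundary from a
#' Dirichlet centred on the previous section's distribution with total
#' concentration `drift_strength` (larger = milder drift; `Inf` freezes the
#' distributions, making sections exchangeable). Each event is, with
#' probability `repeat_prob`, an exact replay of a past event drawn with
#' recency weighting `exp(-recency_decay * age)`; otherwise its attributes
#' are drawn independently from the current section's distributions. Fresh
#' events inject a brand-new token into one random attribute with the
#' per-event probability `novelty_schedule[section]`.
#'
#' The default dimension, alphabet sizes and length mirror an 8-attribute
#' phone-log stream (time of day, cell tower, place, application, contact,
#' call direction, call type, duration class) of about 7,000 events; the
#' default `repeat_prob` is calibrated so the cumulative old ratio at 7,000
#' events lands near one third.
#'
#' @param d Number of attributes.
#' @param category_counts Integer vector of initial alphabet sizes.
#' @param attribute_names Attribute names (defaults to phone-log style).
#' @param n Stream length.
#' @param n_sections Number of drift sections.
#' @param repeat_prob Per-event probability of replaying a past event.
#' @param novelty_schedule Per-section, per-event probability of introducing
#'   a novel token (length `n_sections`, recycled if shorter).
#' @param drift_strength Dirichlet concentration at section boundaries;
#'   `Inf` disables drift.
#' @param recency_decay Exponential decay rate of replay weights per event
#'   of age; 0 gives uniform replay over the history.
#' @param base_concentration Dirichlet parameter of the first section's
#'   distributions; values below 1 give the skewed, few-dominant-values
#'   shape typical of behavioural data.
#' @param seed Integer seed; every draw of [generate_stream()] is a pure
#'   function of the spec including this seed.
#' @return An object of class `stream_spec`.
#' @export
stream_spec <- function(d = 8,
                        category_counts = c(24, 30, 4, 20, 40, 2, 3, 10),
                        attribute_names = NULL,
                        n = 7000,
                        n_sections = 7,
                        repeat_prob = 0.3,
                        novelty_schedule = c(0, 0.001, 0.002, 0.008,
                                             0.003, 0.001, 0.001),
                        drift_strength = 50,
                        recency_decay = 0.002,
                        base_concentration = 0.5,
                        seed = 1L) {
  d <- as.integer(d)
  if (d < 2L) stop("`d` must be at least 2", call. = FALSE)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, d)
  if (length(category_counts) != d)
    stop("`category_counts` must have length d", call. = FALSE)
  if (any(category_counts < 2L))
    stop("each attribute needs at least 2 categories", call. = FALSE)
  if (is.null(attribute_names)) {
    default_names <- c("time", "location", "place", "application",
                       "contact", "direction", "call_type", "duration")
    attribute_names <- if (d <= 8L) default_names[seq_len(d)]
                       else paste0("a", seq_len(d))
  }
  if (length(attribute_names) != d)
    stop("`attribute_names` must have length d", call. = FALSE)
  if (repeat_prob < 0 || repeat_prob > 1)
    stop("`repeat_prob` must lie in [0, 1]", call. = FALSE)
  n_sections <- as.integer(n_sections)
  novelty_schedule <- rep_len(novelty_schedule, n_sections)
  if (any(novelty_schedule < 0 | novelty_schedule > 1))
    stop("`novelty_schedule` entries must lie in [0, 1]", call. = FALSE)
  if (n < 1L) stop("`n` must be positive", call. = FALSE)
  structure(
    list(d = d, category_counts = as.integer(category_counts),
         attribute_names = attribute_names, n = as.integer(n),
         n_sections = n_sections, repeat_prob = repeat_prob,
         novelty_schedule = novelty_schedule,
         drift_strength = drift_strength, recency_decay = recency_decay,
         base_concentration = base_concentration, seed = as.integer(seed)),
    class = "stream_spec"
  )
}

#' @export
print.stream_spec <- function(x, ...) {
  cat("<stream_spec> d = ", x$d, ", n = ", x$n, " in ", x$n_sections,
      " sections, repeat_prob = ", x$repeat_prob,
      ", drift_strength = ", x$drift_strength, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[] <- 1
  g / sum(g)
}

#' Generate a synthetic nonstationary event stream
#'
#' Draws the event stream described by a [stream_spec()]. The output is
#' fully determined by the spec (including its seed): the same spec always
#' yields a byte-identical stream.
#'
#' @param spec A [stream_spec()].
#' @return A tibble with one character column per attribute plus `.event`
#'   (1-based index) and `.section`. The spec is attached as attribute
#'   `"spec"` and the first event index of each section as
#'   `"section_starts"`.
#' @examples
#' stream <- generate_stream(stream_spec(n = 100, seed = 7))
#' head(stream)
#' @export
generate_stream <- function(spec) {
  stopifnot(inherits(spec, "stream_spec"))
  set.seed(spec$seed)
  d <- spec$d
  n <- spec$n
  # tokens: per-attribute alphabets that can grow through novelty injection
  tokens <- lapply(seq_len(d), function(i)
    paste0(spec$attribute_names[i], "_", seq_len(spec$category_counts[i])))
  probs <- lapply(seq_len(d), function(i)
    rdirichlet1(rep(spec$base_concentration, spec$category_counts[i])))

  # section sizes as equal as possible
  bounds <- round(seq(0, n, length.out = spec$n_sections + 1L))
  sizes <- diff(bounds)
  section_of <- rep(seq_len(spec$n_sections), times = sizes)

  events <- matrix(NA_character_, n, d)
  pos <- 0L
  for (s in seq_len(spec$n_sections)) {
    if (s > 1L && is.finite(spec$drift_strength)) {
      probs <- lapply(probs, function(p) {
        alpha <- spec$drift_strength * p + 0.01
        rdirichlet1(alpha)
      })
    }
    ns <- sizes[s]
    if (ns == 0L) next
    # pre-drawn fresh values for the whole section (replays overwrite)
    fresh <- matrix(NA_character_, ns, d)
    for (i in seq_len(d))
      fresh[, i] <- sample(tokens[[i]], ns, replace = TRUE, prob = probs[[i]])
    replay <- runif(ns) < spec$repeat_prob
    novel <- runif(ns) < spec$novelty_schedule[s]
    for (j in seq_len(ns)) {
      t <- pos + j
      if (replay[j] && t > 1L) {
        ages <- (t - 1L):1L  # age of history position 1..t-1
        w <- exp(-spec$recency_decay * (ages - 1L))
        src <- sample.int(t - 1L, 1L, prob = w)
        events[t, ] <- events[src, ]
      } else {
        events[t, ] <- fresh[j, ]
        if (novel[j]) {
          a <- sample.int(d, 1L)
          tok <- paste0(spec$attribute_names[a], "_new",
                        length(tokens[[a]]) + 1L)
          tokens[[a]] <- c(tokens[[a]], tok)
          # the newcomer takes a small share of the attribute's mass
          probs[[a]] <- c(probs[[a]] * (1 - 0.02), 0.02)
          events[t, a] <- tok
        }
      }
    }
    pos <- pos + ns
  }
  out <- tibble::as_tibble(as.data.frame(events, stringsAsFactors = FALSE))
  names(out) <- spec$attribute_names
  out$.event <- seq_len(n)
  out$.section <- section_of
  attr(out, "spec") <- spec
  attr(out, "section_starts") <- head(bounds, -1L) + 1L
  out
}

#' Exact-match old/new ground truth
#'
#' Labels each event of a complete stream as *old* if it is an exact match
#' (over all attributes) of any earlier event, and *new* otherwise. This is
#' the ground truth against which hits and false alarms are scored.
#'
#' @param stream Data frame of complete events (metadata columns starting
#'   with `.` are ignored).
#' @return A logical vector: `TRUE` = old.
#' @export
truth_labels <- function(stream) {
  stopifnot(is.data.frame(stream))
  m <- stream[!startsWith(names(stream), ".")]
  if (anyNA(m)) stop("truth labels require complete instances", call. = FALSE)
  keys <- do.call(paste, c(m, sep = "\r"))
  duplicated(keys)
}

#' Mask attributes of events
#'
#' Sets `n_missing` uniformly chosen distinct attributes of each row to
#' `NA`, producing partial probes for pattern completion. Observed values
#' are untouched. The attributes are drawn independently per row.
#'
#' @param events Data frame of events or one character vector.
#' @param n_missing Number of attributes to mask, `0 <= n_missing <= d`.
#' @return The events with masked values (same shape as the input).
#' @export
make_partial <- function(events, n_missing) {
  vec <- !is.data.frame(events)
  if (vec) {
    m <- matrix(as.character(events), nrow = 1L)
  } else {
    keep <- startsWith(names(events), ".")
    meta <- events[keep]
    m <- as.matrix(events[!keep])
    mode(m) <- "character"
  }
  d <- ncol(m)
  n_missing <- as.integer(n_missing)
  if (n_missing < 0L || n_missing > d)
    stop("`n_missing` must lie in [0, d]", call. = FALSE)
  if (n_missing > 0L)
    for (i in seq_len(nrow(m))) m[i, sample.int(d, n_missing)] <- NA
  if (vec) return(m[1L, ])
  out <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  if (ncol(meta)) out <- dplyr::bind_cols(out, meta)
  out
}
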