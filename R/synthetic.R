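#' Synthetic-corpus generator configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' three-year (2022-2024) forum extract about a topical JAK-inhibitor cream,
#' a four-cluster topic mixture matching the published cluster counts
#' (1765, 558, 491, 136 of 2950), per-cluster mean compound sentiment
#' (0.473, -0.110, 0.349, 0.236), discussion-volume step-ups at the four
#' regulatory approval months (2022-07, 2023-04, 2023-07, 2024-10), a July
#' seasonal peak, a comment:post ratio of 2356:594, and a slight downward
#' sentiment drift. The drift is centered at the study midpoint so that
#' whole-corpus cluster means stay anchored at the configured values.
#'
#' @param n_entries Number of entries to generate.
#' @param mixture Length-4 probability vector over [fv_all_labels()].
#' @param sentiment_means Length-4 vector of per-cluster mean compound
#'   scores.
#' @param sentiment_sd Common sd of the per-entry target compound score.
#' @param monthly_base_rate Baseline entries/month; only used when
#'   `n_entries` is `NULL` (Poisson mode).
#' @param step_months Named numeric vector: `"YYYY-MM"` -> multiplier
#'   applied to the monthly rate from that month onward.
#' @param july_multiplier Extra multiplier on July months.
#' @param comment_post_ratio Expected comments per post.
#' @param drift_per_year Linear drift of the sentiment target, units of
#'   compound score per year, centered at the study midpoint.
#' @param keywords Drug keywords inserted into entry bodies.
#' @param keyword_miss_rate Fraction of entries generated without any drug
#'   keyword (filter-test negatives).
#' @param window Length-2 `"YYYY-MM-DD"` study window (half-open).
#' @param seed Integer seed; a fixed seed yields a byte-identical corpus.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_entries = 3000,
                             mixture = c(1765, 558, 491, 136) / 2950,
                             sentiment_means = c(0.473, -0.110, 0.349, 0.236),
                             sentiment_sd = 0.25,
                             monthly_base_rate = 20,
                             step_months = c("2022-07" = 2.2, "2023-04" = 1.6,
                                             "2023-07" = 1.4, "2024-10" = 1.6),
                             july_multiplier = 1.5,
                             comment_post_ratio = 2356 / 594,
                             drift_per_year = -0.02,
                             keywords = c("ruxolitinib", "opzelura"),
                             keyword_miss_rate = 0.02,
                             window = c("2022-01-01", "2025-01-01"),
                             seed = 1L) {
  mixture <- stats::setNames(as.numeric(mixture), fv_all_labels())
  if (abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    stop_fv("mixture must be nonnegative and sum to 1")
  }
  if (any(step_months <= 0) || july_multiplier <= 0) {
    stop_fv("rate multipliers must be positive")
  }
  if (sentiment_sd <= 0) stop_fv("sentiment_sd must be positive")
  structure(list(
    n_entries = n_entries, mixture = mixture,
    sentiment_means = stats::setNames(as.numeric(sentiment_means), fv_all_labels()),
    sentiment_sd = sentiment_sd, monthly_base_rate = monthly_base_rate,
    step_months = step_months, july_multiplier = july_multiplier,
    comment_post_ratio = comment_post_ratio, drift_per_year = drift_per_year,
    keywords = keywords, keyword_miss_rate = keyword_miss_rate,
    window = window, seed = as.integer(seed)
  ), class = "generator_config")
}

# Per-cluster template vocabularies. Core words are disjoint across clusters
# (and from the filler list) so that token-overlap embeddings separate the
# clusters; this is test scaffolding, not linguistic realism.
cluster_vocab <- function() {
  list(
    therapy_success = c("repigmentation", "face", "eyelid", "pigment",
                        "patch", "spot", "uvb", "phototherapy", "hair",
                        "fading", "repigmented", "progress"),
    side_effects = c("acne", "application", "site", "irritation", "redness",
                     "itchiness", "fatigue", "headache", "nausea", "anemia",
                     "flare", "dizziness"),
    insurance_cost = c("insurance", "copay", "authorization", "denied",
                       "coverage", "pharmacy", "cost", "price", "dollars",
                       "assistance", "deductible", "manufacturer"),
    off_topic = c("husband", "wife", "school", "dating", "friends",
                  "confidence", "makeup", "summer", "beach", "camouflage",
                  "community", "story")
  )
}

filler_vocab <- function() {
  c("i", "ive", "been", "here", "today", "still", "just", "also", "anyone",
    "else", "really", "week")
}

ladder_words <- function() {
  list(pos = c("okay", "fine", "decent", "calm", "glad", "pleased", "easy",
               "liked", "nice"),
       neg = c("meh", "iffy", "annoying", "unhappy", "upset", "frustrated",
               "angry", "miserable", "horrible"))
}

# strong sentiment words drawn on first, in order; all distinct so a single
# document never repeats a token (repetition would dominate its embedding
# norm and distort similarities)
strong_words <- function() {
  list(pos = c("love", "best", "great", "awesome", "amazing", "thrilled",
               "happy", "excellent", "perfect", "fantastic", "grateful",
               "excited", "confident", "improved", "positive", "good",
               "lucky", "hope", "helpful"),
       neg = c("worst", "death", "kill", "hate", "die", "scam", "bad",
               "liar", "painful", "lie", "terrible", "sad", "worse",
               "awful", "ugly", "pain", "lousy", "poor", "nasty"))
}

# distinct words whose lexicon valences sum to ~target (within 0.1), given
# the valence already carried by the other words of the entry
sentiment_filler_words <- function(residual, lexicon) {
  words <- character()
  remaining <- residual
  pool <- if (residual >= 0) strong_words()$pos else strong_words()$neg
  for (w in pool) {
    v <- lexicon[[w]]
    if (abs(v) <= abs(remaining) + 0.1 && sign(v) == sign(remaining)) {
      words <- c(words, w)
      remaining <- remaining - v
    }
    if (abs(remaining) < 0.15) break
  }
  step <- round(abs(remaining) / 0.2)
  if (step > 0) {
    ladder <- if (remaining >= 0) ladder_words()$pos else ladder_words()$neg
    words <- c(words, ladder[[min(step, 9L)]])
  }
  words
}

month_grid <- function(window) {
  lo <- as.Date(paste0(substr(window[[1]], 1, 7), "-01"))
  hi_excl <- as.Date(paste0(substr(window[[2]], 1, 7), "-01"))
  months <- seq(lo, hi_excl, by = "month")
  months[months < hi_excl]
}

monthly_rates <- function(config) {
  months <- month_grid(config$window)
  keys <- format(months, "%Y-%m")
  w <- rep(1, length(months))
  for (step in names(config$step_months)) {
    w[keys >= step] <- w[keys >= step] * config$step_months[[step]]
  }
  w[format(months, "%m") == "07"] <- w[format(months, "%m") == "07"] *
    config$july_multiplier
  stats::setNames(w, keys)
}

#' Generate a labeled synthetic forum corpus
#'
#' Draws per-entry cluster labels from the configured mixture, timestamps
#' from an inhomogeneous monthly rate (approval-month step-ups plus a July
#' peak), kinds from the comment:post ratio, and composes each body from the
#' cluster's template vocabulary, filler words, a drug keyword (except for a
#' small fraction of keyword-free filter-test negatives) and
#' sentiment-bearing words from the bundled mini-lexicon chosen so the
#' entry's compound score lands near its drawn target
#' `Normal(cluster_mean + drift * (t - midpoint), sd)`, truncated to
#' `[-0.95, 0.95]`. A fixed seed yields a byte-identical corpus.
#'
#' @param config A [generator_config()].
#' @return A `labeled_corpus`: list with `entries`, `gold_labels` (named by
#'   entry id), `gold_sentiment` (drawn targets, named), `keyword_free`
#'   (ids of entries without a drug keyword), `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  lexicon <- fv_mini_lexicon()
  vocab <- cluster_vocab()
  fillers <- filler_vocab()
  months <- month_grid(config$window)
  rates <- monthly_rates(config)
  mid <- mean(as.numeric(utc_seconds(config$window)))
  with_seed(config$seed, {
    n <- config$n_entries %||%
      sum(stats::rpois(length(rates), config$monthly_base_rate * rates))
    labels <- sample(fv_all_labels(), n, replace = TRUE, prob = config$mixture)
    month_idx <- sample(seq_along(months), n, replace = TRUE, prob = rates)
    month_start <- utc_seconds(as.character(months[month_idx]))
    next_month <- c(utc_seconds(as.character(months[-1])),
                    utc_seconds(config$window[[2]]))
    created <- floor(month_start +
                       runif(n) * (next_month[month_idx] - month_start))
    kind <- ifelse(runif(n) < config$comment_post_ratio /
                     (1 + config$comment_post_ratio), "comment", "post")
    years_from_mid <- (created - mid) / (365.25 * 24 * 3600)
    target <- rnorm(n, mean = config$sentiment_means[labels] +
                      config$drift_per_year * years_from_mid,
                    sd = config$sentiment_sd)
    target <- pmin(0.95, pmax(-0.95, target))
    has_keyword <- runif(n) >= config$keyword_miss_rate
    ids <- sprintf("e%05d", seq_len(n))
    alpha <- 15
    bodies <- character(n)
    titles <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      core <- sample(vocab[[labels[[i]]]], sample(5:8, 1))
      fill <- sample(fillers, sample(1:3, 1))
      words <- c(core, fill)
      if (has_keyword[[i]]) {
        words <- c(words, sample(c(config$keywords, "Opzelura"), 1))
      }
      if (kind[[i]] == "post") {
        titles[[i]] <- paste(sample(vocab[[labels[[i]]]], 2), collapse = " ")
        words_all <- c(words, strsplit(titles[[i]], " ")[[1]])
      } else {
        words_all <- words
      }
      base_val <- sum(lexicon[match(tolower(words_all), names(lexicon))],
                      na.rm = TRUE)
      s_target <- target[[i]] * sqrt(alpha / (1 - target[[i]]^2))
      senti <- sentiment_filler_words(s_target - base_val, lexicon)
      bodies[[i]] <- paste(sample(c(words, senti)), collapse = " ")
    }
    post_ids <- ids[kind == "post"]
    parent <- rep(NA_character_, n)
    if (length(post_ids)) {
      parent[kind == "comment"] <- sample(post_ids, sum(kind == "comment"),
                                          replace = TRUE)
    }
    entries <- data.frame(id = ids, kind = kind, created_utc = created,
                          title = titles, body = bodies, parent_id = parent,
                          stringsAsFactors = FALSE)
    structure(list(entries = entries,
                   gold_labels = stats::setNames(labels, ids),
                   gold_sentiment = stats::setNames(target, ids),
                   keyword_free = ids[!has_keyword],
                   config = config),
              class = "labeled_corpus")
  })
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("<labeled_corpus> %d entries (%d posts, %d comments), seed %d\n",
              nrow(x$entries), sum(x$entries$kind == "post"),
              sum(x$entries$kind == "comment"), x$config$seed))
  print(round(prop.table(table(x$gold_labels)), 3))
  invisible(x)
}

#' Simulate a human annotator over gold labels
#'
#' Each gold label is kept with probability `1 - epsilon` and otherwise
#' replaced by a label drawn uniformly from the other three clusters.
#'
#' @param gold_labels Named character vector (entry id -> cluster).
#' @param epsilon Symmetric error rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame `entry_id`, `label`.
#' @export
generate_annotations <- function(gold_labels, epsilon = 0.116, seed = 1) {
  if (epsilon < 0 || epsilon >= 1) stop_fv("epsilon must be in [0, 1)")
  with_seed(seed, {
    n <- length(gold_labels)
    flip <- runif(n) < epsilon
    out <- unname(gold_labels)
    if (any(flip)) {
      out[flip] <- vapply(out[flip], function(l) {
        sample(setdiff(fv_all_labels(), l), 1)
      }, character(1))
    }
    data.frame(entry_id = names(gold_labels), label = out,
               stringsAsFactors = FALSE)
  })
}

#' Write a labeled corpus to disk
#'
#' Emits the NDJSON corpus [read_corpus()] ingests plus a gold-label CSV
#' (`entry_id`, `gold_label`, `gold_sentiment`).
#'
#' @param corpus A `labeled_corpus`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_labeled_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ndjson <- file.path(dir, "corpus.ndjson")
  csv <- file.path(dir, "gold_labels.csv")
  write_corpus_ndjson(corpus$entries, ndjson)
  write.csv(data.frame(entry_id = names(corpus$gold_labels),
                       gold_label = unname(corpus$gold_labels),
                       gold_sentiment = unname(corpus$gold_sentiment)),
            csv, row.names = FALSE)
  invisible(c(corpus = ndjson, gold = csv))
}
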