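#' Run the full infodemiology pipeline
#'
#' Orchestrates ingest -> keyword filter -> empty removal -> normalization ->
#' topic classification -> sentiment scoring -> temporal analysis ->
#' (optional) human validation, and writes a reproducible report bundle.
#' Identical inputs, configuration and seed give byte-identical reports.
#'
#' Written files (under `output_dir`): `run_header.json` (provenance: seeds,
#' thresholds, backend), `ledger.json`, `assignments.csv`, `sentiment.csv`,
#' `cluster_table.json`/`.csv` (counts, percent with Wald 95% CI, mean
#' sentiment with 95% CI), `monthly_series.csv` (with 12-month trailing
#' moving averages), `breakpoints.json`, `seasonal_profile.csv`,
#' `post_comment_comparison.json`, `sentiment_trend.csv`, and
#' `validation.json` when annotations are supplied.
#'
#' @param corpus A `forum_corpus`, a `labeled_corpus`, an entries data
#'   frame, or a path to an NDJSON corpus file.
#' @param output_dir Directory for the report bundle; created if needed.
#'   `NULL` skips writing.
#' @param config Cluster configuration (see [default_cluster_config()]).
#' @param keywords Drug keywords for the retention filter.
#' @param window Optional study window (UNIX seconds or POSIXct, half-open).
#' @param annotations Optional gold labels (data frame `entry_id`, `label`)
#'   to run the validation protocol.
#' @param backend Embedding backend; `NULL` builds a [hashing_backend()]
#'   from `config$seed`.
#' @param engine Sentiment engine.
#' @param seed Seed for validation sampling and bootstrap.
#' @param validation_n Validation sample size.
#' @param bootstrap_B Bootstrap replicates for validation CIs.
#' @param cp_penalty,cp_min_size Change-point detection controls (see
#'   [detect_change_points()]).
#' @return A `pipeline_report` list with all computed components, invisibly
#'   when `output_dir` is set.
#' @export
run_pipeline <- function(corpus, output_dir = NULL,
                         config = default_cluster_config(),
                         keywords = c("ruxolitinib", "opzelura"),
                         window = NULL, annotations = NULL, backend = NULL,
                         engine = mini_sentiment_engine(), seed = 1,
                         validation_n = 500, bootstrap_B = 2000,
                         cp_penalty = NULL, cp_min_size = 2) {
  stage <- "ingest"
  report <- tryCatch({
    if (inherits(corpus, "labeled_corpus")) {
      if (is.null(annotations)) {
        annotations <- data.frame(entry_id = names(corpus$gold_labels),
                                  label = unname(corpus$gold_labels),
                                  stringsAsFactors = FALSE)
      }
      corpus <- corpus$entries
    }
    fc <- if (is.character(corpus)) read_corpus(corpus, window = window)
          else corpus_parts(if (is.null(window)) corpus
                            else as_forum_entries(corpus, window = window))
    fc <- if (inherits(fc, "forum_corpus")) fc else new_corpus(fc$entries, fc$ledger)

    stage <- "filter"
    fc <- filter_by_keywords(fc, keywords)
    fc <- drop_empty(fc)
    entries <- fc$entries

    stage <- "classify"
    if (is.null(backend)) {
      backend <- hashing_backend(seed = config$seed %||% 42L)
    }
    sets <- build_prototype_sets(config_phrases(config), backend)
    tau <- config$tau %||% 0.25
    cls <- classify_corpus(entries, sets, tau = tau,
                           override_lists = config_override_lists(config),
                           backend = backend)

    stage <- "sentiment"
    scores <- score_corpus(entries, engine)
    cluster_sent <- summarize_by_cluster(scores, cls$assignments)
    trend <- sentiment_trend(scores, cls$assignments, entries)

    stage <- "temporal"
    series <- monthly_counts(entries, window = window)
    series$posts_ma12 <- moving_average(series$posts, 12)
    series$comments_ma12 <- moving_average(series$comments, 12)
    cps <- list(
      posts = detect_change_points(series$posts, penalty = cp_penalty,
                                   min_size = cp_min_size, "posts",
                                   variance_stabilize = TRUE),
      comments = detect_change_points(series$comments, penalty = cp_penalty,
                                      min_size = cp_min_size, "comments",
                                      variance_stabilize = TRUE),
      total = detect_change_points(series$posts + series$comments,
                                   penalty = cp_penalty,
                                   min_size = cp_min_size, "total",
                                   variance_stabilize = TRUE))
    profile <- seasonal_profile(series)
    comparison <- post_comment_comparison(profile)

    stage <- "cluster_table"
    total <- nrow(entries)
    tab <- do.call(rbind, lapply(fv_all_labels(), function(cl) {
      k <- cls$counts[[cl]]
      ci <- wald_ci(k, total)
      srow <- cluster_sent[cluster_sent$cluster == cl, ]
      data.frame(cluster = cl, n = k, pct = ci$pct,
                 pct_lower = ci$lower, pct_upper = ci$upper,
                 mean_sentiment = if (nrow(srow)) srow$mean else NA_real_,
                 sent_lower = if (nrow(srow)) srow$ci_lower else NA_real_,
                 sent_upper = if (nrow(srow)) srow$ci_upper else NA_real_,
                 stringsAsFactors = FALSE)
    }))

    validation <- NULL
    if (!is.null(annotations)) {
      stage <- "validate"
      validation <- validate_classifier(cls$assignments, annotations,
                                        n = min(validation_n, total),
                                        seed = seed, B = bootstrap_B)
    }

    structure(list(
      header = list(
        package = "forumvigil",
        keywords = keywords, tau = tau, backend = backend$name,
        config_seed = config$seed %||% NA, run_seed = seed,
        validation_n = validation_n, bootstrap_B = bootstrap_B,
        cp_min_size = cp_min_size,
        cp_penalty = cp_penalty %||% "auto"),
      ledger = fc$ledger, entries = entries, assignments = cls$assignments,
      counts = cls$counts, scores = scores, cluster_table = tab,
      cluster_sentiment = cluster_sent, trend = trend, series = series,
      change_points = cps, seasonal = profile, comparison = comparison,
      validation = validation
    ), class = "pipeline_report")
  }, error = function(e) {
    stop_fv("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  if (!is.null(output_dir)) {
    write_report_bundle(report, output_dir)
    return(invisible(report))
  }
  report
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

write_report_bundle <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_json_file(report$header, p("run_header.json"))
  write_json_file(as.list(report$ledger), p("ledger.json"))
  write.csv(report$assignments, p("assignments.csv"), row.names = FALSE)
  write.csv(report$scores, p("sentiment.csv"), row.names = FALSE)
  write.csv(report$cluster_table, p("cluster_table.csv"), row.names = FALSE)
  write_json_file(report$cluster_table, p("cluster_table.json"))
  write.csv(report$series, p("monthly_series.csv"), row.names = FALSE)
  bp <- lapply(report$change_points, function(cp) {
    list(series = cp$series_name, breakpoints = cp$breakpoints,
         months = breakpoint_months(cp, report$series),
         penalty = cp$penalty, segment_means = cp$segment_means)
  })
  write_json_file(bp, p("breakpoints.json"))
  write.csv(report$seasonal, p("seasonal_profile.csv"), row.names = FALSE)
  write_json_file(unclass(report$comparison), p("post_comment_comparison.json"))
  write.csv(report$trend, p("sentiment_trend.csv"), row.names = FALSE)
  if (!is.null(report$validation)) {
    v <- report$validation
    write_json_file(list(
      n = v$n,
      accuracy = v$accuracy, weighted_f1 = v$weighted_f1, kappa = v$kappa,
      kappa_band = v$kappa_band,
      confusion = as.data.frame(as.table(v$confusion),
                                stringsAsFactors = FALSE),
      seed = v$seed, B = v$B), p("validation.json"))
  }
  invisible(output_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$ledger)
  cat("cluster table:\n")
  print(x$cluster_table, digits = 4)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' Export the most polar entries per cluster
#'
#' Supports qualitative review: for each cluster, the `k` entries with the
#' largest absolute compound score, ties broken by entry id.
#'
#' @param entries Entries data frame.
#' @param assignments Assignment data frame.
#' @param scores Sentiment scores data frame.
#' @param k Entries per cluster (`>= 1`); clusters smaller than `k` are
#'   exported whole.
#' @param path Optional output text file.
#' @return Data frame `cluster`, `entry_id`, `compound`, `text` (also
#'   written to `path` when given), invisibly when writing.
#' @export
export_exemplars <- function(entries, assignments, scores, k = 5,
                             path = NULL) {
  if (k < 1) stop_fv("k must be >= 1")
  merged <- merge(merge(assignments[, c("entry_id", "label")], scores,
                        by = "entry_id"),
                  data.frame(entry_id = entries$id,
                             text = paste(ifelse(is.na(entries$title), "",
                                                 entries$title),
                                          entries$body),
                             stringsAsFactors = FALSE),
                  by = "entry_id")
  rows <- lapply(fv_all_labels(), function(cl) {
    sub <- merged[merged$label == cl, ]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(-abs(sub$compound), sub$entry_id), ]
    head(sub, k)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(cluster = out$label, entry_id = out$entry_id,
                    compound = out$compound, text = out$text,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    lines <- unlist(lapply(split(out, factor(out$cluster, fv_all_labels())),
                           function(sub) {
      if (!nrow(sub)) return(character())
      c(sprintf("== %s ==", sub$cluster[[1]]),
        sprintf("[%s] (%.4f) %s", sub$entry_id, sub$compound, sub$text), "")
    }))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
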