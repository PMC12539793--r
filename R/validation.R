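#' Proportional validation sample
#'
#' Allocates a sample of size `n` across the model-assigned clusters by
#' largest-remainder rounding of `n * cluster_count / total`, then draws a
#' seeded simple random sample within each cluster. If a cluster is smaller
#' than its allocation, the allocation is truncated and the shortfall is
#' redistributed across clusters with spare capacity (largest remainder
#' first), with a warning.
#'
#' @param assignments Assignment data frame (see [classify_corpus()]).
#' @param n Sample size (`<=` corpus size).
#' @param seed Integer seed; identical seeds give identical samples.
#' @return Character vector of sampled entry ids.
#' @export
proportional_sample <- function(assignments, n = 500, seed = 1) {
  total <- nrow(assignments)
  if (n > total) stop_fv("sample size %d exceeds corpus size %d", n, total)
  counts <- vapply(fv_all_labels(),
                   function(cl) sum(assignments$label == cl), numeric(1))
  alloc <- largest_remainder(n * counts / total, n)
  over <- alloc > counts
  if (any(over)) {
    warn_fv("allocation exceeds cluster size for %s; redistributing",
            paste(names(counts)[over], collapse = ", "))
    alloc[over] <- counts[over]
    shortfall <- n - sum(alloc)
    while (shortfall > 0) {
      capacity <- counts - alloc
      if (all(capacity <= 0)) stop_fv("cannot allocate %d entries", n)
      # grant one unit to the open cluster with the largest remainder
      rem <- n * counts / total - floor(n * counts / total)
      rem[capacity <= 0] <- -Inf
      pick <- which.max(rem + capacity / (total + 1e-9) * 1e-12)
      alloc[pick] <- alloc[pick] + 1
      shortfall <- shortfall - 1
    }
  }
  with_seed(seed, {
    ids <- character()
    for (cl in fv_all_labels()) {
      pool <- assignments$entry_id[assignments$label == cl]
      k <- alloc[[cl]]
      if (k > 0) ids <- c(ids, sort(pool)[sample.int(length(pool), k)])
    }
    ids
  })
}

#' Largest-remainder rounding of fractional quotas
#'
#' Rounds nonnegative quotas down and distributes the remaining units to the
#' largest fractional remainders (ties to the larger quota, then first in
#' order).
#'
#' @param quotas Nonnegative numeric vector summing (approximately) to `n`.
#' @param n Integer total to allocate.
#' @return Integer vector of allocations summing to `n`.
#' @export
largest_remainder <- function(quotas, n) {
  base <- floor(quotas)
  short <- as.integer(round(n - sum(base)))
  if (short > 0) {
    rem <- quotas - base
    ord <- order(-rem, -quotas, seq_along(quotas))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(quotas))
}

#' Confusion matrix of human (gold) vs model labels
#'
#' @param gold,predicted Character vectors of equal length over
#'   [fv_all_labels()].
#' @param labels Label order for rows/columns.
#' @return Integer matrix, rows = gold, columns = model.
#' @export
confusion_matrix <- function(gold, predicted, labels = fv_all_labels()) {
  if (length(gold) != length(predicted)) stop_fv("label vectors differ in length")
  unknown <- setdiff(unique(c(gold, predicted)), labels)
  if (length(unknown)) stop_fv("unknown label '%s'", unknown[[1]])
  table(factor(gold, levels = labels), factor(predicted, levels = labels)) |>
    unclass()
}

#' Classification metrics from a confusion matrix
#'
#' `cm_accuracy` is trace/total. `weighted_f1` computes per-class F1
#' (`2PR/(P+R)`, 0 when undefined) with precision from columns and recall
#' from rows, weighted by gold support (row sums). `cohens_kappa` is
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum(row_i * col_i) / total^2`;
#' a degenerate `p_e = 1` yields 1 when agreement is perfect and an error
#' otherwise.
#'
#' @param cm Square counts matrix (rows gold, columns model).
#' @return Numeric scalar.
#' @export
cm_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_fv("empty confusion matrix")
  sum(diag(cm)) / total
}

#' @rdname cm_accuracy
#' @export
weighted_f1 <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_fv("empty confusion matrix")
  support <- rowSums(cm)
  f1 <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (support[i] > 0) tp / support[i] else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  sum(f1 * support) / total
}

#' @rdname cm_accuracy
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_fv("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    if (abs(1 - p_o) < .Machine$double.eps^0.5) return(1)
    stop_fv("kappa undefined: expected agreement is 1 with imperfect agreement")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Interpretation band for Cohen's kappa
#'
#' Half-open benchmark bands: `[0.01, 0.21)` slight, `[0.21, 0.41)` fair,
#' `[0.41, 0.61)` moderate, `[0.61, 0.81)` substantial, `[0.81, 1]` almost
#' perfect; below 0.01 is "none". The half-open convention places
#' kappa = 0.801 in "substantial".
#'
#' @param kappa Value in `[-1, 1]`.
#' @return Band name.
#' @export
kappa_band <- function(kappa) {
  if (kappa < -1 || kappa > 1) stop_fv("kappa must be in [-1, 1]")
  if (kappa < 0.01) return("none")
  if (kappa < 0.21) return("slight")
  if (kappa < 0.41) return("fair")
  if (kappa < 0.61) return("moderate")
  if (kappa < 0.81) return("substantial")
  "almost perfect"
}

#' Run the human-validation protocol
#'
#' Draws a proportional sample of entries, confronts model labels with the
#' gold (human) labels, and reports accuracy, weighted F1 and Cohen's kappa
#' with seeded percentile-bootstrap 95% CIs (resampling the sampled pairs),
#' plus the kappa interpretation band.
#'
#' @param assignments Assignment data frame.
#' @param gold Named character vector or data frame (`entry_id`, `label`)
#'   of gold labels covering the sampled ids.
#' @param n Validation sample size.
#' @param seed Seed for sampling and bootstrap.
#' @param B Bootstrap replicates.
#' @return A `validation_report` list: `n`, `confusion`, `accuracy`,
#'   `weighted_f1`, `kappa` (each with `ci95`), `kappa_band`, `seed`, `B`.
#' @export
validate_classifier <- function(assignments, gold, n = 500, seed = 1,
                                B = 2000) {
  if (is.data.frame(gold)) {
    gold <- stats::setNames(gold$label, gold$entry_id)
  }
  ids <- proportional_sample(assignments, n = n, seed = seed)
  if (any(!ids %in% names(gold))) {
    stop_fv("gold labels missing for %d sampled entries",
            sum(!ids %in% names(gold)))
  }
  pred <- assignments$label[match(ids, assignments$entry_id)]
  g <- unname(gold[ids])
  pairs <- data.frame(gold = g, pred = pred, stringsAsFactors = FALSE)
  cm <- confusion_matrix(pairs$gold, pairs$pred)
  boot <- function(metric) {
    bootstrap_ci(function(p) metric(confusion_matrix(p$gold, p$pred)),
                 pairs, B = B, seed = seed)
  }
  acc_ci <- boot(cm_accuracy)
  f1_ci <- boot(weighted_f1)
  kap_ci <- boot(cohens_kappa)
  kap <- cohens_kappa(cm)
  structure(list(
    n = nrow(pairs), confusion = cm,
    accuracy = list(value = cm_accuracy(cm), ci95 = c(acc_ci$lower, acc_ci$upper)),
    weighted_f1 = list(value = weighted_f1(cm), ci95 = c(f1_ci$lower, f1_ci$upper)),
    kappa = list(value = kap, ci95 = c(kap_ci$lower, kap_ci$upper)),
    kappa_band = kappa_band(kap),
    seed = seed, B = B
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d\n", x$n))
  cat(sprintf("  accuracy    %.3f (95%% CI %.3f to %.3f)\n",
              x$accuracy$value, x$accuracy$ci95[1], x$accuracy$ci95[2]))
  cat(sprintf("  weighted F1 %.3f (95%% CI %.3f to %.3f)\n",
              x$weighted_f1$value, x$weighted_f1$ci95[1], x$weighted_f1$ci95[2]))
  cat(sprintf("  Cohen kappa %.3f (95%% CI %.3f to %.3f) [%s]\n",
              x$kappa$value, x$kappa$ci95[1], x$kappa$ci95[2], x$kappa_band))
  invisible(x)
}
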