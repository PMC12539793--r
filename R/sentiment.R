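#' Bundled miniature sentiment lexicon
#'
#' About two hundred everyday sentiment-bearing words with signed valences
#' on the familiar roughly -4..+4 lexicon scale. Magnitudes are this
#' package's own calibrations in the style of social-media sentiment
#' lexicons; the set deliberately covers a fine ladder of magnitudes
#' (0.2, 0.4, ..., 1.8) in both signs so synthetic text can be composed to
#' hit a target compound score. Unknown tokens score 0.
#'
#' @return Named numeric vector: token -> valence.
#' @export
fv_mini_lexicon <- function() {
  c(
    # positive
    good = 1.9, great = 3.1, excellent = 2.7, amazing = 2.8, awesome = 3.1,
    love = 3.2, loved = 2.9, like = 1.5, liked = 1.6, best = 3.2,
    better = 1.9, improve = 1.9, improved = 2.1, improving = 2.0,
    improvement = 2.0, success = 2.7, successful = 2.6, win = 2.8,
    works = 1.7, worked = 1.6, working = 1.4, effective = 2.1,
    helpful = 1.9, help = 1.7, helped = 1.8, hope = 1.9, hoping = 1.6,
    hopeful = 1.5, encouraged = 1.8, encouraging = 1.9, progress = 1.7,
    recovery = 1.6, relief = 1.9, relieved = 1.9, grateful = 2.3,
    thankful = 2.2, thanks = 1.9, thank = 1.6, happy = 2.7, happier = 2.4,
    joy = 2.8, glad = 1.0, pleased = 1.2, delighted = 1.6, excited = 2.2,
    exciting = 2.1, thrilled = 2.8, fantastic = 2.6, perfect = 2.7,
    beautiful = 2.9, nice = 1.8, positive = 2.0, promising = 1.6,
    confident = 2.2, confidence = 1.9, comfortable = 1.5, safe = 1.6,
    easy = 1.4, easier = 1.5, free = 1.4, support = 1.7, supportive = 2.0,
    recommend = 1.6, recommended = 1.5, impressed = 2.1, impressive = 2.3,
    wonderful = 1.8, luck = 1.8, lucky = 1.9, smile = 2.0, friendly = 2.2,
    clear = 1.1, cleared = 1.3, clearing = 1.0, gain = 1.5, gained = 1.4,
    okay = 0.2, fine = 0.4, decent = 0.6, calm = 0.8, cool = 1.3, strong = 1.3,
    worth = 1.1, cheap = 0.9, affordable = 1.3, generous = 2.0,
    # negative
    bad = -2.5, worse = -2.1, worst = -3.1, terrible = -2.1, awful = -2.0,
    horrible = -1.8, hate = -2.7, hated = -2.6, fail = -2.5, failed = -2.3,
    failure = -2.4, problem = -1.7, problems = -1.7, issue = -1.2,
    issues = -1.3, pain = -2.0, painful = -2.2, hurt = -2.0, hurts = -1.9,
    sick = -1.9, sicker = -2.1, ill = -1.8, illness = -1.7, disease = -1.5,
    worry = -1.6, worried = -1.5, worrying = -1.6, worries = -1.5,
    anxious = -1.7, anxiety = -1.8, panic = -2.2, scared = -1.9,
    scary = -1.9, fear = -1.9, afraid = -1.8, depressed = -2.2,
    depression = -2.1, sad = -2.1, unhappy = -0.8, upset = -1.0,
    frustrated = -1.2, frustrating = -1.6, angry = -1.4, anger = -1.8,
    annoyed = -1.4, annoying = -0.6, miserable = -1.6, stress = -1.6,
    stressed = -1.8, stressful = -1.9, tired = -1.2, exhausted = -1.7,
    fatigue = -1.5, fatigued = -1.6, weak = -1.4, dizzy = -1.3,
    nausea = -1.6, rash = -1.4, burning = -1.6, itchy = -1.3, itching = -1.3,
    acne = -1.2, swelling = -1.3, severe = -1.8, dangerous = -1.9,
    danger = -1.9, risk = -1.1, risks = -1.2, risky = -1.4, warning = -1.0,
    denied = -1.6, denial = -1.5, deny = -1.4, refuse = -1.5, refused = -1.6,
    rejected = -1.9, expensive = -1.1, costly = -1.2, overpriced = -1.5,
    struggle = -1.7, struggling = -1.8, difficult = -1.5, hard = -0.4,
    harder = -0.9, impossible = -1.6, useless = -1.8, waste = -1.8,
    wasted = -1.9, disappointing = -2.0, disappointed = -1.9, poor = -1.9,
    lousy = -1.9, nasty = -1.9, gross = -1.7, ugly = -2.0, stigma = -1.5,
    embarrassing = -1.6, embarrassed = -1.5, ashamed = -1.8, cry = -1.9,
    crying = -2.0, died = -2.6, die = -2.7, death = -2.9, kill = -2.8,
    killed = -2.9, relapse = -1.8, relapsed = -1.9, spread = -0.9,
    spreading = -1.0, meh = -0.2, iffy = -0.4, unlucky = -1.6, broke = -1.3,
    scam = -2.6, fraud = -2.7, lie = -2.2, lies = -2.1, liar = -2.5
  )
}

#' Negation tokens recognized by the mini sentiment engine
#' @return Character vector of negation words.
#' @export
fv_negations <- function() {
  c("not", "no", "never", "none", "nothing", "cannot", "cant", "can't",
    "dont", "don't", "didnt", "didn't", "doesnt", "doesn't", "isnt",
    "isn't", "wasnt", "wasn't", "wont", "won't", "without", "hardly",
    "neither", "nor", "nobody")
}

#' Miniature lexicon-and-rules sentiment engine
#'
#' Scores text on the compound scale: signed valences of known tokens are
#' summed (a token's valence is sign-flipped when a negation word occurs in
#' the three preceding tokens), and the sum `s` is normalized to
#' `s / sqrt(s^2 + alpha)`, which is odd, strictly increasing and bounded in
#' `(-1, 1)`. This implements the normalization and negation rule of
#' social-media lexicon scorers; boosters, idioms, punctuation emphasis and
#' emoji handling are deliberately out of scope. An adapter to a full
#' lexicon-rule tool can be supplied through the same contract (a list with
#' `name` and `score(texts)`).
#'
#' @param lexicon Named numeric token -> valence map.
#' @param negations Character vector of negation tokens.
#' @param alpha Normalization constant (default 15).
#' @return A `sentiment_engine` object.
#' @export
mini_sentiment_engine <- function(lexicon = fv_mini_lexicon(),
                                  negations = fv_negations(),
                                  alpha = 15) {
  structure(list(
    name = "mini-lexicon-rule",
    alpha = alpha,
    score = function(texts) {
      texts[is.na(texts)] <- ""
      toks <- strsplit(tolower(texts), "[^a-z0-9']+")
      vapply(toks, function(tk) {
        tk <- tk[nzchar(tk)]
        if (!length(tk)) return(0)
        val <- unname(lexicon[match(tk, names(lexicon))])
        val[is.na(val)] <- 0
        isneg <- tk %in% negations
        if (any(isneg)) {
          lastneg <- cummax(ifelse(isneg, seq_along(tk), 0L))
          lastneg_before <- c(0L, lastneg[-length(tk)])
          flip <- lastneg_before > 0 & lastneg_before >= seq_along(tk) - 3
          val[flip] <- -val[flip]
        }
        s <- sum(val)
        s / sqrt(s^2 + alpha)
      }, numeric(1))
    }
  ), class = "sentiment_engine")
}

#' Score texts on the compound sentiment scale
#'
#' @param texts Character vector (raw text: lexicon-rule scoring is applied
#'   before normalization, since casing and punctuation carry signal for
#'   richer engines).
#' @param engine A `sentiment_engine`, default [mini_sentiment_engine()].
#' @return Numeric vector of compound scores in `[-1, 1]`; empty text
#'   scores 0.
#' @export
score_sentiment <- function(texts, engine = mini_sentiment_engine()) {
  if (!is.list(engine) || !is.function(engine$score)) {
    stop_fv("engine does not provide a score() function")
  }
  engine$score(texts)
}

#' Score every entry of a corpus
#'
#' @param entries Entries data frame.
#' @param engine A `sentiment_engine`.
#' @return Data frame `entry_id`, `compound`.
#' @export
score_corpus <- function(entries, engine = mini_sentiment_engine()) {
  raw <- paste(ifelse(is.na(entries$title), "", entries$title), entries$body)
  data.frame(entry_id = entries$id,
             compound = score_sentiment(raw, engine),
             stringsAsFactors = FALSE)
}

#' Per-cluster sentiment summaries
#'
#' Arithmetic mean compound per cluster with a normal-approximation 95% CI
#' (`mean +- 1.96 * sd / sqrt(n)`). Singleton clusters get a degenerate
#' `[mean, mean]` interval with a warning; empty clusters are omitted.
#'
#' @param scores Data frame `entry_id`, `compound` (see [score_corpus()]).
#' @param assignments Assignment data frame (see [classify_corpus()]).
#' @param conf Confidence level.
#' @return Data frame `cluster`, `n`, `mean`, `ci_lower`, `ci_upper`.
#' @export
summarize_by_cluster <- function(scores, assignments, conf = 0.95) {
  merged <- merge(scores, assignments[, c("entry_id", "label")],
                  by = "entry_id")
  if (nrow(merged) != nrow(scores)) {
    stop_fv("every scored entry must have an assignment")
  }
  z <- qnorm((1 + conf) / 2)
  rows <- lapply(fv_all_labels(), function(cl) {
    x <- merged$compound[merged$label == cl]
    n <- length(x)
    if (!n) return(NULL)
    m <- mean(x)
    if (n == 1) {
      warn_fv("cluster '%s' has a single entry; degenerate CI", cl)
      half <- 0
    } else {
      half <- z * sd(x) / sqrt(n)
    }
    data.frame(cluster = cl, n = n, mean = m,
               ci_lower = m - half, ci_upper = m + half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-cluster sentiment time series
#'
#' Mean compound score per cluster per calendar period (month or year);
#' periods inside the observed range with no entries for a cluster appear
#' with `NA` mean.
#'
#' @param scores Data frame `entry_id`, `compound`.
#' @param assignments Assignment data frame.
#' @param entries Entries data frame (for timestamps).
#' @param period `"month"` or `"year"`.
#' @return Data frame `cluster`, `period`, `n`, `mean`.
#' @export
sentiment_trend <- function(scores, assignments, entries,
                            period = c("month", "year")) {
  period <- match.arg(period)
  fmt <- if (period == "month") "%Y-%m" else "%Y"
  df <- merge(merge(scores, assignments[, c("entry_id", "label")],
                    by = "entry_id"),
              data.frame(entry_id = entries$id,
                         period = format(utc_time(entries$created_utc), fmt),
                         stringsAsFactors = FALSE),
              by = "entry_id")
  all_periods <- if (period == "month") {
    rng <- range(as.Date(paste0(df$period, "-01")))
    format(seq(rng[1], rng[2], by = "month"), "%Y-%m")
  } else {
    as.character(seq(min(as.integer(df$period)), max(as.integer(df$period))))
  }
  grid <- expand.grid(cluster = fv_all_labels(), period = all_periods,
                      stringsAsFactors = FALSE)
  agg_n <- aggregate(compound ~ label + period, data = df, FUN = length)
  agg_m <- aggregate(compound ~ label + period, data = df, FUN = mean)
  names(agg_n) <- c("cluster", "period", "n")
  names(agg_m) <- c("cluster", "period", "mean")
  out <- merge(merge(grid, agg_n, all.x = TRUE), agg_m, all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  out <- out[order(out$cluster, out$period), c("cluster", "period", "n", "mean")]
  rownames(out) <- NULL
  out
}
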