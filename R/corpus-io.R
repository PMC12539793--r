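#' Filter ledgers
#'
#' A filter ledger records how many forum entries survive each stage of the
#' ingestion pipeline, split by entry kind (post vs comment). It is the
#' auditable counterpart of a study flow diagram: `collected` entries come in,
#' `keyword_matched` mention the drug, `empty_removed` are deleted/blank, and
#' `final = keyword_matched - empty_removed` reach analysis.
#'
#' @param collected,keyword_matched,empty_removed Optional named integer
#'   vectors with elements `post` and `comment`.
#' @return An object of class `filter_ledger`: a list of per-stage counts by
#'   kind, each a named integer vector `c(post=, comment=)`.
#' @export
filter_ledger <- function(collected = NULL, keyword_matched = NULL,
                          empty_removed = NULL) {
  ledger <- structure(list(), class = "filter_ledger")
  if (!is.null(collected)) ledger$collected <- as_kind_counts(collected)
  if (!is.null(keyword_matched)) ledger$keyword_matched <- as_kind_counts(keyword_matched)
  if (!is.null(empty_removed)) {
    ledger$empty_removed <- as_kind_counts(empty_removed)
    if (is.null(ledger$keyword_matched)) {
      stop_fv("empty_removed requires keyword_matched counts")
    }
    ledger$final <- ledger$keyword_matched - ledger$empty_removed
  }
  validate_ledger(ledger)
  ledger
}

as_kind_counts <- function(x) {
  if (is.null(names(x))) names(x) <- c("post", "comment")[seq_along(x)]
  out <- c(post = 0L, comment = 0L)
  out[names(x)] <- as.integer(x)
  out
}

validate_ledger <- function(ledger) {
  for (stage in names(ledger)) {
    if (any(ledger[[stage]] < 0L)) {
      stop_fv("negative count in ledger stage '%s'", stage)
    }
  }
  if (!is.null(ledger$final) && !is.null(ledger$keyword_matched) &&
      !is.null(ledger$empty_removed)) {
    stopifnot(identical(ledger$final,
                        ledger$keyword_matched - ledger$empty_removed))
  }
  invisible(ledger)
}

count_by_kind <- function(entries) {
  c(post = sum(entries$kind == "post"),
    comment = sum(entries$kind == "comment"))
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("Filter ledger (posts / comments / total)\n")
  for (stage in names(x)) {
    cat(sprintf("  %-16s %6d / %6d / %6d\n", stage,
                x[[stage]][["post"]], x[[stage]][["comment"]], sum(x[[stage]])))
  }
  invisible(x)
}

#' @export
as.list.filter_ledger <- function(x, ...) {
  out <- lapply(unclass(x), function(cnt) {
    list(post = unname(cnt[["post"]]), comment = unname(cnt[["comment"]]),
         total = unname(sum(cnt)))
  })
  out
}

#' Total entries at a ledger stage
#' @param ledger A [filter_ledger()].
#' @param stage Stage name, e.g. `"final"`.
#' @return Integer total over kinds.
#' @export
ledger_total <- function(ledger, stage = "final") {
  if (is.null(ledger[[stage]])) stop_fv("ledger has no stage '%s'", stage)
  sum(ledger[[stage]])
}

new_corpus <- function(entries, ledger) {
  structure(list(entries = entries, ledger = ledger), class = "forum_corpus")
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat(sprintf("<forum_corpus> %d entries\n", nrow(x$entries)))
  print(x$ledger)
  invisible(x)
}

empty_entries <- function() {
  data.frame(id = character(), kind = character(), created_utc = numeric(),
             title = character(), body = character(), parent_id = character(),
             stringsAsFactors = FALSE)
}

#' Read a forum corpus from newline-delimited JSON
#'
#' Each line of the file is one JSON object describing a post or comment with
#' fields `id`, `kind` (`"post"` or `"comment"`), `created_utc` (UNIX seconds,
#' UTC), optional `title` (posts only), `body`, and optional `parent_id`.
#' Entries are returned in file order; duplicate ids keep the first
#' occurrence with a warning. An optional half-open study window
#' `[start, end)` drops entries outside it.
#'
#' @param path Path to an NDJSON file.
#' @param window Optional length-2 vector of POSIXct or UNIX-second bounds;
#'   entries with `start <= created_utc < end` are kept.
#' @return A `forum_corpus`: list with `entries` (data frame) and `ledger`
#'   (a [filter_ledger()] with the `collected` stage filled in).
#' @export
read_corpus <- function(path, window = NULL) {
  if (!file.exists(path)) stop_fv("corpus file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop_fv("malformed JSON on line %d: %s", i, conditionMessage(e))
                    })
    for (field in c("id", "kind", "created_utc", "body")) {
      if (is.null(obj[[field]])) {
        stop_fv("line %d: missing required field '%s'", i, field)
      }
    }
    if (!obj$kind %in% c("post", "comment")) {
      stop_fv("line %d: unknown kind '%s'", i, obj$kind)
    }
    parsed[[i]] <- data.frame(
      id = as.character(obj$id), kind = as.character(obj$kind),
      created_utc = as.numeric(obj$created_utc),
      title = if (is.null(obj$title)) NA_character_ else as.character(obj$title),
      body = as.character(obj$body),
      parent_id = if (is.null(obj$parent_id)) NA_character_ else as.character(obj$parent_id),
      stringsAsFactors = FALSE)
  }
  entries <- if (length(parsed)) do.call(rbind, parsed) else empty_entries()
  entries <- as_forum_entries(entries, window = window)
  new_corpus(entries, filter_ledger(collected = count_by_kind(entries)))
}

#' Coerce a data frame to validated forum entries
#'
#' Validates ids, kinds and timestamps, deduplicates by id (first occurrence
#' wins, with a warning) and optionally applies a half-open study window.
#'
#' @inheritParams read_corpus
#' @param entries Data frame with at least `id`, `kind`, `created_utc`, `body`.
#' @return The validated entries data frame.
#' @export
as_forum_entries <- function(entries, window = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!nrow(entries)) return(empty_entries())
  if (is.null(entries$title)) entries$title <- NA_character_
  if (is.null(entries$parent_id)) entries$parent_id <- NA_character_
  if (any(!nzchar(entries$id))) stop_fv("empty entry id")
  bad_kind <- setdiff(unique(entries$kind), c("post", "comment"))
  if (length(bad_kind)) stop_fv("unknown kind '%s'", bad_kind[[1]])
  dup <- duplicated(entries$id)
  if (any(dup)) {
    warn_fv("%d duplicate id(s) dropped (first occurrence kept)", sum(dup))
    entries <- entries[!dup, , drop = FALSE]
  }
  # comments carry no title
  entries$title[entries$kind == "comment"] <- NA_character_
  if (!is.null(window)) {
    bounds <- as.numeric(window)
    keep <- entries$created_utc >= bounds[[1]] & entries$created_utc < bounds[[2]]
    entries <- entries[keep, , drop = FALSE]
  }
  rownames(entries) <- NULL
  entries
}

corpus_parts <- function(x) {
  if (inherits(x, "forum_corpus")) {
    list(entries = x$entries, ledger = x$ledger)
  } else {
    entries <- as_forum_entries(x)
    list(entries = entries,
         ledger = filter_ledger(collected = count_by_kind(entries)))
  }
}

#' Retain entries that mention any of a set of drug keywords
#'
#' An entry is retained iff any keyword occurs case-insensitively as a
#' substring of its title and body (concatenated). Records the
#' `keyword_matched` stage in the corpus ledger.
#'
#' @param corpus A `forum_corpus` (from [read_corpus()]) or an entries
#'   data frame.
#' @param keywords Nonempty character vector of search terms; empty strings
#'   are an error.
#' @return A `forum_corpus` with the retained entries and updated ledger.
#' @export
filter_by_keywords <- function(corpus, keywords = c("ruxolitinib", "opzelura")) {
  if (!length(keywords)) stop_fv("keywords must be nonempty")
  if (any(!nzchar(keywords))) stop_fv("empty keyword string")
  parts <- corpus_parts(corpus)
  entries <- parts$entries
  haystack <- tolower(paste(ifelse(is.na(entries$title), "", entries$title),
                            entries$body))
  hit <- rep(FALSE, nrow(entries))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, haystack, fixed = TRUE)
  }
  entries <- entries[hit, , drop = FALSE]
  rownames(entries) <- NULL
  ledger <- parts$ledger
  ledger$keyword_matched <- count_by_kind(entries)
  new_corpus(entries, validate_ledger(ledger))
}

#' Remove deleted or empty entries
#'
#' Drops deleted or empty entries after whitespace stripping: an entry whose
#' body equals an explicit deletion marker (`"[deleted]"`, `"[removed]"`) is
#' dropped regardless of its title, since the content is gone even when the
#' title survives deletion; an entry whose body is merely blank is dropped
#' only when it has no substantive title either (title-only posts are real
#' content). Records the `empty_removed` and `final` ledger stages, with
#' `final = keyword_matched - empty_removed` per kind.
#'
#' @param corpus A `forum_corpus` or entries data frame.
#' @param markers Marker strings counting as deleted/empty content; the
#'   empty string means "blank body".
#' @return A `forum_corpus` with the retained entries and completed ledger.
#' @export
drop_empty <- function(corpus, markers = c("", "[deleted]", "[removed]")) {
  parts <- corpus_parts(corpus)
  entries <- parts$entries
  ledger <- parts$ledger
  if (is.null(ledger$keyword_matched)) {
    ledger$keyword_matched <- count_by_kind(entries)
  }
  body_trim <- trimws(entries$body)
  explicit <- body_trim %in% setdiff(markers, "")
  blank <- ("" %in% markers) & body_trim == ""
  title_empty <- is.na(entries$title) | trimws(entries$title) %in% markers
  remove <- explicit | (blank & (entries$kind == "comment" | title_empty))
  removed <- entries[remove, , drop = FALSE]
  entries <- entries[!remove, , drop = FALSE]
  rownames(entries) <- NULL
  ledger$empty_removed <- count_by_kind(removed)
  ledger$final <- ledger$keyword_matched - ledger$empty_removed
  new_corpus(entries, validate_ledger(ledger))
}

#' Normalize forum text
#'
#' Lowercases, removes characters outside letters/digits/whitespace,
#' collapses whitespace and lemmatizes each token. Idempotent:
#' `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param text Character vector.
#' @param lemmatizer A function mapping a character vector of tokens to their
#'   lemmas. Defaults to [default_lemmatizer()]; tests may pass a fixed
#'   dictionary via [dictionary_lemmatizer()].
#' @return Character vector of normalized text.
#' @export
normalize_text <- function(text, lemmatizer = default_lemmatizer) {
  text[is.na(text)] <- ""
  x <- tolower(text)
  x <- gsub("[^a-z0-9[:space:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  token_lists <- strsplit(x, " ", fixed = TRUE)
  tokens <- unlist(token_lists, use.names = FALSE)
  if (!length(tokens)) return(x)
  lens <- lengths(token_lists)
  uniq <- unique(tokens)
  lemma <- lemmatizer(uniq)
  mapped <- lemma[match(tokens, uniq)]
  out <- vapply(split(mapped, rep(seq_along(lens), lens)),
                paste, character(1), collapse = " ")
  res <- character(length(x))
  res[lens > 0] <- out
  res
}

#' Suffix-rule lemmatizer
#'
#' A small dictionary + suffix-rule lemmatizer standing in for a full WordNet
#' lookup: strips plural endings (`-ies`, `-sses`, `-s`) and verbal endings
#' (`-ing`, `-ed`) with a minimum stem length and final-consonant
#' undoubling. Rules are applied to a fixpoint so the map is idempotent
#' (`default_lemmatizer(default_lemmatizer(w)) == default_lemmatizer(w)`),
#' which in turn makes [normalize_text()] idempotent.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas, same length.
#' @export
default_lemmatizer <- function(tokens) {
  vapply(tokens, lemma_fixpoint, character(1), USE.NAMES = FALSE)
}

lemma_exceptions <- c(
  feet = "foot", teeth = "tooth", men = "man", women = "woman",
  children = "child", people = "person", was = "be", is = "be", are = "be",
  has = "have", does = "do", better = "good", worse = "bad"
)

lemma_step <- function(w) {
  if (w %in% names(lemma_exceptions)) return(unname(lemma_exceptions[[w]]))
  n <- nchar(w)
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 4 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
  if (n > 3 && endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us") &&
      !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  for (suf in c("ing", "ed")) {
    if (endsWith(w, suf) && n - nchar(suf) >= 3) {
      stem <- substr(w, 1, n - nchar(suf))
      m <- nchar(stem)
      last <- substr(stem, m, m)
      if (m >= 4 && last == substr(stem, m - 1, m - 1) && !last %in% c("l", "s", "z")) {
        stem <- substr(stem, 1, m - 1)
      }
      return(stem)
    }
  }
  w
}

lemma_fixpoint <- function(w) {
  repeat {
    w2 <- lemma_step(w)
    if (identical(w2, w)) return(w)
    w <- w2
  }
}

#' Dictionary lemmatizer factory
#'
#' Builds a lemmatizer from a fixed token-to-lemma dictionary; tokens not in
#' the dictionary pass through unchanged. Useful for reproducible tests.
#'
#' @param dict Named character vector, `names(dict)` are surface tokens.
#' @return A function usable as the `lemmatizer` argument of
#'   [normalize_text()].
#' @export
dictionary_lemmatizer <- function(dict) {
  force(dict)
  function(tokens) {
    hit <- match(tokens, names(dict))
    out <- tokens
    out[!is.na(hit)] <- unname(dict[hit[!is.na(hit)]])
    out
  }
}

#' Write entries as newline-delimited JSON
#'
#' Emits the same NDJSON dialect [read_corpus()] reads; `NA` titles and
#' parent ids are omitted from the JSON objects.
#'
#' @param entries Entries data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_ndjson <- function(entries, path) {
  lines <- vapply(seq_len(nrow(entries)), function(i) {
    obj <- list(id = entries$id[[i]], kind = entries$kind[[i]],
                created_utc = entries$created_utc[[i]])
    if (!is.na(entries$title[[i]])) obj$title <- entries$title[[i]]
    obj$body <- entries$body[[i]]
    if (!is.na(entries$parent_id[[i]])) obj$parent_id <- entries$parent_id[[i]]
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export entries as CSV
#'
#' Writes `id`, `kind`, `month` (YYYY-MM, UTC) and `normalized_text`.
#'
#' @param entries Entries data frame.
#' @param path Output file path.
#' @param lemmatizer Passed to [normalize_text()].
#' @return `path`, invisibly.
#' @export
export_entries_csv <- function(entries, path, lemmatizer = default_lemmatizer) {
  out <- data.frame(
    id = entries$id, kind = entries$kind,
    month = format(utc_time(entries$created_utc), "%Y-%m"),
    normalized_text = normalize_text(
      paste(ifelse(is.na(entries$title), "", entries$title), entries$body),
      lemmatizer = lemmatizer),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

utc_time <- function(seconds) {
  as.POSIXct(seconds, origin = "1970-01-01", tz = "UTC")
}

#' UNIX timestamp of a UTC date-time string
#'
#' Convenience wrapper used for study windows, e.g.
#' `utc_seconds("2022-01-01")`.
#'
#' @param x Date or date-time string understood in UTC.
#' @return Numeric UNIX seconds.
#' @export
utc_seconds <- function(x) {
  as.numeric(as.POSIXct(x, tz = "UTC"))
}
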