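test_that("read_corpus parses NDJSON, counts by kind and applies the window", {
  objs <- list(
    list(id = "p1", kind = "post", created_utc = utc_seconds("2022-02-01"),
         title = "t", body = "opzelura works"),
    list(id = "p2", kind = "post", created_utc = utc_seconds("2022-03-01"),
         title = "t", body = "b"),
    list(id = "p3", kind = "post", created_utc = utc_seconds("2022-04-01"),
         title = "t", body = "b"),
    list(id = "c1", kind = "comment", created_utc = utc_seconds("2022-05-01"),
         body = "b", parent_id = "p1"),
    list(id = "c2", kind = "comment", created_utc = utc_seconds("2023-05-01"),
         body = "b", parent_id = "p1"))
  path <- write_ndjson(objs)
  fc <- read_corpus(path)
  expect_equal(nrow(fc$entries), 5)
  expect_equal(fc$ledger$collected, c(post = 3L, comment = 2L))
  expect_identical(fc$entries$id, c("p1", "p2", "p3", "c1", "c2"))
  expect_true(is.na(fc$entries$title[fc$entries$id == "c1"]))

  # half-open window excluding the last comment
  fc2 <- read_corpus(path, window = utc_seconds(c("2022-01-01", "2023-01-01")))
  expect_equal(nrow(fc2$entries), 4)
  expect_equal(fc2$ledger$collected, c(post = 3L, comment = 1L))
})

test_that("read_corpus errors name the offending line", {
  path <- tempfile()
  writeLines(c('{"id":"a","kind":"post","created_utc":1,"body":"x"}',
               '{"id":"b", oops'), path)
  expect_error(read_corpus(path), "line 2")
  path2 <- write_ndjson(list(list(id = "a", kind = "reply",
                                  created_utc = 1, body = "x")))
  expect_error(read_corpus(path2), "unknown kind")
})

test_that("duplicate ids keep the first occurrence with a warning", {
  e <- make_entries(c("one", "two"), ids = c("dup", "dup"))
  expect_warning(out <- as_forum_entries(e), "duplicate")
  expect_equal(nrow(out), 1)
  expect_equal(out$body, "one")
})

test_that("keyword filter retains case-insensitive substring matches only", {
  e <- make_entries(c("Opzelura worked", "UVB only", "generic ruxolitinib cream"))
  fc <- filter_by_keywords(e, c("ruxolitinib", "opzelura"))
  expect_equal(nrow(fc$entries), 2)
  expect_equal(sum(fc$ledger$keyword_matched), 2)

  shout <- filter_by_keywords(make_entries("OPZELURA!!!"), "opzelura")
  expect_equal(nrow(shout$entries), 1)

  none <- drop_empty(filter_by_keywords(make_entries(c("aaa", "bbb")), "opzelura"))
  expect_equal(nrow(none$entries), 0)
  expect_equal(ledger_total(none$ledger, "final"), 0)

  expect_error(filter_by_keywords(e, character()), "nonempty")
  expect_error(filter_by_keywords(e, c("opzelura", "")), "empty keyword")
})

test_that("keyword filter matches in the title too and is monotone in keywords", {
  e <- make_entries(rep("no drug here", 3),
                    titles = c("Opzelura question", "hello", "ruxo"))
  fc <- filter_by_keywords(e, "opzelura")
  expect_equal(fc$entries$id, "x001")

  set.seed(42)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon")
  bodies <- replicate(40, paste(sample(words, 3), collapse = " "))
  e2 <- make_entries(bodies)
  for (k in 1:4) {
    small <- filter_by_keywords(e2, words[seq_len(k)])$entries$id
    bigger <- filter_by_keywords(e2, words[seq_len(k + 1)])$entries$id
    expect_true(all(small %in% bigger))
  }
})

test_that("drop_empty removes marker bodies and keeps the ledger consistent", {
  e <- make_entries(c("[deleted]", "  ", "real content", "[removed]"),
                    kinds = c("post", "comment", "comment", "comment"))
  fc <- drop_empty(e)
  expect_equal(nrow(fc$entries), 1)
  expect_equal(fc$ledger$final,
               fc$ledger$keyword_matched - fc$ledger$empty_removed)

  # a post with empty body but a substantive title is kept
  p <- make_entries("", titles = "Opzelura experiences?")
  expect_equal(nrow(drop_empty(p)$entries), 1)

  all_deleted <- make_entries(rep("[deleted]", 3))
  expect_equal(nrow(drop_empty(all_deleted)$entries), 0)

  no_empty <- make_entries(c("a", "b"))
  led <- drop_empty(no_empty)$ledger
  expect_equal(led$final, led$keyword_matched)
})

test_that("normalize_text lowercases, strips specials, lemmatizes, and is idempotent", {
  expect_equal(normalize_text("Opzelura WORKS!!!",
                              lemmatizer = dictionary_lemmatizer(c(works = "works"))),
               "opzelura works")
  expect_equal(normalize_text("creams spots",
                              lemmatizer = dictionary_lemmatizer(
                                c(creams = "cream", spots = "spot"))),
               "cream spot")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("creams spots"), "cream spot")

  set.seed(7)
  pool <- c("Opzelura!!", "WORKING", "spots,", "stories", "running", "e-mail",
            "5% better", "(UV-B)", "applied", "fading...", "stringing")
  for (i in 1:25) {
    x <- paste(sample(pool, sample(1:6, 1), replace = TRUE), collapse = " ")
    once <- normalize_text(x)
    expect_identical(normalize_text(once), once)
    expect_false(grepl("[^a-z0-9 ]", once))
  }
})

test_that("ledger stage counts are conserved and exports round-trip", {
  lc <- small_labeled_corpus()
  fc <- drop_empty(filter_by_keywords(lc$entries))
  led <- fc$ledger
  for (stage in names(led)) expect_true(all(led[[stage]] >= 0))
  expect_equal(led$final, led$keyword_matched - led$empty_removed)
  expect_equal(ledger_total(led, "final"), nrow(fc$entries))

  path <- tempfile(fileext = ".ndjson")
  write_corpus_ndjson(fc$entries, path)
  back <- read_corpus(path)
  expect_equal(back$entries$id, fc$entries$id)
  expect_equal(back$entries$body, fc$entries$body)
  expect_equal(back$entries$created_utc, fc$entries$created_utc)

  csv <- tempfile(fileext = ".csv")
  export_entries_csv(utils::head(fc$entries, 5), csv)
  got <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(names(got), c("id", "kind", "month", "normalized_text"))
  expect_equal(nrow(got), 5)
})
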