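# shared fixtures and independent oracles

make_entries <- function(bodies, kinds = rep("post", length(bodies)),
                         titles = NULL, times = NULL, ids = NULL) {
  n <- length(bodies)
  data.frame(
    id = ids %||% sprintf("x%03d", seq_len(n)),
    kind = kinds,
    created_utc = times %||% (utc_seconds("2022-06-15") + seq_len(n)),
    title = titles %||% ifelse(kinds == "post", "a title", NA_character_),
    body = bodies,
    parent_id = NA_character_,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_ndjson <- function(objs, path = tempfile(fileext = ".ndjson")) {
  writeLines(vapply(objs, function(o) {
    as.character(jsonlite::toJSON(o, auto_unbox = TRUE))
  }, character(1)), path)
  path
}

# brute-force signed-rank oracle: enumerate all 2^m sign assignments
wilcoxon_enum_oracle <- function(diffs) {
  d <- diffs[diffs != 0]
  m <- length(d)
  stopifnot(m >= 1, m <= 12)
  r <- rank(abs(d))
  total <- sum(r)
  W_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  wpos <- as.numeric(signs %*% r)
  p <- (sum(wpos <= W_obs + 1e-9) + sum(wpos >= total - W_obs - 1e-9)) / 2^m
  list(W = W_obs, p = min(1, p))
}

# stub embedding backend mapping known texts to fixed vectors
stub_backend <- function(map) {
  list(name = "stub", dim = length(map[[1]]),
       embed = function(texts) {
         do.call(rbind, lapply(texts, function(tx) {
           if (is.null(map[[tx]])) stop("stub backend: unknown text ", tx)
           map[[tx]]
         }))
       })
}

# small deterministic corpus for pipeline-level tests
small_labeled_corpus <- function(seed = 101, n = 600) {
  generate_corpus(generator_config(n_entries = n, seed = seed))
}
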