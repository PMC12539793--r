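#' Seeded token-hashing embedding backend
#'
#' A deterministic, download-free embedding backend: each token is hashed to
#' one of `dim` coordinates with a pseudo-random sign, a document vector is
#' the signed token-count vector scaled to unit Euclidean norm. Documents
#' sharing no tokens are orthogonal up to hash collisions, so cosine
#' similarity reduces to (signed) token overlap — enough structure for the
#' prototype-centroid classifier to be exercised end to end without a
#' pretrained model. A transformer-based backend can be supplied through the
#' same contract (a list with `name`, `dim` and `embed(texts)` returning one
#' row per text).
#'
#' @param dim Embedding dimension.
#' @param seed Integer mixed into the token hash; fixed seed + fixed input
#'   gives identical vectors.
#' @return An `embedding_backend` object.
#' @export
hashing_backend <- function(dim = 512L, seed = 42L) {
  dim <- as.integer(dim)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  token_codes <- function(tokens) {
    new <- tokens[!vapply(tokens, exists, logical(1), envir = cache)]
    for (tok in unique(new)) {
      codes <- utf8ToInt(tok)
      h1 <- seed %% 2147483647
      h2 <- (seed + 101) %% 2147483647
      for (cc in codes) {
        h1 <- (h1 * 31 + cc) %% 2147483647
        h2 <- (h2 * 37 + cc) %% 2147482951
      }
      assign(tok, c(h1 %% dim + 1, if (h2 %% 2 == 0) 1 else -1), envir = cache)
    }
    vapply(tokens, get, numeric(2), envir = cache)
  }
  backend <- list(
    name = sprintf("hashing-%d-seed%d", dim, seed),
    dim = dim,
    seed = seed,
    embed = function(texts) {
      if (any(!nzchar(trimws(texts)))) {
        stop_fv("input invalid: cannot embed empty text")
      }
      token_lists <- strsplit(trimws(texts), "[[:space:]]+")
      n <- length(texts)
      mat <- matrix(0, nrow = n, ncol = dim)
      all_tokens <- unique(unlist(token_lists, use.names = FALSE))
      codes <- token_codes(all_tokens)
      for (i in seq_len(n)) {
        tk <- token_lists[[i]]
        cc <- codes[, match(tk, all_tokens), drop = FALSE]
        for (j in seq_along(tk)) {
          mat[i, cc[1, j]] <- mat[i, cc[1, j]] + cc[2, j]
        }
      }
      norms <- sqrt(rowSums(mat^2))
      if (any(norms == 0)) {
        stop_fv("input invalid: text hashed to the zero vector")
      }
      mat / norms
    }
  )
  structure(backend, class = "embedding_backend")
}

#' Embed texts with a backend
#'
#' @param texts Character vector of (normalized) nonempty texts.
#' @param backend An `embedding_backend`, e.g. [hashing_backend()].
#' @return Numeric matrix, one unit-norm row per text.
#' @export
embed_text <- function(texts, backend = hashing_backend()) {
  if (!is.list(backend) || !is.function(backend$embed)) {
    stop_fv("model not installed: backend does not provide an embed() function")
  }
  backend$embed(texts)
}

#' Cosine similarity
#'
#' `dot(u, v) / (|u| |v|)`; symmetric and scale-invariant, in `[-1, 1]`.
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return Cosine similarity.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop_fv("cosine: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_fv("cosine: zero vector")
  sum(u * v) / (nu * nv)
}

#' Build prototype sets from a cluster configuration
#'
#' Each substantive cluster is anchored by a list of prototype phrases; the
#' cluster centroid is the arithmetic mean of the phrase embeddings
#' (computed on normalized phrases, matching the preprocessing applied to
#' corpus entries).
#'
#' @param phrases Named list mapping cluster name to a nonempty character
#'   vector of phrases. Names must be among [fv_clusters()].
#' @param backend Embedding backend.
#' @param lemmatizer Passed to [normalize_text()].
#' @return List of `prototype_set` objects (fields `cluster`, `phrases`,
#'   `centroid`), in fixed cluster order.
#' @export
build_prototype_sets <- function(phrases, backend = hashing_backend(),
                                 lemmatizer = default_lemmatizer) {
  unknown <- setdiff(names(phrases), fv_clusters())
  if (length(unknown)) stop_fv("unknown cluster name '%s'", unknown[[1]])
  lapply(intersect(fv_clusters(), names(phrases)), function(cl) {
    ph <- phrases[[cl]]
    if (!length(ph)) stop_fv("cluster '%s' has no prototype phrases", cl)
    emb <- embed_text(normalize_text(ph, lemmatizer = lemmatizer), backend)
    structure(list(cluster = cl, phrases = ph, centroid = colMeans(emb)),
              class = "prototype_set")
  })
}

#' Assign one entry to a cluster by prototype-centroid similarity
#'
#' Computes cosine similarity between the entry embedding and every cluster
#' centroid; the label is the argmax if the best similarity reaches the
#' abstention threshold `tau`, otherwise `"off_topic"`. Exact similarity ties
#' break by the fixed cluster order of [fv_clusters()]. Empty normalized text
#' yields `"off_topic"` with `NA` similarities.
#'
#' @param text Normalized entry text (single string).
#' @param id Entry id.
#' @param sets Prototype sets from [build_prototype_sets()].
#' @param tau Abstention threshold in `[0, 1)`.
#' @param backend Embedding backend.
#' @return A one-row assignment data frame: `entry_id`, `label`, one
#'   `sim_<cluster>` column per substantive cluster, `overridden`.
#' @export
assign_cluster <- function(text, id, sets, tau = 0.25,
                           backend = hashing_backend()) {
  classify_entries(data.frame(entry_id = id, text = text,
                              stringsAsFactors = FALSE),
                   sets, tau = tau, backend = backend)
}

classify_entries <- function(docs, sets, tau, backend) {
  if (tau < 0 || tau >= 1) stop_fv("tau must be in [0, 1)")
  clusters <- vapply(sets, `[[`, character(1), "cluster")
  centroids <- do.call(rbind, lapply(sets, `[[`, "centroid"))
  cnorm <- sqrt(rowSums(centroids^2))
  if (any(cnorm == 0)) stop_fv("cosine: zero vector centroid")
  n <- nrow(docs)
  sims <- matrix(NA_real_, n, length(clusters),
                 dimnames = list(NULL, clusters))
  nonempty <- nzchar(trimws(docs$text))
  if (any(nonempty)) {
    emb <- embed_text(docs$text[nonempty], backend)
    enorm <- sqrt(rowSums(emb^2))
    if (any(enorm == 0)) stop_fv("cosine: zero vector embedding")
    sims[nonempty, ] <- (emb %*% t(centroids)) / outer(enorm, cnorm)
  }
  label <- rep("off_topic", n)
  if (any(nonempty)) {
    best <- max.col(sims[nonempty, , drop = FALSE], ties.method = "first")
    bestval <- sims[nonempty, , drop = FALSE][cbind(seq_len(sum(nonempty)), best)]
    lab <- ifelse(bestval >= tau, clusters[best], "off_topic")
    label[nonempty] <- lab
  }
  out <- data.frame(entry_id = docs$entry_id, label = label,
                    stringsAsFactors = FALSE)
  for (j in seq_along(clusters)) {
    out[[paste0("sim_", clusters[[j]])]] <- sims[, j]
  }
  out$overridden <- FALSE
  out
}

#' Validate keyword-override lists
#'
#' Override lists must be disjoint across clusters; overlap is a
#' configuration error.
#'
#' @param override_lists Named list mapping cluster name to a character
#'   vector of override keywords.
#' @return The validated lists, invisibly.
#' @export
validate_override_lists <- function(override_lists) {
  unknown <- setdiff(names(override_lists), fv_clusters())
  if (length(unknown)) stop_fv("unknown cluster name '%s'", unknown[[1]])
  all_kw <- tolower(unlist(override_lists, use.names = FALSE))
  if (anyDuplicated(all_kw)) {
    stop_fv("override keyword lists overlap across clusters ('%s')",
            all_kw[duplicated(all_kw)][[1]])
  }
  invisible(override_lists)
}

#' Apply the keyword override to assignments
#'
#' If exactly one cluster's override list matches an entry (case-insensitive
#' substring of its raw text) and that cluster differs from the semantic
#' label, the entry is reassigned with `overridden = TRUE`. If lists from
#' several clusters match, the semantic label is kept and a warning is
#' logged. Similarities are never modified.
#'
#' @param texts Character vector of raw entry texts (title + body), parallel
#'   to `assignments`.
#' @param assignments Assignment data frame from [classify_entries()] /
#'   [assign_cluster()].
#' @param override_lists Named list of per-cluster keyword vectors (validated
#'   with [validate_override_lists()]).
#' @return The assignments with overrides applied.
#' @export
keyword_override <- function(texts, assignments, override_lists) {
  validate_override_lists(override_lists)
  if (length(texts) != nrow(assignments)) {
    stop_fv("texts and assignments length mismatch")
  }
  haystack <- tolower(texts)
  match_mat <- sapply(fv_clusters(), function(cl) {
    kws <- tolower(override_lists[[cl]] %||% character())
    hit <- rep(FALSE, length(haystack))
    for (kw in kws) hit <- hit | grepl(kw, haystack, fixed = TRUE)
    hit
  })
  match_mat <- matrix(match_mat, ncol = length(fv_clusters()),
                      dimnames = list(NULL, fv_clusters()))
  n_match <- rowSums(match_mat)
  multi <- n_match > 1
  if (any(multi)) {
    warn_fv("%d entr%s matched override keywords from multiple clusters; semantic label kept",
            sum(multi), if (sum(multi) == 1) "y" else "ies")
  }
  single <- which(n_match == 1)
  for (i in single) {
    target <- fv_clusters()[which(match_mat[i, ])]
    if (!identical(target, assignments$label[[i]])) {
      assignments$label[[i]] <- target
      assignments$overridden[[i]] <- TRUE
    }
  }
  assignments
}

#' Classify a corpus into thematic clusters
#'
#' Full semisupervised classification: embed every entry, score it against
#' each prototype centroid, apply the abstention threshold, then the keyword
#' override. Per-entry labels are independent of entry order.
#'
#' @param entries Entries data frame (see [read_corpus()]).
#' @param sets Prototype sets from [build_prototype_sets()].
#' @param tau Abstention threshold.
#' @param override_lists Optional named list of per-cluster override
#'   keywords.
#' @param backend Embedding backend.
#' @param lemmatizer Passed to [normalize_text()].
#' @return List with `assignments` (data frame) and `counts` (named integer
#'   vector over [fv_all_labels()], summing to `nrow(entries)`).
#' @export
classify_corpus <- function(entries, sets, tau = 0.25, override_lists = NULL,
                            backend = hashing_backend(),
                            lemmatizer = default_lemmatizer) {
  raw <- paste(ifelse(is.na(entries$title), "", entries$title), entries$body)
  docs <- data.frame(entry_id = entries$id,
                     text = normalize_text(raw, lemmatizer = lemmatizer),
                     stringsAsFactors = FALSE)
  assignments <- classify_entries(docs, sets, tau = tau, backend = backend)
  if (!is.null(override_lists)) {
    assignments <- keyword_override(raw, assignments, override_lists)
  }
  counts <- table(factor(assignments$label, levels = fv_all_labels()))
  list(assignments = assignments,
       counts = setNames(as.integer(counts), fv_all_labels()))
}

#' Default cluster configuration
#'
#' Ships seven prototype phrases per substantive cluster plus per-cluster
#' override keywords. The original study's phrase and keyword lists are
#' unpublished; these are reconstructions written from the clusters'
#' published descriptions (repigmentation/improvement phrasing for therapy
#' success; application-site acne/fatigue phrasing for side effects;
#' copay/denial phrasing for insurance and cost) and should be tuned for any
#' new corpus via a YAML/JSON config ([load_cluster_config()]).
#'
#' @return List with `clusters` (per-cluster `phrases` and
#'   `override_keywords`), `tau`, `backend`, `seed`.
#' @export
default_cluster_config <- function() {
  list(
    clusters = list(
      therapy_success = list(
        phrases = c(
          "face repigmentation progress with uvb phototherapy",
          "spot patch fading, new pigment on face",
          "eyelid face repigmented, steady progress",
          "uvb phototherapy helping patch repigmentation",
          "hair repigmented, white spot fading",
          "pigment returning, face patch repigmented",
          "repigmentation progress, spot closing, phototherapy"),
        override_keywords = c("fully repigmented", "cleared up completely")),
      side_effects = list(
        phrases = c(
          "acne on application site",
          "redness itchiness irritation on application site",
          "fatigue headache since starting treatment",
          "nausea dizziness flare after applying",
          "anemia fatigue dizziness daily",
          "application site acne redness irritation",
          "itchiness headache nausea flare"),
        override_keywords = c("side effect", "black box warning")),
      insurance_cost = list(
        phrases = c(
          "insurance denied coverage, appealing now",
          "copay assistance from manufacturer pharmacy",
          "prior authorization denied by insurance",
          "cost price two thousand dollars",
          "deductible copay, pharmacy assistance program",
          "insurance calls it cosmetic, coverage denied",
          "manufacturer assistance brought cost price down"),
        override_keywords = c("prior authorization", "insurance denied"))),
    tau = 0.25,
    backend = "hashing",
    seed = 42L)
}

#' Read a cluster configuration from YAML or JSON
#'
#' Expected shape mirrors [default_cluster_config()]: per-cluster `phrases`
#' and optional `override_keywords`, plus `tau`, `backend`, `seed`. Override
#' lists are validated for cross-cluster disjointness at load time.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
load_cluster_config <- function(path) {
  config <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  config$tau <- config$tau %||% 0.25
  validate_override_lists(config_override_lists(config))
  config
}

config_phrases <- function(config) {
  lapply(config$clusters, function(cl) cl$phrases)
}

config_override_lists <- function(config) {
  lists <- lapply(config$clusters, function(cl) cl$override_keywords)
  lists[!vapply(lists, is.null, logical(1))]
}
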