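test_that("hashing backend is deterministic, unit-norm, and separates disjoint texts", {
  be <- hashing_backend()
  e1 <- embed_text("face repigmentation uvb", be)
  e2 <- embed_text("face repigmentation uvb", be)
  expect_identical(e1, e2)
  expect_equal(sqrt(sum(e1^2)), 1, tolerance = 1e-9)

  # no shared tokens, no hash collisions in this fixture vocabulary
  e <- embed_text(c("alpha bravo charlie", "delta echo foxtrot"), be)
  expect_equal(cosine(e[1, ], e[2, ]), 0)

  expect_error(embed_text("", be), "empty")
  expect_error(embed_text("x", list(name = "broken")), "embed")
})

test_that("cosine matches hand computations and rejects degenerate input", {
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(2, 4, 6), c(1, 2, 3)), 1)
  expect_equal(cosine(c(1, 2, 3), c(4, 5, 6)), 32 / sqrt(14 * 77),
               tolerance = 1e-9)
  expect_equal(cosine(c(1, 2, 3), c(4, 5, 6)), 0.974632, tolerance = 1e-6)
  expect_equal(cosine(c(1, 2), c(10, 20)), cosine(c(1, 2), c(1, 2)))
  expect_error(cosine(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("prototype centroids are phrase-order-invariant arithmetic means", {
  be <- hashing_backend()
  one <- build_prototype_sets(list(therapy_success = "face repigmentation"), be)
  expect_equal(one[[1]]$centroid,
               as.numeric(embed_text("face repigmentation", be)))

  twice <- build_prototype_sets(
    list(therapy_success = rep("face repigmentation", 2)), be)
  expect_equal(twice[[1]]$centroid, one[[1]]$centroid)

  ph <- c("acne site", "fatigue headache", "nausea flare")
  a <- build_prototype_sets(list(side_effects = ph), be)
  b <- build_prototype_sets(list(side_effects = rev(ph)), be)
  expect_equal(a[[1]]$centroid, b[[1]]$centroid)

  expect_error(build_prototype_sets(list(bogus_cluster = "x"), be), "unknown")
  expect_error(build_prototype_sets(list(side_effects = character()), be),
               "no prototype")
})

test_that("assignment follows the thresholded argmax with fixed-order tie-break", {
  map <- list(doc = c(0.8, 0.6, 0), a = c(1, 0, 0), b = c(0.6, 0.8, 0),
              tie = c(1, 0, 0))
  be <- stub_backend(map)
  sets <- list(
    structure(list(cluster = "therapy_success", phrases = "a",
                   centroid = c(1, 0, 0)), class = "prototype_set"),
    structure(list(cluster = "side_effects", phrases = "b",
                   centroid = c(0.6, 0.8, 0)), class = "prototype_set"))
  out <- assign_cluster("doc", "d1", sets, tau = 0.25, backend = be)
  expect_equal(out$sim_therapy_success, 0.8, tolerance = 1e-12)
  expect_equal(out$sim_side_effects, 0.96, tolerance = 1e-12)
  expect_equal(out$label, "side_effects")

  # below threshold -> off_topic
  high_tau <- assign_cluster("doc", "d1", sets, tau = 0.99, backend = be)
  expect_equal(high_tau$label, "off_topic")

  # document identical to a sole prototype phrase
  self <- assign_cluster("a", "d2", sets, tau = 0.25, backend = be)
  expect_equal(self$label, "therapy_success")
  expect_equal(self$sim_therapy_success, 1, tolerance = 1e-12)

  # exact tie between a cluster and an equally similar one breaks by order
  sets_tie <- list(
    structure(list(cluster = "therapy_success", phrases = "t",
                   centroid = c(1, 0, 0)), class = "prototype_set"),
    structure(list(cluster = "side_effects", phrases = "t",
                   centroid = c(2, 0, 0)), class = "prototype_set"))
  tie <- assign_cluster("tie", "d3", sets_tie, tau = 0.1, backend = be)
  expect_equal(tie$label, "therapy_success")

  # empty text -> off_topic with NA similarities
  emp <- assign_cluster("", "d4", sets, tau = 0.25, backend = be)
  expect_equal(emp$label, "off_topic")
  expect_true(is.na(emp$sim_therapy_success))
  expect_false(emp$overridden)

  expect_error(assign_cluster("doc", "d", sets, tau = 1, backend = be), "tau")
})

test_that("assignment matches an exhaustive brute-force cosine argmax on toy vectors", {
  set.seed(11)
  dims <- 4
  centroid_vecs <- list(therapy_success = runif(dims), side_effects = runif(dims),
                        insurance_cost = runif(dims))
  sets <- lapply(names(centroid_vecs), function(cl) {
    structure(list(cluster = cl, phrases = cl, centroid = centroid_vecs[[cl]]),
              class = "prototype_set")
  })
  docs <- paste0("doc", 1:10)
  map <- stats::setNames(lapply(docs, function(d) runif(dims)), docs)
  be <- stub_backend(map)
  tau <- 0.5
  for (d in docs) {
    got <- assign_cluster(d, d, sets, tau = tau, backend = be)
    sims <- vapply(centroid_vecs, function(cv) cosine(map[[d]], cv), numeric(1))
    want <- if (max(sims) >= tau) names(sims)[which.max(sims)] else "off_topic"
    expect_equal(got$label, want)
    expect_equal(unlist(got[paste0("sim_", names(sims))], use.names = FALSE),
                 unname(sims), tolerance = 1e-12)
  }
})

test_that("keyword override reassigns on a unique cross-cluster match only", {
  base <- data.frame(entry_id = "e1", label = "therapy_success",
                     sim_therapy_success = 0.9, sim_side_effects = 0.1,
                     sim_insurance_cost = 0.1, overridden = FALSE,
                     stringsAsFactors = FALSE)
  lists <- list(insurance_cost = c("prior authorization"),
                side_effects = c("black box"))
  out <- keyword_override("they need Prior Authorization first", base, lists)
  expect_equal(out$label, "insurance_cost")
  expect_true(out$overridden)
  expect_equal(out$sim_therapy_success, 0.9)  # similarities untouched

  unchanged <- keyword_override("no markers here", base, lists)
  expect_equal(unchanged$label, "therapy_success")
  expect_false(unchanged$overridden)

  expect_warning(
    multi <- keyword_override("prior authorization and black box", base, lists),
    "multiple")
  expect_equal(multi$label, "therapy_success")
  expect_false(multi$overridden)

  # a match agreeing with the semantic label is not an override
  same <- keyword_override("black box",
                           transform(base, label = "side_effects"), lists)
  expect_false(same$overridden)

  expect_error(validate_override_lists(list(side_effects = "copay",
                                            insurance_cost = "copay")),
               "overlap")
})

test_that("corpus classification conserves counts and is permutation-invariant", {
  be <- hashing_backend()
  cfg <- default_cluster_config()
  sets <- build_prototype_sets(lapply(cfg$clusters, `[[`, "phrases"), be)
  phrase <- cfg$clusters$therapy_success$phrases[[1]]
  e <- make_entries(rep(phrase, 10))
  res <- classify_corpus(e, sets, tau = 0.25, backend = be)
  expect_equal(unname(res$counts["therapy_success"]), 10L)
  expect_equal(sum(res$counts), 10L)

  lc <- small_labeled_corpus(seed = 5, n = 200)
  res1 <- classify_corpus(lc$entries, sets, tau = 0.25, backend = be)
  perm <- sample(nrow(lc$entries))
  res2 <- classify_corpus(lc$entries[perm, ], sets, tau = 0.25, backend = be)
  m <- match(res1$assignments$entry_id, res2$assignments$entry_id)
  expect_identical(res1$assignments$label, res2$assignments$label[m])
  expect_equal(sum(res1$counts), nrow(lc$entries))
})

test_that("raising the abstention threshold never decreases the off-topic count", {
  be <- hashing_backend()
  cfg <- default_cluster_config()
  sets <- build_prototype_sets(lapply(cfg$clusters, `[[`, "phrases"), be)
  lc <- small_labeled_corpus(seed = 9, n = 300)
  previous <- -1L
  for (tau in c(0.1, 0.25, 0.5, 0.9)) {
    n_off <- classify_corpus(lc$entries, sets, tau = tau,
                             backend = be)$counts[["off_topic"]]
    expect_gte(n_off, previous)
    previous <- n_off
  }
})

test_that("cluster config round-trips through YAML and JSON", {
  cfg <- default_cluster_config()
  expect_true(all(lengths(lapply(cfg$clusters, `[[`, "phrases")) == 7))

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  cfg_y <- load_cluster_config(yml)
  expect_equal(cfg_y$clusters$side_effects$phrases,
               cfg$clusters$side_effects$phrases)
  expect_equal(cfg_y$tau, 0.25)

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  cfg_j <- load_cluster_config(jsn)
  expect_equal(cfg_j$clusters$insurance_cost$override_keywords,
               cfg$clusters$insurance_cost$override_keywords)
})
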