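test_that("largest-remainder allocation reproduces quota arithmetic", {
  alloc <- largest_remainder(500 * c(1765, 558, 491, 136) / 2950, 500)
  expect_equal(unname(alloc), c(299L, 95L, 83L, 23L))
  expect_equal(sum(alloc), 500L)

  even <- largest_remainder(c(2.5, 2.5), 5)
  expect_equal(sum(even), 5L)
  exact <- largest_remainder(c(3, 7), 10)
  expect_equal(unname(exact), c(3L, 7L))
})

test_that("proportional sampling is seeded, proportional, and handles small clusters", {
  labels <- rep(fv_all_labels(), c(1765, 558, 491, 136))
  asg <- data.frame(entry_id = sprintf("e%04d", seq_along(labels)),
                    label = labels, stringsAsFactors = FALSE)
  ids <- proportional_sample(asg, n = 500, seed = 4)
  expect_equal(length(ids), 500)
  got <- table(asg$label[match(ids, asg$entry_id)])[fv_all_labels()]
  expect_equal(unname(as.integer(got)), c(299L, 95L, 83L, 23L))

  expect_identical(ids, proportional_sample(asg, n = 500, seed = 4))
  expect_false(identical(ids, proportional_sample(asg, n = 500, seed = 5)))

  solo <- data.frame(entry_id = sprintf("s%03d", 1:600),
                     label = "therapy_success", stringsAsFactors = FALSE)
  expect_equal(length(proportional_sample(solo, n = 500, seed = 1)), 500)

  expect_error(proportional_sample(solo, n = 700, seed = 1), "exceeds")

  # drawing the whole corpus allocates every cluster exactly its size
  tiny <- data.frame(
    entry_id = sprintf("t%03d", 1:100),
    label = rep(c("therapy_success", "side_effects"), c(98, 2)),
    stringsAsFactors = FALSE)
  tiny$label[1:10] <- "off_topic"
  ids2 <- proportional_sample(tiny, n = 100, seed = 2)
  expect_setequal(ids2, tiny$entry_id)
})

test_that("confusion matrices tally gold-versus-model pairs", {
  same <- confusion_matrix(rep("side_effects", 4), rep("side_effects", 4))
  expect_equal(sum(diag(same)), 4)
  expect_equal(sum(same) - sum(diag(same)), 0)

  off <- confusion_matrix(rep("therapy_success", 3), rep("off_topic", 3))
  expect_equal(off["therapy_success", "off_topic"], 3)
  expect_equal(sum(off), 3)

  g <- c("therapy_success", "therapy_success", "side_effects",
         "insurance_cost", "off_topic", "side_effects")
  p <- c("therapy_success", "side_effects", "side_effects",
         "insurance_cost", "therapy_success", "side_effects")
  cm <- confusion_matrix(g, p)
  expect_equal(cm["therapy_success", "therapy_success"], 1)
  expect_equal(cm["therapy_success", "side_effects"], 1)
  expect_equal(cm["side_effects", "side_effects"], 2)
  expect_equal(cm["off_topic", "therapy_success"], 1)

  expect_error(confusion_matrix("bogus", "off_topic"), "unknown label")
})

test_that("accuracy, weighted F1 and kappa match hand computations", {
  diag4 <- diag(c(5, 3, 2, 1))
  dimnames(diag4) <- list(fv_all_labels(), fv_all_labels())
  expect_equal(cm_accuracy(diag4), 1)
  expect_equal(weighted_f1(diag4), 1)
  expect_equal(cohens_kappa(diag4), 1)

  cm <- matrix(c(40, 20, 10, 30), 2)  # rows gold: [[40,10],[20,30]]
  expect_equal(cm_accuracy(cm), 0.70)
  expect_equal(weighted_f1(cm), (50 * (2 * (40/60) * 0.8) / ((40/60) + 0.8) +
                                 50 * (2 * 0.75 * 0.6) / (0.75 + 0.6)) / 100,
               tolerance = 1e-12)
  expect_equal(round(weighted_f1(cm), 4), 0.697)
  expect_equal(cohens_kappa(cm), 0.40, tolerance = 1e-12)

  # degenerate chance agreement: both marginals concentrated on one class
  onecell <- matrix(c(6, 0, 0, 0), 2)
  expect_equal(cohens_kappa(onecell), 1)
})

test_that("kappa agrees with an independent implementation and vanishes under independence", {
  skip_if_not_installed("e1071")
  set.seed(14)
  for (rep in 1:10) {
    cm <- matrix(sample(0:30, 16, replace = TRUE), 4)
    ref <- e1071::classAgreement(cm)$kappa
    expect_equal(cohens_kappa(cm), ref, tolerance = 1e-10)
  }
  set.seed(15)
  g <- sample(fv_all_labels(), 10000, replace = TRUE)
  p <- sample(fv_all_labels(), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(confusion_matrix(g, p))), 0.05)
})

test_that("kappa bands use the half-open benchmark convention", {
  expect_equal(kappa_band(0.70), "substantial")
  expect_equal(kappa_band(0.801), "substantial")
  expect_equal(kappa_band(1.0), "almost perfect")
  expect_equal(kappa_band(0.81), "almost perfect")
  expect_equal(kappa_band(0.205), "slight")
  expect_equal(kappa_band(0.21), "fair")
  expect_equal(kappa_band(0.41), "moderate")
  expect_equal(kappa_band(0.005), "none")
  expect_equal(kappa_band(-0.3), "none")
  expect_error(kappa_band(1.2), "\\[-1, 1\\]")
})

test_that("metrics are invariant under a simultaneous label permutation", {
  set.seed(16)
  labs <- fv_all_labels()
  g <- sample(labs, 300, replace = TRUE)
  p <- ifelse(runif(300) < 0.8, g, sample(labs, 300, replace = TRUE))
  cm <- confusion_matrix(g, p)
  perm <- c("off_topic", "side_effects", "therapy_success", "insurance_cost")
  cmp <- confusion_matrix(g, p, labels = perm)
  expect_equal(cm_accuracy(cm), cm_accuracy(cmp))
  expect_equal(weighted_f1(cm), weighted_f1(cmp))
  expect_equal(cohens_kappa(cm), cohens_kappa(cmp))
})

test_that("the validation protocol reports perfect agreement as exactly that", {
  lc <- small_labeled_corpus(seed = 19, n = 800)
  asg <- data.frame(entry_id = names(lc$gold_labels),
                    label = unname(lc$gold_labels), stringsAsFactors = FALSE)
  rep <- validate_classifier(asg, lc$gold_labels, n = 300, seed = 2, B = 200)
  expect_equal(rep$accuracy$value, 1)
  expect_equal(rep$kappa$value, 1)
  expect_equal(rep$accuracy$ci95, c(1, 1))
  expect_equal(rep$kappa_band, "almost perfect")
  expect_equal(rep$n, 300)
})

test_that("a symmetric annotator recovers the closed-form kappa on balanced classes", {
  eps <- 0.1
  set.seed(20)
  n <- 2000
  gold <- stats::setNames(rep(fv_all_labels(), each = n / 4),
                          sprintf("b%04d", 1:n))
  asg <- data.frame(entry_id = names(gold), label = unname(gold),
                    stringsAsFactors = FALSE)
  ann <- generate_annotations(gold, epsilon = eps, seed = 77)
  rep <- validate_classifier(asg, ann, n = 500, seed = 3, B = 400)
  kappa_true <- ((1 - eps) - 0.25) / (1 - 0.25)
  expect_true(rep$kappa$ci95[1] <= kappa_true && kappa_true <= rep$kappa$ci95[2])
  expect_equal(rep$kappa$value, kappa_true, tolerance = 0.08)
})
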