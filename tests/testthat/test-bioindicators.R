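# build a minimal elimination trace by hand to test the selection rules in
# isolation from forest stochasticity
fake_trace <- function(importances, errors) {
  rounds <- mapply(function(imp, err) {
    ord <- order(-imp, names(imp))
    list(features = names(imp),
         n_features = length(imp),
         oob_error = err,
         importance = data.frame(asv_id = names(imp)[ord],
                                 importance = unname(imp[ord]),
                                 share = unname(imp[ord]) / sum(imp),
                                 rank = seq_along(imp),
                                 stringsAsFactors = FALSE))
  }, importances, errors, SIMPLIFY = FALSE)
  structure(list(rounds = rounds,
                 summary = data.frame(
                   round = seq_along(rounds),
                   n_features = vapply(rounds, `[[`, 1L, "n_features"),
                   oob_error = vapply(rounds, `[[`, 0, "oob_error")),
                 spec = rf_spec()),
            class = "elimination_trace")
}

test_that("the 1%-of-sum threshold and top-k rule select as specified", {
  imp <- c(f1 = 10, f2 = 5, f3 = 1, f4 = 0.05)
  tr <- fake_trace(list(imp), list(0.1))
  sel <- suppressWarnings(select_bioindicators(tr, threshold_share = 0.01, k = 15))
  # 1% of 16.05 = 0.1605: f4 falls below
  expect_setequal(attr(sel, "candidates"), c("f1", "f2", "f3"))
  expect_equal(sel$asv_id, c("f1", "f2", "f3", "f4")) # fewer than k: all, ranked

  sel2 <- select_bioindicators(tr, k = 2)
  expect_equal(sel2$asv_id, c("f1", "f2"))
  expect_equal(sel2$rank, 1:2)
})

test_that("selection uses the earliest minimum-error round with >= k features", {
  imps <- list(c(a = 4, b = 3, c = 2, d = 1),
               c(a = 4, c = 3, b = 2),
               c(c = 5, a = 1))
  tr <- fake_trace(imps, list(0.2, 0.1, 0.1))
  sel <- select_bioindicators(tr, k = 3)
  expect_equal(attr(sel, "best_round"), 2) # round 3 ties but holds < k features
  expect_equal(sel$asv_id, c("a", "c", "b"))
})

test_that("exact importance ties break lexicographically with a warning", {
  imp <- c(z = 1, a = 1, m = 1, b = 1)
  tr <- fake_trace(list(imp), list(0))
  expect_warning(sel <- select_bioindicators(tr, k = 2), "tied")
  expect_equal(sel$asv_id, c("a", "b"))
})

test_that("the classifier reports OOB error, Gini shares and held-out accuracy", {
  set.seed(21)
  n <- 40
  x <- matrix(runif(n * 6), n, dimnames = list(paste0("s", 1:n), paste0("f", 1:6)))
  y <- factor(rep(c("HRT8", "HRT2"), each = n / 2), levels = c("HRT8", "HRT2"))
  x[y == "HRT2", 1] <- x[y == "HRT2", 1] + 2 # one strongly informative feature
  fit <- train_hrt_classifier(x, y, fast_rf())
  expect_lt(fit$oob_error, 0.1)
  expect_equal(sum(fit$importance$share), 1)
  expect_equal(fit$importance$asv_id[1], "f1")
  expect_true(all(diff(fit$importance$importance) <= 0))

  held <- classify_heldout(fit, x, y)
  expect_gt(held$accuracy, 0.9)
  # ASVs absent from the test table are zero-filled, not an error
  held2 <- classify_heldout(fit, x[, 1:4], y)
  expect_gt(held2$accuracy, 0.9)

  expect_error(train_hrt_classifier(x, factor(rep("HRT2", n))), "single class")

  # label permutation removes the signal: OOB error near the chance level
  set.seed(2)
  fit_null <- train_hrt_classifier(x, sample(y), fast_rf(seed = 2))
  expect_gt(fit_null$oob_error, 0.25)
})

test_that("recursive elimination drops uninformative features first", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    x <- matrix(runif(n * 3), n,
                dimnames = list(paste0("s", 1:n), c("sig1", "sig2", "noise")))
    y <- factor(rep(c("HRT8", "HRT2"), each = n / 2))
    x[y == "HRT2", 1] <- x[y == "HRT2", 1] + 1.5
    x[y == "HRT2", 2] <- x[y == "HRT2", 2] + 1.5
    tr <- recursive_gini_elimination(x, y, fast_rf(seed = s))
    if (!"noise" %in% tr$rounds[[length(tr$rounds)]]$features) hits <- hits + 1L
  }
  expect_gte(hits, 4L) # univariate-separation oracle: noise goes first

  # one-per-round elimination: trace spans n_start - 1 rounds
  set.seed(1)
  x6 <- matrix(runif(120), 20,
               dimnames = list(paste0("s", 1:20), paste0("f", 1:6)))
  y6 <- factor(rep(c("HRT8", "HRT2"), each = 10))
  x6[y6 == "HRT2", 1] <- x6[y6 == "HRT2", 1] + 2
  tr6 <- recursive_gini_elimination(x6, y6, fast_rf())
  expect_equal(tr6$summary$n_features[1], 6)
  expect_equal(tail(tr6$summary$n_features, 1), 2)
  expect_lte(nrow(tr6$summary), 5) # ties may drop several at once
})

test_that("shared sets intersect by ASV id with averaged shares", {
  mk <- function(ids, shares, reactor) {
    new_bioindicator_set(
      data.frame(asv_id = ids, rank = seq_along(ids),
                 importance = shares * 10, share = shares,
                 stringsAsFactors = FALSE),
      target = "HRT", reactor = reactor)
  }
  a <- mk(c("x", "y", "z"), c(0.5, 0.3, 0.2), "A")
  b <- mk(c("y", "x", "w"), c(0.6, 0.3, 0.1), "B")
  sh <- shared_set(a, b)
  expect_setequal(sh$asv_id, c("x", "y"))
  expect_equal(sh$share[sh$asv_id == "y"], (0.3 + 0.6) / 2)
  expect_equal(sh$asv_id[1], "y") # ordered by mean share

  expect_equal(shared_set(a, a)$asv_id, a$asv_id)
  d <- mk(c("p", "q"), c(0.6, 0.4), "B")
  expect_warning(empty <- shared_set(a, d), "disjoint")
  expect_equal(nrow(empty), 0)

  c6 <- mk("x", 1, "A"); attr(c6, "target") <- "prod_C6"
  expect_error(shared_set(a, c6), "different")
})

test_that("bioindicator sets serialize with taxonomy annotation", {
  sim <- .small_sim()
  set <- new_bioindicator_set(
    data.frame(asv_id = sim$taxonomy$asv_id[1:3], rank = 1:3,
               importance = c(3, 2, 1), share = c(0.5, 0.3, 0.2),
               stringsAsFactors = FALSE),
    target = "HRT", reactor = "A")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bioindicator_set(set, tsv, taxonomy = sim$taxonomy)
  back <- read.delim(tsv)
  expect_equal(back$genus, sim$taxonomy$genus[1:3])
  js <- withr::local_tempfile(fileext = ".json")
  write_bioindicator_set(set, js)
  expect_equal(jsonlite::read_json(js)$target, "HRT")
})
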