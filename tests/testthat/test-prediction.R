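test_that("SMOTE balances toward the target while preserving originals", {
  set.seed(8)
  x <- matrix(rnorm(27 * 5), 27, dimnames = list(paste0("s", 1:27), paste0("f", 1:5)))
  y <- factor(rep(c("HRT8", "HRT2"), c(7, 20)), levels = c("HRT8", "HRT2"))
  out <- smote_oversample(x, y, smote_spec(target_total = 100, seed = 3))
  cnt <- table(out$labels)
  expect_equal(sum(cnt), 100)
  expect_true(abs(cnt[["HRT8"]] - cnt[["HRT2"]]) <= 5)
  # originals verbatim, first rows
  expect_equal(out$features[1:27, ], x)
  expect_equal(as.character(out$labels[1:27]), as.character(y))

  # every synthetic point lies within its class's componentwise bounding box
  synth <- out$features[-(1:27), ]
  sy <- out$labels[-(1:27)]
  for (cl in levels(y)) {
    xo <- x[y == cl, , drop = FALSE]
    xs <- synth[sy == cl, , drop = FALSE]
    expect_true(all(t(xs) >= apply(xo, 2, min) - 1e-12))
    expect_true(all(t(xs) <= apply(xo, 2, max) + 1e-12))
  }

  # already balanced at target: returned unchanged
  xb <- x[1:14, ]; yb <- factor(rep(c("HRT8", "HRT2"), each = 7))
  outb <- smote_oversample(xb, yb, smote_spec(target_total = 14))
  expect_equal(outb$features, xb)

  expect_error(smote_oversample(x, y, smote_spec(k_neighbors = 7)), "smaller k")
  expect_error(smote_oversample(x, factor(rep("a", 27))), "two classes")
})

test_that("synthetic SMOTE points interpolate seed and neighbor exactly", {
  # with k = 1 every synthetic point must lie on a segment between its seed
  # and that seed's single nearest same-class neighbor
  x <- matrix(c(0, 0, 1, 0, 10, 10, 11, 10, 30, 0, 31, 0), 6, 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), c("f1", "f2")))
  y <- factor(c("a", "a", "a", "a", "b", "b"))
  out <- smote_oversample(x, y, smote_spec(k_neighbors = 1, target_total = 20,
                                           seed = 5))
  synth <- out$features[-(1:6), , drop = FALSE]
  sy <- out$labels[-(1:6)]
  pairs <- list(a = list(c(0, 0), c(1, 0), c(10, 10), c(11, 10)),
                b = list(c(30, 0), c(31, 0)))
  on_segment <- function(p, u, v) {
    d <- v - u
    if (all(d == 0)) return(all(abs(p - u) < 1e-9))
    t1 <- if (d[1] != 0) (p[1] - u[1]) / d[1] else (p[2] - u[2]) / d[2]
    t1 >= -1e-9 && t1 <= 1 + 1e-9 && all(abs(u + t1 * d - p) < 1e-9)
  }
  for (i in seq_len(nrow(synth))) {
    pts <- pairs[[as.character(sy[i])]]
    ok <- FALSE
    for (u in seq_along(pts)) for (v in seq_along(pts)) {
      if (u != v && on_segment(synth[i, ], pts[[u]], pts[[v]])) ok <- TRUE
    }
    expect_true(ok)
  }
})

test_that("RRMSE is the mean-normalized RMSE in percent", {
  expect_equal(rrmse(c(10, 10), c(11, 9)), 10)
  expect_equal(rrmse(c(5, 7, 9), c(5, 7, 9)), 0)
  m <- runif(10, 1, 5); p <- m + rnorm(10, 0, 0.3)
  expect_equal(rrmse(3 * m, 3 * p), rrmse(m, p), tolerance = 1e-12) # scale-free
  expect_error(rrmse(c(0, 0), c(1, 1)), "positive")
  expect_error(rrmse(1:3, 1:4), "equal")
})

test_that("regression benchmarking recovers a realizable linear target", {
  set.seed(4)
  x <- matrix(runif(40 * 3), 40, dimnames = list(NULL, paste0("f", 1:3)))
  y <- 2 + 5 * x[, 1]
  bm <- benchmark_regressors(x, y, spec = fast_rf(), k_folds = 5)
  expect_setequal(unique(bm$algorithm), c("linear", "svm_radial", "rf"))
  expect_equal(unique(bm$dataset), "original")
  expect_equal(nrow(bm), 15) # 3 algorithms x 5 folds
  expect_true(all(bm$rmse >= 0))
  lin <- bm$rmse[bm$algorithm == "linear"]
  expect_lt(max(lin), 1e-9) # exact hypothesis class

  labs <- factor(rep(c("HRT8", "HRT2"), each = 20))
  bm2 <- benchmark_regressors(x, y, labels = labs, spec = fast_rf(),
                              smote = smote_spec(target_total = 60, seed = 1))
  expect_setequal(unique(bm2$dataset), c("original", "balanced"))
  expect_equal(nrow(bm2), 30)

  expect_error(benchmark_regressors(x, rep(1, 40)), "constant")
})

test_that("cross-reactor forest regression reports training and test metrics", {
  sim <- .small_sim()
  md <- sim$metadata
  rel <- to_relative(sim$abundance)
  lab <- !is.na(md$hrt_label)
  tr <- lab & md$reactor == "A"; te <- lab & md$reactor == "B"
  rep1 <- rf_regress(unclass(rel)[tr, ], md$prod_C6[tr],
                     unclass(rel)[te, ], md$prod_C6[te],
                     spec = fast_rf(), parameter = "prod_C6")
  expect_true(rep1$predictable)
  expect_gt(rep1$explained_variance_train, 50)
  expect_equal(length(rep1$predicted), sum(te))
  expect_equal(rep1$accuracy, 100 - rep1$rrmse)
  expect_equal(sum(rep1$importance$share), 1)
  expect_named(rep1$fit, c("slope", "intercept", "r_squared"))

  # constant training target flags the parameter as non-predictable
  repc <- rf_regress(unclass(rel)[tr, ], rep(3, sum(tr)),
                     unclass(rel)[te, ], md$prod_C6[te], spec = fast_rf())
  expect_false(repc$predictable)

  # bioindicators absent from the test table are zero-filled
  ids <- colnames(rel)[1:5]
  rep2 <- rf_regress(unclass(rel)[tr, ], md$prod_C6[tr],
                     unclass(rel)[te, 6:ncol(rel)], md$prod_C6[te],
                     asv_ids = ids, spec = fast_rf())
  expect_length(rep2$predicted, sum(te))

  expect_error(
    rf_regress(unclass(rel)[tr, ], replace(md$prod_C6[tr], 1, NA),
               unclass(rel)[te, ], md$prod_C6[te]),
    "missing target")
})

test_that("non-HRT selection returns a ranked top-15 and nulls stay null", {
  sim <- .small_sim()
  md <- sim$metadata
  rel <- unclass(to_relative(sim$abundance))
  lab <- !is.na(md$hrt_label)
  nh <- select_nonhrt_bioindicators(rel[lab, ], md$prod_C6[lab], k = 15,
                                    spec = fast_rf(), parameter = "prod_C6")
  expect_equal(nrow(nh), 15)
  expect_equal(attr(nh, "target"), "prod_C6")
  expect_equal(nh$rank, 1:15)

  # permuted parameter: importance decouples from the planted coupling
  truth <- as.numeric(colnames(rel) %in% sim$ground_truth$coupled)
  imp_cor <- function(target, s) {
    r <- select_nonhrt_bioindicators(rel[lab, ], target, k = ncol(rel),
                                     spec = fast_rf(seed = s))
    cor(r$importance[match(colnames(rel), r$asv_id)], truth,
        method = "spearman")
  }
  null_cors <- vapply(1:5, function(s) {
    set.seed(s)
    imp_cor(sample(md$prod_C6[lab]), s)
  }, 0)
  expect_lt(median(abs(null_cors)), 0.3)
  expect_gt(imp_cor(md$prod_C6[lab], 1), 0.5) # the real target is coupled
})

test_that("SMOTE works with a single nearest neighbor", {
  x <- matrix(rnorm(24), 12, 2,
              dimnames = list(paste0("s", 1:12), c("f1", "f2")))
  y <- factor(rep(c("a", "b"), c(4, 8)))
  out <- smote_oversample(x, y, smote_spec(k_neighbors = 1, target_total = 20,
                                           seed = 2))
  expect_equal(length(out$labels), 20)
})

test_that("the time-independent set is the HRT set minus the non-HRT union", {
  mk <- function(ids, target = "HRT") {
    new_bioindicator_set(
      data.frame(asv_id = ids, rank = seq_along(ids),
                 importance = rev(seq_along(ids)),
                 share = rep(1 / length(ids), length(ids)),
                 stringsAsFactors = FALSE),
      target = target, reactor = "A&B")
  }
  hrt <- mk(c("a", "b", "c", "d"))
  nh1 <- mk(c("b", "x"), "prod_C6"); nh2 <- mk(c("d", "y"), "prod_C8")
  ti <- time_independent_set(hrt, list(nh1, nh2))
  expect_equal(ti$asv_id, c("a", "c")) # order preserved from the HRT set
  expect_equal(ti$rank, 1:2)

  expect_equal(time_independent_set(hrt, mk("zzz", "p"))$asv_id, hrt$asv_id)
  expect_warning(emp <- time_independent_set(hrt, mk(c("a", "b", "c", "d"), "p")),
                 "cover")
  expect_equal(nrow(emp), 0)
})

test_that("the replicate protocol subsamples the set and applies the cutoff", {
  sim <- .small_sim()
  md <- sim$metadata
  rel <- unclass(to_relative(sim$abundance))
  lab <- !is.na(md$hrt_label)
  tr <- lab & md$reactor == "A"; te <- lab & md$reactor == "B"
  ids <- sim$ground_truth$coupled
  rr <- replicate_rrmse(rel[tr, ], md$prod_C6[tr], rel[te, ], md$prod_C6[te],
                        set = ids, n_replicates = 8, subsample_size = 3,
                        spec = fast_rf())
  expect_length(rr$rrmse, 8)
  expect_equal(rr$mean_rrmse, mean(rr$rrmse))
  expect_equal(rr$predictable, rr$mean_rrmse < 10)

  # subsample covering the whole set: only forest seeds vary
  rr2 <- replicate_rrmse(rel[tr, ], md$prod_C6[tr], rel[te, ], md$prod_C6[te],
                         set = ids[1:3], n_replicates = 4, subsample_size = 3,
                         spec = fast_rf())
  expect_lt(sd(rr2$rrmse), 5) # forest-seed variation only

  expect_error(
    replicate_rrmse(rel[tr, ], md$prod_C6[tr], rel[te, ], md$prod_C6[te],
                    set = ids[1:2], subsample_size = 3),
    "exceeds")
})
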