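make_expr <- function(v, labels, condition = "tumor") {
  meta <- data.frame(sample_id = colnames(v), subject_id = colnames(v),
                     cancer_label = labels, condition = condition,
                     stringsAsFactors = FALSE)
  expression_matrix(v, meta)
}

test_that("joint quantile normalization equalizes column distributions", {
  v1 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  v2 <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "s2"))
  out <- quantile_normalize_joint(list(make_expr(v1, "X"),
                                       make_expr(v2, "Y")))
  expect_equal(unname(out[[1]]$values[, 1]), c(5.5, 11, 16.5))
  expect_equal(unname(out[[2]]$values[, 1]), c(5.5, 11, 16.5))
  # identical columns are left unchanged
  same <- matrix(rep(c(2, 4, 9), 2), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  out2 <- quantile_normalize_joint(list(make_expr(same, "X")))
  expect_equal(out2[[1]]$values, same)
  # sorted columns identical across matrices, on random input
  set.seed(30)
  r1 <- matrix(rnorm(60), 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), paste0("a", 1:3)))
  r2 <- matrix(rexp(40), 20, 2,
               dimnames = list(sprintf("g%02d", 1:20), paste0("b", 1:2)))
  nn <- quantile_normalize_joint(list(make_expr(r1, "X"),
                                      make_expr(r2, "Y")))
  all_cols <- cbind(nn[[1]]$values, nn[[2]]$values)
  sorted <- apply(all_cols, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("centroids average training samples in module space", {
  v <- matrix(c(0, 2,
                2, 0), 2, 2, byrow = FALSE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  e <- make_expr(v, c("CA", "CA"))
  mods <- structure(list(list(module_id = 1, genes = "g1", score = NA),
                         list(module_id = 2, genes = "g2", score = NA)),
                    class = "gene_modules")
  cent <- centroid_fit(e, mods)
  expect_equal(unname(cent["CA", ]), c(1, 1))
  # one sample per cancer: centroid equals that sample's module vector
  e2 <- make_expr(v, c("X", "Y"))
  cent2 <- centroid_fit(e2, mods)
  expect_equal(unname(cent2["X", ]), c(0, 2))
  expect_equal(unname(cent2["Y", ]), c(2, 0))
})

test_that("module distance is Euclidean and satisfies metric axioms", {
  expect_equal(module_distance(c(0, 0, 0, 0, 0), c(3, 4, 0, 0, 0)), 5)
  expect_equal(module_distance(1:5, 1:5), 0)
  expect_error(module_distance(1:3, 1:4), "equal length")
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
    expect_equal(module_distance(a, b), sqrt(sum((a - b)^2)),
                 tolerance = 1e-12)
    expect_equal(module_distance(a, b), module_distance(b, a))
    expect_lte(module_distance(a, c),
               module_distance(a, b) + module_distance(b, c) + 1e-12)
  }
})

test_that("classification picks the nearest centroid, ties lexicographic", {
  cent <- rbind(A = c(0, 0), B = c(4, 0), C = c(0, 4))
  expect_identical(classify_sample(cent, c(4, 0)), "B")
  expect_identical(classify_sample(cent, c(0.1, 0.1)), "A")
  expect_identical(classify_sample(cent, c(2, 0)), "A")  # tie A vs B
})

test_that("ROC from ranking matches the Mann-Whitney pairwise oracle", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    n_pos <- sample(seq_len(n - 1), 1)
    is_pos <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    d <- sample(seq_len(8), n, replace = TRUE) / 2  # deliberate ties
    roc <- roc_from_ranking(d, is_pos)
    expect_equal(roc$auc, mw_auc(d, is_pos), tolerance = 1e-12)
    # curve endpoints and monotonicity
    expect_equal(roc$curve$fpr[1], 0)
    expect_equal(roc$curve$tpr[1], 0)
    expect_equal(roc$curve$fpr[nrow(roc$curve)], 1)
    expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
    expect_true(all(diff(roc$curve$fpr) >= 0))
    expect_true(all(diff(roc$curve$tpr) >= 0))
  }
})

test_that("extreme rankings give AUC 1 and 0; degenerate labels error", {
  d <- 1:6
  expect_equal(roc_from_ranking(d, c(T, T, T, F, F, F))$auc, 1.0)
  expect_equal(roc_from_ranking(d, c(F, F, F, T, T, T))$auc, 0.0)
  expect_error(roc_from_ranking(d, rep(TRUE, 6)), "positive")
})

test_that("sensitivity is read at the most liberal point with specificity >= target", {
  # distances 1..10; positives at ranks 1,2,3,9; 6 negatives
  d <- 1:10
  is_pos <- c(T, T, T, F, F, F, F, F, T, F)
  roc <- roc_from_ranking(d, is_pos, operating_specificity = 0.7)
  # thresholds: at d<=3, fpr=0 (spec 1); at d<=4, fpr=1/6 (spec .83); at
  # d<=5, fpr=2/6 (spec .67 < .7). So the operating point is d<=4: tpr 3/4.
  expect_equal(roc$sensitivity_at_spec, 0.75)
  expect_equal(roc$achieved_specificity, 1 - 1 / 6)
})

test_that("internal cross-validation is reproducible and separates planted groups", {
  sim <- small_study(seed = 7)
  expr <- preprocess_study(sim)
  mods <- discover_modules(expr, n_repeats = 10, rng_seed = 3)
  cv1 <- run_cv(expr, mods, n_trials = 8, mode = "internal",
                refit_modules = FALSE, rng_seed = 5)
  cv2 <- run_cv(expr, mods, n_trials = 8, mode = "internal",
                refit_modules = FALSE, rng_seed = 5)
  expect_identical(cv1$per_cancer, cv2$per_cancer)   # bit-identical rerun
  expect_gte(cv1$mean_auc, 0.99)
  expect_gte(cv1$mean_sensitivity, 0.95)
  # full protocol (module re-discovery inside each trial) at a few trials
  cv3 <- run_cv(expr, mods, n_trials = 2, mode = "internal",
                refit_modules = TRUE, rng_seed = 6,
                refit_args = list(n_repeats = 5, rng_seed = 1))
  expect_gte(cv3$mean_auc, 0.95)
})

test_that("permuted labels drive the cross-validated AUC to chance", {
  sim <- small_study(seed = 8)
  expr <- preprocess_study(sim)
  mods <- discover_modules(expr, n_repeats = 10, rng_seed = 3)
  set.seed(33)
  shuffled <- expr
  tumor <- shuffled$meta$condition == "tumor"
  shuffled$meta$cancer_label[tumor] <-
    sample(shuffled$meta$cancer_label[tumor])
  cv <- run_cv(shuffled, mods, n_trials = 30, mode = "internal",
               refit_modules = FALSE, rng_seed = 5)
  expect_gt(cv$mean_auc, 0.40)
  expect_lt(cv$mean_auc, 0.60)
})

test_that("confusable background negatives degrade per-cancer specificity", {
  # background negatives are cancers the model was never trained on; when
  # they sit closer to a centroid than the modeled alternatives do, the
  # specificity at any fixed distance threshold can only drop (weighted
  # average of the old specificity and the extras' exceedance rate)
  set.seed(34)
  cent <- c(5, 0, 0)
  pos <- matrix(rnorm(60, mean = c(5, 0, 0), sd = 1), 3, 20)
  neg <- matrix(rnorm(60, mean = c(0, 4, 0), sd = 1), 3, 20)
  extra <- matrix(rnorm(60, mean = c(3, 1, 0), sd = 1), 3, 20)  # confusable
  dist_to <- function(m) apply(m, 2, module_distance, centroid = cent)
  d_neg <- dist_to(neg); d_extra <- dist_to(extra)
  spec0 <- spec1 <- numeric(0)
  for (t in quantile(c(dist_to(pos), d_neg), seq(0.1, 0.9, by = 0.2))) {
    s0 <- mean(d_neg > t)
    s1 <- mean(c(d_neg, d_extra) > t)
    e_rate <- mean(d_extra > t)
    expect_true(s1 <= max(s0, e_rate) + 1e-12)
    expect_true(s1 >= min(s0, e_rate) - 1e-12)
    spec0 <- c(spec0, s0); spec1 <- c(spec1, s1)
  }
  # degradation direction across the sweep
  expect_true(all(spec1 <= spec0 + 1e-12))
})
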