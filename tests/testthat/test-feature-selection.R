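test_that("a label copy ranks first and a constant feature last", {
  set.seed(6)
  labels <- factor(rep(c("improved", "unimproved"), each = 6))
  feats <- data.frame(
    noise1 = rnorm(12),
    copy = as.numeric(labels == "improved") + rnorm(12, sd = 1e-3),
    noise2 = rnorm(12),
    flat = rep(1, 12)
  )
  rk <- mrmr_rank(feats, labels)
  expect_equal(rk$feature[1], "copy")
  expect_equal(rk$feature[4], "flat")
  expect_equal(rk$relevance[rk$feature == "flat"], 0)
})

test_that("a duplicated informative feature defers to a complementary one", {
  # 8-sample truth table; oracle = greedy mRMR re-derived via entropy MI
  labels <- factor(c("improved", "improved", "improved", "improved",
                     "improved", "unimproved", "unimproved", "unimproved"))
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)       # strong predictor
  b <- c(1, 0, 1, 0, 1, 0, 0, 0)       # weaker, complementary
  feats <- data.frame(a = a, a_dup = a, b = b)
  rk <- mrmr_rank(feats, labels)
  expect_equal(rk$feature[1], "a")
  expect_equal(rk$feature[2], "b")       # duplicate demoted below complement
  expect_equal(rk$feature[3], "a_dup")
  expect_identical(rk$feature, mrmr_oracle(feats, labels))
})

test_that("mRMR ranking equals the exhaustive-MI oracle on random tables", {
  set.seed(19)
  for (i in 1:15) {
    labels <- factor(sample(c("improved", "unimproved"), 12, replace = TRUE,
                            prob = c(0.6, 0.4)))
    if (length(unique(labels)) < 2) next
    feats <- data.frame(f1 = rnorm(12), f2 = rnorm(12),
                        f3 = as.numeric(labels == "improved") + rnorm(12),
                        f4 = rnorm(12))
    expect_identical(mrmr_rank(feats, labels)$feature,
                     mrmr_oracle(feats, labels))
  }
})

test_that("ranking is invariant to strictly monotone feature transforms", {
  set.seed(23)
  labels <- factor(rep(c("improved", "unimproved"), times = c(8, 6)))
  feats <- data.frame(u = rnorm(14), v = as.numeric(labels == "improved") +
                        rnorm(14, sd = 0.5), w = runif(14))
  warped <- data.frame(u = exp(feats$u), v = feats$v^3 + 10 * feats$v,
                       w = log(feats$w))
  expect_identical(mrmr_rank(feats, labels)$feature,
                   mrmr_rank(warped, labels)$feature)
})

test_that("mRMR validates its preconditions", {
  labels <- factor(rep("improved", 8))
  feats <- data.frame(a = rnorm(8), b = rnorm(8))
  expect_error(mrmr_rank(feats, labels), "constant")
  expect_error(mrmr_rank(feats[1:2, ], factor(c("improved", "unimproved"))),
               ">=|bins|samples")
})

test_that("stratified folds balance classes and sizes (11/4 over 5)", {
  labels <- factor(rep(c("improved", "unimproved"), times = c(11, 4)))
  for (seed in 1:10) {
    fold <- stratified_folds(labels, k = 5, seed = seed)
    tab <- table(fold, labels)
    expect_equal(sort(as.integer(tab[, "improved"])), c(2, 2, 2, 2, 3))
    expect_equal(sort(as.integer(tab[, "unimproved"])), c(0, 1, 1, 1, 1))
    expect_equal(as.integer(table(fold)), rep(3L, 5))
    # the fold with 3 improved is the one lacking the minority class
    expect_equal(unname(tab[tab[, "improved"] == 3, "unimproved"]), 0L)
  }
  expect_error(stratified_folds(labels, k = 20), "k must be")
})

test_that("majority voting selects consistently top-ranked features", {
  mk_rank <- function(fold, feats) {
    tibble::tibble(fold_id = fold, rank = seq_along(feats), feature = feats)
  }
  # identical rankings in all folds: the common top-3
  same <- dplyr::bind_rows(lapply(1:5, mk_rank,
                                  feats = c("cs", "xcrd", "cc", "dtw", "ed")))
  sel <- vote_select(same, k = 3)
  expect_identical(sel$feature[sel$selected], c("cs", "xcrd", "cc"))

  # top-3 in 3 of 5 folds -> selected; 2 of 5 -> not
  rks <- dplyr::bind_rows(
    mk_rank(1, c("a", "b", "c", "d", "e")),
    mk_rank(2, c("a", "b", "c", "d", "e")),
    mk_rank(3, c("a", "b", "c", "e", "d")),
    mk_rank(4, c("a", "b", "d", "e", "c")),
    mk_rank(5, c("a", "b", "d", "e", "c"))
  )
  sel <- vote_select(rks, k = 3)
  expect_true(sel$selected[sel$feature == "c"])   # 3/5 folds
  expect_false(sel$selected[sel$feature == "d"])  # 2/5 folds
  expect_equal(sel$votes[sel$feature == "c"], 3)

  # tie at the majority threshold resolved by mean rank
  tie <- dplyr::bind_rows(
    mk_rank(1, c("a", "b", "c", "d")),
    mk_rank(2, c("a", "c", "b", "d")),
    mk_rank(3, c("b", "a", "d", "c")),
    mk_rank(4, c("c", "d", "a", "b")),
    mk_rank(5, c("d", "b", "a", "c"))
  )
  sel <- vote_select(tie, k = 2)
  tally <- sel[order(sel$feature), ]
  # a and b both reach top-2 in 3/5 folds; a's mean rank is better
  expect_equal(tally$votes[tally$feature == "a"], 3)
  expect_equal(tally$votes[tally$feature == "b"], 3)
  expect_true(sel$selected[sel$feature == "a"])
  expect_true(sel$selected[sel$feature == "b"])

  bad <- dplyr::bind_rows(mk_rank(1, c("a", "b")), mk_rank(2, c("a", "c")))
  expect_error(vote_select(bad, k = 1), "inconsistent")
})

test_that("fold-voted mRMR on synthetic profiles favours cs/xcrd/cc/dtw", {
  co <- simulate_cohort(synthetic_config(seed = 31, missing_rate = 0))
  prof <- similarity_profiles(co)
  feats <- prof[, c("ed", "md", "dtw", "xcrd", "cc", "cs")]
  rk <- mrmr_rank_folds(feats, prof$label, k = 5, seed = 31)
  top4 <- rk |>
    dplyr::group_by(fold_id) |>
    dplyr::summarise(
      n_top = sum(feature[rank <= 4] %in% c("cs", "xcrd", "cc", "dtw")))
  # cs/xcrd/cc/dtw outrank ed/md in a majority of folds
  expect_gte(sum(top4$n_top >= 3), ceiling(nrow(top4) / 2))
})
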