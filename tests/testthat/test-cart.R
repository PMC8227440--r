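test_that("gini impurity follows the two-class formula", {
  expect_equal(gini_impurity(0, 10), 0)
  expect_equal(gini_impurity(5, 5), 0.5)
  expect_equal(gini_impurity(3, 1), 0.375)
  expect_error(gini_impurity(0, 0), class = "msclassify_domain_error")
})

test_that("a separable 1-D problem yields a single split at the midpoint", {
  d <- data.frame(
    edss = c(1, 2, 2.5, 3, 4, 4.5, 5, 6, 7, 8),
    phenotype = c(rep("RR", 5), rep("SP", 5))
  )
  fit <- fit_sp_tree(d, outcome = "phenotype", features = "edss",
                     cp = 1e-4, min_node_size = 2, min_bucket = 1)
  td <- tidy(fit)
  expect_equal(sum(!td$leaf), 1)
  thr <- td$threshold[!td$leaf]
  expect_gt(thr, 4.0)
  expect_lte(thr, 4.5)
  expect_equal(mean(predict(fit, d, type = "class") == d$phenotype), 1)
})

test_that("single-class input gives a depth-0 leaf, not an error", {
  d <- data.frame(edss = c(1, 2, 3, 4), phenotype = "RR")
  fit <- fit_sp_tree(d, outcome = "phenotype", features = "edss",
                     cp = "auto", min_node_size = 2, min_bucket = 1,
                     cv_folds = 2)
  expect_equal(n_leaves(fit), 1)
  expect_true(all(predict(fit, d, type = "class") == "RR"))
})

test_that("checkerboard (XOR) labels are fit exactly by a depth-2 tree", {
  d <- data.frame(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1),
                  y = c("RR", "SP", "SP", "RR"))
  fit <- fit_sp_tree(d, outcome = "y", features = c("x1", "x2"),
                     cp = 0, min_node_size = 2, min_bucket = 1)
  expect_equal(max(tidy(fit)$depth), 2)
  expect_equal(mean(predict(fit, d, type = "class") == d$y), 1)
})

test_that("pruning honours its boundary cases and is monotone in cp", {
  set.seed(8)
  d <- data.frame(edss = runif(400, 0, 10), age = runif(400, 20, 80))
  d$phenotype <- ifelse(d$edss + rnorm(400, 0, 1.5) > 5, "SP", "RR")
  fit <- fit_sp_tree(d, outcome = "phenotype", cp = 0)
  # cp = 0 keeps the full tree; cp = 1 collapses to the root leaf
  expect_gt(n_leaves(fit, 0), 1)
  expect_equal(n_leaves(fit, 1), 1)
  # leaves non-increasing in cp, and pruned trees are nested
  cps <- sort(unique(c(0, fit$tree$collapse_alpha, 1)))
  leaves <- vapply(cps, function(cc) n_leaves(fit, cc), integer(1))
  expect_true(all(diff(leaves) <= 0))
  # nestedness: a node that is a leaf at cp1 stays a leaf at cp2 > cp1
  for (k in seq_len(length(cps) - 1)) {
    l1 <- msclassify:::effective_leaf(fit$tree, cps[k])
    l2 <- msclassify:::effective_leaf(fit$tree, cps[k + 1])
    expect_true(all(l2[l1]))
  }
  # separable example: one split survives cp = 1e-4 (improvement ~ 1)
  d2 <- data.frame(edss = c(1, 2, 3, 4.5, 5, 6),
                   phenotype = c("RR", "RR", "RR", "SP", "SP", "SP"))
  f2 <- fit_sp_tree(d2, outcome = "phenotype", features = "edss",
                    cp = 1e-4, min_node_size = 2, min_bucket = 1)
  expect_equal(n_leaves(f2), 2)
})

test_that("training class predictions match rpart with identical settings", {
  library(rpart)
  for (s in 1:5) {
    set.seed(s)
    n <- 120 + s * 15
    d <- data.frame(
      edss = runif(n, 0, 10) + rnorm(n, 0, 1e-6),
      age = runif(n, 20, 80) + rnorm(n, 0, 1e-6)
    )
    d$phenotype <- ifelse(d$edss + 0.05 * d$age + rnorm(n, 0, 2) > 7,
                          "SP", "RR")
    if (length(unique(d$phenotype)) < 2) next
    mine <- fit_sp_tree(d, outcome = "phenotype", cp = 0, min_node_size = 20)
    ref <- rpart(
      factor(phenotype) ~ edss + age, d, method = "class",
      control = rpart.control(minsplit = 20, minbucket = 7, cp = 0,
                              xval = 0, maxcompete = 0, maxsurrogate = 0)
    )
    expect_identical(
      unname(predict(mine, d, type = "class")),
      unname(as.character(predict(ref, d, type = "class")))
    )
  }
})

test_that("fits are deterministic for identical inputs and seed", {
  set.seed(5)
  d <- data.frame(edss = runif(300, 0, 10), age = runif(300, 20, 80))
  d$phenotype <- ifelse(d$edss > 4.2, "SP", "RR")
  d$phenotype[1:25] <- sample(c("RR", "SP"), 25, TRUE)
  f1 <- fit_sp_tree(d, outcome = "phenotype", cp = "auto", seed = 3)
  f2 <- fit_sp_tree(d, outcome = "phenotype", cp = "auto", seed = 3)
  expect_identical(f1$tree, f2$tree)
  expect_identical(f1$cp, f2$cp)
  expect_identical(f1$cv_table, f2$cv_table)
})

test_that("cross-validation breaks exact ties toward the simpler tree", {
  # below the top split every deeper split refines probabilities without
  # changing any class prediction, so all those pruning levels tie exactly
  # in CV error and the largest cp (one split) must be selected
  d <- data.frame(
    edss = rep(c(1, 2, 3, 5, 6, 7), each = 10),
    phenotype = c(rep("RR", 19), "SP", rep("RR", 10),
                  rep("SP", 19), "RR", rep("SP", 10))
  )
  for (s in 1:3) {
    fit <- fit_sp_tree(d, outcome = "phenotype", features = "edss",
                       cp = "auto", min_node_size = 5, min_bucket = 2,
                       seed = s)
    expect_equal(n_leaves(fit), 2)
  }
})

test_that("pure-noise labels frequently collapse to the root leaf", {
  # with no signal the cross-validated error of every subtree hovers at
  # chance; the minimum-error rule with ties to the larger cp recovers the
  # stump in a substantial share of replicates
  stumps <- 0
  for (s in 1:20) {
    set.seed(s + 100)
    d <- data.frame(
      edss = sample(valid_edss_grid(), 200, TRUE),
      age = runif(200, 20, 80),
      phenotype = sample(c("RR", "SP"), 200, TRUE)
    )
    fit <- fit_sp_tree(d, outcome = "phenotype", cp = "auto", seed = s)
    stumps <- stumps + (n_leaves(fit) == 1)
  }
  expect_gte(stumps, 5)
})

test_that("variable importance sums improvements per variable", {
  d <- data.frame(
    edss = c(1, 2, 2.5, 3, 4, 4.5, 5, 6, 7, 8),
    age = 50,
    phenotype = c(rep("RR", 5), rep("SP", 5))
  )
  fit <- fit_sp_tree(d, outcome = "phenotype", cp = 1e-4,
                     min_node_size = 2, min_bucket = 1)
  vi <- variable_importance(fit)
  expect_equal(vi$importance[vi$variable == "edss"], 1)
  expect_equal(vi$importance[vi$variable == "age"], 0)
  # stump -> all-zero report
  stump <- prune_sp_tree(fit, 1)
  expect_true(all(variable_importance(stump)$importance == 0))
})

test_that("trees survive a JSON round trip", {
  set.seed(2)
  d <- data.frame(edss = runif(150, 0, 10), age = runif(150, 20, 80))
  d$phenotype <- ifelse(d$edss > 5, "SP", "RR")
  fit <- fit_sp_tree(d, outcome = "phenotype", cp = 1e-4)
  path <- withr::local_tempfile(fileext = ".json")
  write_sp_tree(fit, path)
  back <- read_sp_tree(path)
  expect_equal(predict(back, d, type = "prob"), predict(fit, d, type = "prob"))
  expect_identical(back$features, fit$features)
})

test_that("missing features and infeasible folds are rejected", {
  d <- data.frame(edss = c(1, NA, 3, 6), age = 50,
                  phenotype = c("RR", "RR", "SP", "SP"))
  expect_error(fit_sp_tree(d, outcome = "phenotype"),
               class = "msclassify_domain_error")
  d2 <- data.frame(edss = c(1, 2, 3, 6), age = 50,
                   phenotype = c("RR", "RR", "RR", "SP"))
  expect_error(
    fit_sp_tree(d2, outcome = "phenotype", cp = "auto", cv_folds = 3,
                min_node_size = 2, min_bucket = 1),
    class = "msclassify_domain_error"
  )
})
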