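test_that("Gini impurity matches direct proportion arithmetic", {
  expect_equal(gini_impurity(rep("HFrEF", 5)), 0)
  expect_equal(gini_impurity(c("HFrEF", "HFrEF", "NoHF", "NoHF")), 0.5)
  expect_equal(gini_impurity(hf_labels()), 0.75)
  expect_error(gini_impurity(character(0)), "empty")
  withr::with_seed(1, {
    for (i in 1:20) {
      lab <- random_labels(sample(1:40, 1))
      expect_equal(gini_impurity(lab), oracle_gini(lab))
    }
  })
})

test_that("best_split agrees with exhaustive enumeration on small instances", {
  sch <- default_schema()
  withr::with_seed(20, {
    for (i in 1:60) {
      n <- sample(2:30, 1)
      attrs <- sample(sch$name, sample(1:3, 1))
      cohort <- random_cohort(n, seed = 5000 + i,
                              missingness = sample(c(0, 0.2), 1))
      labels <- random_labels(n)
      got <- best_split(cohort, attributes = attrs, labels = labels)
      want <- oracle_best_split(cohort, labels, attrs)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_false(is.null(got))
        expect_equal(got$decrease, max(want$decrease), tolerance = 1e-9)
        hit <- want$attribute == got$attribute &
          (is.na(want$threshold) | abs(want$threshold - got$threshold) < 1e-9)
        expect_true(any(hit))
      }
    }
  })
})

test_that("ties break to the earlier schema attribute, then smaller threshold", {
  # two continuous attributes with identical perfect splits: lavi
  # precedes lvmi in the schema, so lavi must win
  cohort <- data.frame(lavi = c(10, 11, 60, 61), lvmi = c(30, 31, 200, 201))
  labels <- c("NoHF", "NoHF", "HFrEF", "HFrEF")
  got <- best_split(cohort, attributes = c("lvmi", "lavi"), labels = labels)
  expect_equal(got$attribute, "lavi")
  # within one attribute, two thresholds with equal decrease: smaller wins
  cohort2 <- data.frame(lvef = c(10, 20, 30))
  labels2 <- c("HFrEF", "NoHF", "HFrEF")
  got2 <- best_split(cohort2, labels = labels2)
  oracle2 <- oracle_best_split(cohort2, labels2, "lvef")
  expect_equal(got2$decrease, max(oracle2$decrease), tolerance = 1e-12)
  expect_equal(got2$threshold, min(oracle2$threshold))
})

test_that("no admissible split on pure or unsplittable data", {
  cohort <- data.frame(lvef = c(10, 20, 30))
  expect_null(best_split(cohort, labels = rep("HFrEF", 3)))
  expect_null(best_split(cohort[1, , drop = FALSE], labels = "HFrEF"))
  # min_samples_leaf can forbid every candidate
  expect_null(best_split(data.frame(lvef = c(10, 50)),
                         labels = c("HFrEF", "NoHF"),
                         min_samples_leaf = 2))
})

test_that("induction handles the degenerate cases the stopping rules define", {
  one <- random_cohort(1, seed = 3)
  t1 <- induce_cart(one)
  expect_equal(n_leaves(t1), 1)
  expect_equal(diagnose(t1, one)$outcome, one$gold_diagnosis)

  co <- random_cohort(100, seed = 4)
  t0 <- induce_cart(co, induction_params(max_depth = 0))
  expect_equal(n_leaves(t0), 1)
  maj <- names(which.max(table(co$gold_diagnosis)))
  expect_equal(diagnose(t0, co[1, , drop = FALSE])$outcome, maj)

  expect_error(induce_cart(co[0, , drop = FALSE]), "non-empty")
})

test_that("unbounded induction fits consistent training data exactly", {
  co <- random_cohort(120, seed = 9)
  # continuous attributes almost surely have no duplicated vectors
  tree <- induce_cart(co, induction_params(max_depth = 50,
                                           min_samples_leaf = 1))
  pred <- diagnose_cohort(tree, co)
  expect_equal(mean(pred == co$gold_diagnosis), 1)
  expect_true(all(tree_splits(tree)$provenance == "learned"))
})

test_that("induced trees route Missing values and stay total", {
  co <- random_cohort(200, seed = 13, missingness = 0.15)
  tree <- induce_cart(co)
  # every internal node must carry an explicit Missing path
  ok <- TRUE
  check <- function(node) {
    if (is.null(node$leaf)) {
      if (is.null(node$na_route) && is.null(node$na_branch)) ok <<- FALSE
      for (b in node$branches) check(b$node)
    }
  }
  check(tree$root)
  expect_true(ok)
  holdout <- random_cohort(100, seed = 14, missingness = 0.5)
  expect_false(any(diagnose_cohort(tree, holdout) == "Uncovered"))
})

test_that("the learner recovers the LVEF boundaries the labels encode", {
  skip_if_not_installed("rpart")
  co <- random_cohort(400, seed = 31)
  tree <- induce_cart(co)
  splits <- tree_splits(tree)
  expect_equal(splits$attribute[splits$depth == 0], "lvef")

  # independent reference learner sees the same dominant split
  ref_data <- transform(co[, -1], gold_diagnosis = factor(gold_diagnosis))
  ref <- rpart::rpart(gold_diagnosis ~ ., data = ref_data,
                      method = "class",
                      control = rpart::rpart.control(minsplit = 10, cp = 0.01))
  expect_equal(as.character(ref$frame$var[1]), "lvef")
  ref_thr <- ref$splits[rownames(ref$splits) == "lvef", "index"][1]
  own_thr <- as.numeric(splits$thresholds[splits$depth == 0])
  expect_lt(abs(ref_thr - own_thr), 2)
})

test_that("feature ranking puts the label-determining attribute first", {
  co <- random_cohort(300, seed = 17)
  imp <- rank_features(co)
  expect_equal(imp$attribute[1], "lvef")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))

  # permuted labels destroy the signal: no attribute may dominate
  withr::with_seed(99, {
    for (s in 1:10) {
      co2 <- co
      co2$gold_diagnosis <- sample(co2$gold_diagnosis)
      imp2 <- rank_features(co2)
      expect_lt(max(imp2$importance), 0.5)
    }
  })

  # single-attribute data: all importance on that attribute
  imp3 <- rank_features(co, attributes = "lvef")
  expect_equal(imp3$importance[imp3$attribute == "lvef"], 1)

  # single-class labels: all-zero importances in schema order
  co3 <- co
  co3$gold_diagnosis <- "HFpEF"
  imp4 <- rank_features(co3)
  expect_true(all(imp4$importance == 0))
  expect_equal(imp4$attribute, default_schema()$name)
})

test_that("algorithm ranking is monotone, symmetric and order-invariant", {
  cand <- data.frame(
    algorithm = c("CART", "CHAID", "J48"),
    accuracy = c(88.5, 82.1, 85.0),
    n_rules = c(12, 30, 25),
    n_attributes = c(4, 9, 7))
  ranked <- rank_algorithms(cand)
  expect_equal(ranked$algorithm[1], "CART")  # best on all three criteria
  expect_equal(ranked$rank_value[1], 1)      # min-max tops every term

  # permutation invariance
  perm <- rank_algorithms(cand[c(3, 1, 2), ])
  expect_equal(perm$algorithm, ranked$algorithm)
  expect_equal(perm$rank_value, ranked$rank_value)

  # identical candidates score identically
  twins <- rank_algorithms(data.frame(
    algorithm = c("A", "B"), accuracy = c(80, 80),
    n_rules = c(10, 10), n_attributes = c(5, 5)))
  expect_equal(twins$rank_value[1], twins$rank_value[2])

  # degenerate-range convention: a lone candidate scores 1
  expect_equal(rank_algorithms(cand[1, , drop = FALSE])$rank_value, 1)

  # monotone in accuracy, all else equal
  m <- rank_algorithms(data.frame(
    algorithm = c("lo", "hi"), accuracy = c(70, 90),
    n_rules = c(10, 10), n_attributes = c(5, 5)))
  expect_equal(m$algorithm[1], "hi")

  expect_error(rank_algorithms(cand[0, ]), "no candidates")
  expect_error(rank_algorithms(transform(cand, accuracy = accuracy + 50)),
               "\\[0, 100\\]")
})

test_that("cross-validated accuracy summarizes the learner sensibly", {
  co <- random_cohort(200, seed = 23)
  inp <- cart_rank_input(co, induction_params(seed = 7), k = 5)
  expect_true(inp$accuracy > 60 && inp$accuracy <= 100)
  expect_gte(inp$n_rules, 2)
  expect_gte(inp$n_attributes, 1)
  # seeded: reproducible
  expect_equal(cv_accuracy(co, induction_params(seed = 7)),
               cv_accuracy(co, induction_params(seed = 7)))
})
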