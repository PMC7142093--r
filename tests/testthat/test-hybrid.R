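test_that("coverage counts reachable leaves and localizes failures", {
  ckm <- default_hf_ckm()
  cohort <- random_cohort(40, seed = 8)
  expect_equal(coverage(ckm, cohort)$coverage, 1)

  # hand-trace: 3 of 10 records with LVEF Missing fail at the LVEF node
  ten <- random_cohort(10, seed = 9)
  ten$hf_symptoms_signs <- TRUE           # all reach the LVEF node
  ten$lvef[c(2, 5, 9)] <- NA
  cov <- coverage(ckm, ten)
  expect_equal(cov$coverage, 0.7)
  expect_equal(cov$n_covered, 7)
  expect_equal(nrow(cov$uncovered), 3)
  expect_true(all(cov$uncovered$failure_attribute == "lvef"))
  expect_equal(length(unique(cov$uncovered$failure_node)), 1)
  expect_true(all(cov$uncovered$failure_reason == "missing"))

  # vacuous coverage of the empty cohort is 1 by convention
  expect_equal(coverage(ckm, ten[0, , drop = FALSE])$coverage, 1)
})

test_that("hybridization with nothing to patch returns the model unchanged", {
  ckm <- default_hf_ckm()
  cohort <- random_cohort(60, seed = 12)
  pm <- induce_cart(cohort)
  expect_identical(tree_structure(hybridize(ckm, pm, cohort)),
                   tree_structure(ckm))
})

test_that("a Missing symptoms attribute grows a Not-Available root path", {
  ckm <- default_hf_ckm()
  cohort <- random_cohort(200, seed = 15)
  cohort$hf_symptoms_signs[1:60] <- NA
  pm <- induce_cart(cohort)
  rckm <- hybridize(ckm, pm, cohort)

  root <- rckm$root
  expect_equal(root$attribute, "hf_symptoms_signs")
  expect_false(is.null(root$na_branch))
  expect_equal(root$na_branch$provenance, "grafted")
  # the grafted subtree starts from the learned model's dominant
  # attribute: LVEF
  expect_equal(root$na_branch$attribute, "lvef")
  # grafted provenance appears only below the graft point
  grafted_ids <- character(0)
  walk <- function(node) {
    if (node$provenance == "grafted") grafted_ids <<- c(grafted_ids,
                                                        node$node_id)
    for (b in node$branches) walk(b$node)
    if (!is.null(node$na_branch)) walk(node$na_branch)
  }
  walk(root)
  in_graft <- character(0)
  walk2 <- function(node) {
    in_graft <<- c(in_graft, node$node_id)
    for (b in node$branches) walk2(b$node)
    if (!is.null(node$na_branch)) walk2(node$na_branch)
  }
  walk2(root$na_branch)
  expect_setequal(grafted_ids, in_graft)

  expect_equal(coverage(rckm, cohort)$coverage, 1)
})

test_that("hybridization is monotone and preserves expert decisions", {
  withr::with_seed(77, {
    for (i in 1:25) {
      ckm <- random_tree(max_depth = 3, na_prob = 0)
      cohort <- random_cohort(sample(30:80, 1), seed = 7000 + i,
                              missingness = runif(1, 0.05, 0.3))
      pm <- induce_cart(cohort)
      rckm <- hybridize(ckm, pm, cohort)

      cov0 <- coverage(ckm, cohort)
      cov1 <- coverage(rckm, cohort)
      expect_gte(cov1$coverage, cov0$coverage)
      expect_gte(n_leaves(rckm), n_leaves(ckm))
      if (nrow(cov0$uncovered)) expect_gt(n_leaves(rckm), n_leaves(ckm))

      # expert precedence: identical diagnoses wherever the CKM decided
      pred0 <- diagnose_cohort(ckm, cohort)
      pred1 <- diagnose_cohort(rckm, cohort)
      decided <- pred0 != "Uncovered"
      expect_identical(pred1[decided], pred0[decided])
    }
  })
})

test_that("domain gaps are grafted with branches over the gap interval", {
  # expert-style node covering only lvef < 40: values above fall through
  gappy <- structure(list(tree_id = "gap", root = tree_node(
    "lvef",
    list(list(lo = -Inf, hi = 40, node = tree_leaf("HFrEF"))),
    node_id = "g1")), class = "hf_tree")
  gappy <- assign_ids_for_test(gappy)
  cohort <- random_cohort(120, seed = 33)
  pm <- induce_cart(cohort)
  cov0 <- coverage(gappy, cohort)
  expect_true(any(cov0$uncovered$failure_reason == "gap"))
  rckm <- hybridize(gappy, pm, cohort)
  expect_length(validate_tree(rckm), 0)
  expect_equal(coverage(rckm, cohort)$coverage, 1)
  # records the gap model decided keep their decision
  pred0 <- diagnose_cohort(gappy, cohort)
  keep <- pred0 != "Uncovered"
  expect_identical(diagnose_cohort(rckm, cohort)[keep], pred0[keep])
})

test_that("tiny uncovered groups get a majority leaf, empty PMs a NoHF leaf", {
  ckm <- default_hf_ckm()
  cohort <- random_cohort(50, seed = 41)
  cohort$hf_symptoms_signs[1:2] <- NA    # below min_samples_leaf = 5
  pm <- induce_cart(cohort)
  rckm <- hybridize(ckm, pm, cohort)
  expect_true(!is.null(rckm$root$na_branch$leaf))
  maj <- names(which.max(table(cohort$gold_diagnosis[1:2])))
  expect_equal(rckm$root$na_branch$leaf, maj)

  # no usable labels at all: gold stripped and PM cannot classify
  blank <- cohort
  blank$gold_diagnosis <- NULL
  blank[1:2, setdiff(names(blank), "patient_id")] <- NA
  stub <- decision_tree(tree_leaf("HFpEF", provenance = "learned"))
  rckm2 <- hybridize(ckm, stub, blank)
  expect_equal(coverage(rckm2, blank)$coverage, 1)
})

test_that("extracted rules mirror the tree exactly", {
  # leaf-only tree: one rule, empty condition
  leafy <- decision_tree(tree_leaf("NoHF"))
  rb0 <- extract_rules(leafy)
  expect_length(rb0$rules, 1)
  expect_length(rb0$rules[[1]]$conditions, 0)

  # depth-1 binary split: exactly two rules
  b1 <- decision_tree(tree_node("male", list(
    list(value = FALSE, node = tree_leaf("NoHF")),
    list(value = TRUE, node = tree_leaf("HFrEF")))))
  expect_length(extract_rules(b1)$rules, 2)

  # on random trees, every covered record matches exactly one rule and
  # that rule concludes what traversal concludes
  withr::with_seed(55, {
    for (i in 1:12) {
      tr <- if (i %% 2) random_tree(max_depth = 3, na_prob = 0.4)
            else induce_cart(random_cohort(60, seed = 8000 + i,
                                           missingness = 0.2))
      rb <- extract_rules(tr)
      expect_length(rb$rules, n_leaves(tr))
      cohort <- random_cohort(40, seed = 8100 + i, missingness = 0.2)
      for (r in seq_len(nrow(cohort))) {
        rec <- cohort[r, , drop = FALSE]
        out <- diagnose(tr, rec)$outcome
        matches <- vapply(seq_along(rb$rules), function(j) {
          one <- rb
          one$rules <- rb$rules[j]
          apply_rules(one, rec)$outcome != "Uncovered"
        }, logical(1))
        if (out == "Uncovered") {
          expect_equal(sum(matches), 0)
        } else {
          expect_equal(sum(matches), 1)
          expect_equal(rb$rules[[which(matches)]]$conclusion, out)
        }
      }
    }
  })
})

test_that("rule provenance propagates from grafted paths", {
  ckm <- default_hf_ckm()
  cohort <- random_cohort(150, seed = 61, missingness = 0.15)
  pm <- induce_cart(cohort)
  rckm <- hybridize(ckm, pm, cohort)
  rb <- extract_rules(rckm)
  provs <- vapply(rb$rules, function(r) r$provenance, character(1))
  expect_true(any(provs == "grafted"))
  expect_true(any(provs == "expert"))
  # grafted rules contain an "is Missing" term
  grafted <- rb$rules[provs == "grafted"]
  has_missing_term <- vapply(grafted, function(r)
    any(vapply(r$conditions, function(t) t$kind == "missing", logical(1))),
    logical(1))
  expect_true(all(has_missing_term))
})

test_that("the rule base exports and re-imports losslessly", {
  cohort <- random_cohort(100, seed = 71, missingness = 0.1)
  pm <- induce_cart(cohort)
  rckm <- hybridize(default_hf_ckm(), pm, cohort)
  rb <- extract_rules(rckm, code_map = c(lvef = "SCT:78564009",
                                         nt_probnp = "LOINC:33762-6"))
  path <- withr::local_tempfile(fileext = ".json")
  export_rule_base(rb, path)
  back <- import_rule_base(path)
  expect_equal(length(back$rules), length(rb$rules))
  expect_identical(back$rules, rb$rules)
  expect_equal(back$source_tree_id, rb$source_tree_id)
  expect_equal(back$code_map, rb$code_map)

  # code map is applied to the exported condition blocks
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lvef_terms <- unlist(lapply(doc$rules, function(r)
    lapply(r$conditions, function(cn)
      if (identical(cn$attribute, "lvef")) cn$code else NULL)))
  expect_true(length(lvef_terms) > 0)
  expect_true(all(lvef_terms == "SCT:78564009"))

  # the imported rule base is executable and agrees with the tree
  pred_tree <- diagnose_cohort(rckm, cohort)
  pred_rules <- diagnose_cohort(back, cohort)
  expect_identical(pred_rules, pred_tree)
})
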