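# Random-case generators used by the property-style tests.

# A random valid decision tree over the default schema.  na_prob
# controls how often an internal node gets a Missing path (na_route);
# 0 gives an expert-style tree that hybridization must patch.
random_tree <- function(max_depth = 3, na_prob = 0, leaf_prob = 0.3,
                        provenance = "expert", tree_id = "random") {
  sch <- default_schema()
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < leaf_prob)
      return(tree_leaf(sample(hf_labels(), 1), provenance = provenance))
    i <- sample(nrow(sch), 1)
    if (sch$kind[i] == "binary") {
      branches <- list(list(value = TRUE, node = build(depth + 1)),
                       list(value = FALSE, node = build(depth + 1)))
    } else {
      k <- sample(1:2, 1)
      cuts <- sort(runif(k, sch$lo[i], sch$hi[i]))
      branches <- interval_branches(
        cuts, lapply(seq_len(k + 1), function(j) build(depth + 1)))
    }
    na_route <- if (runif(1) < na_prob) sample(length(branches), 1) else NULL
    tree_node(sch$name[i], branches, na_route = na_route,
              provenance = provenance)
  }
  root <- build(0)
  if (is_random_leaf(root))   # guarantee at least one test node
    root <- tree_node("lvef", interval_branches(50, list(
      root, tree_leaf(sample(hf_labels(), 1), provenance = provenance))),
      provenance = provenance)
  decision_tree(root, tree_id = tree_id)
}

is_random_leaf <- function(node) !is.null(node$leaf)

# Small synthetic cohort with optional MCAR missingness
random_cohort <- function(n, seed, missingness = 0) {
  cohort <- generate_cohort(table1_default_spec(n = n, seed = seed))
  if (missingness > 0)
    cohort <- inject_missingness(cohort, missingness, seed = seed + 1000L)
  cohort
}

# Random label vector re-used by evaluation tests
random_labels <- function(n) sample(hf_labels(), n, replace = TRUE)

# Structural equality of trees ignoring attached induction metadata
tree_structure <- function(tree) {
  strip <- function(node) {
    node$n <- NULL
    node$decrease <- NULL
    if (!is.null(node$branches))
      node$branches <- lapply(node$branches, function(b) {
        b$node <- strip(b$node)
        b
      })
    if (!is.null(node$na_branch)) node$na_branch <- strip(node$na_branch)
    node[order(names(node))]
  }
  strip(tree$root)
}

# Assign node ids without running constructor validation (for building
# deliberately invalid trees in tests)
assign_ids_for_test <- function(tree) {
  i <- 0
  rec <- function(node) {
    i <<- i + 1
    if (is.null(node$node_id)) node$node_id <- paste0("t", i)
    if (!is.null(node$branches))
      node$branches <- lapply(node$branches, function(b) {
        b$node <- rec(b$node)
        b
      })
    if (!is.null(node$na_branch)) node$na_branch <- rec(node$na_branch)
    node
  }
  tree$root <- rec(tree$root)
  tree
}
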