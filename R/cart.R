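#' Gini impurity of a diagnosis multiset
#'
#' `1 - sum(p_k^2)` over the class proportions.  Zero iff the set is
#' pure; maximal (0.75) at the uniform mixture over the four labels.
#'
#' @param labels Non-empty character vector of diagnosis labels.
#' @return Impurity in `[0, 0.75]`.
#' @export
#' @examples
#' gini_impurity(c("HFrEF", "HFrEF", "NoHF", "NoHF"))  # 0.5
gini_impurity <- function(labels) {
  if (!length(labels)) stop("empty label set has no impurity", call. = FALSE)
  p <- tabulate(factor(labels, levels = hf_labels()), nbins = 4) /
    length(labels)
  1 - sum(p^2)
}

#' Hyperparameters for CART-style induction
#'
#' @param max_depth Maximum tree depth (root at depth 0); `0` forces a
#'   single majority-class leaf.
#' @param min_samples_leaf Minimum records per leaf, after Missing
#'   routing.
#' @param min_impurity_decrease Minimum weighted impurity decrease a
#'   split must achieve; splits must always decrease impurity strictly.
#' @param seed Seed for the seeded parts of the pipeline
#'   (cross-validation folds); induction itself is deterministic.
#' @return Validated parameter list.
#' @export
induction_params <- function(max_depth = 6, min_samples_leaf = 5,
                             min_impurity_decrease = 0, seed = 1L) {
  stopifnot(length(max_depth) == 1, max_depth >= 0,
            length(min_samples_leaf) == 1, min_samples_leaf >= 1,
            length(min_impurity_decrease) == 1, min_impurity_decrease >= 0,
            length(seed) == 1, is.finite(seed))
  list(max_depth = as.integer(max_depth),
       min_samples_leaf = as.integer(min_samples_leaf),
       min_impurity_decrease = as.numeric(min_impurity_decrease),
       seed = as.integer(seed))
}

# Gini of rows of a count matrix (rows may include routed Missing counts)
row_gini <- function(counts, n) {
  ifelse(n > 0, 1 - rowSums((counts / pmax(n, 1))^2), 0)
}

# All admissible splits of one attribute, vectorized over thresholds.
# Missing values are routed to the side holding the majority of present
# records (ties to the low/FALSE side); the routing is returned so the
# node can record it as its explicit Missing path.
attribute_splits <- function(values, y, kind, min_samples_leaf) {
  present <- !is.na(values)
  m_counts <- colSums(y[!present, , drop = FALSE])
  m <- sum(!present)
  n <- length(values)
  if (kind == "binary") {
    v <- values[present]
    yp <- y[present, , drop = FALSE]
    cF <- colSums(yp[!v, , drop = FALSE])
    cT <- colSums(yp[v, , drop = FALSE])
    nF <- sum(cF); nT <- sum(cT)
    if (nF == 0 || nT == 0) return(NULL)
    to_left <- nF >= nT
    cL <- cF + if (to_left) m_counts else 0
    cR <- cT + if (to_left) 0 else m_counts
    nL <- nF + if (to_left) m else 0L
    nR <- nT + if (to_left) 0L else m
    if (nL < min_samples_leaf || nR < min_samples_leaf) return(NULL)
    child <- (nL * (1 - sum((cL / nL)^2)) + nR * (1 - sum((cR / nR)^2))) / n
    return(data.frame(threshold = NA_real_, child_impurity = child,
                      na_left = to_left))
  }
  v <- values[present]
  if (length(unique(v)) < 2) return(NULL)
  ord <- order(v)
  sv <- v[ord]
  yp <- y[present, , drop = FALSE][ord, , drop = FALSE]
  np <- length(sv)
  C <- apply(yp, 2, cumsum)
  if (is.null(dim(C))) C <- matrix(C, nrow = 1)
  d <- which(diff(sv) > 0)
  if (!length(d)) return(NULL)
  thr <- (sv[d] + sv[d + 1]) / 2
  cL <- C[d, , drop = FALSE]
  tot <- C[np, ]
  cR <- matrix(tot, nrow = length(d), ncol = 4, byrow = TRUE) - cL
  nL <- rowSums(cL); nR <- np - nL
  to_left <- nL >= nR
  mL <- matrix(m_counts, nrow = length(d), ncol = 4, byrow = TRUE)
  cLm <- cL + mL * to_left
  cRm <- cR + mL * (!to_left)
  nLm <- nL + m * to_left
  nRm <- nR + m * (!to_left)
  child <- (nLm * row_gini(cLm, nLm) + nRm * row_gini(cRm, nRm)) / n
  ok <- nLm >= min_samples_leaf & nRm >= min_samples_leaf
  if (!any(ok)) return(NULL)
  data.frame(threshold = thr[ok], child_impurity = child[ok],
             na_left = to_left[ok])
}

#' Find the best single split of a labeled cohort
#'
#' Candidate splits are, for continuous attributes, the midpoints between
#' consecutive distinct observed values, and for binary attributes the
#' `FALSE`/`TRUE` partition.  Missing values are routed to the side that
#' holds the majority of the present records, and that side is reported
#' so the induced node can keep it as an explicit Missing path.  The
#' split maximizing the weighted Gini impurity decrease wins; ties break
#' to the earlier schema attribute, then the smaller threshold.
#'
#' @param cohort Cohort data frame.
#' @param attributes Attributes to consider (default: full schema).
#' @param labels Diagnosis labels, one per row (default
#'   `cohort$gold_diagnosis`).
#' @param min_samples_leaf Minimum child size (after Missing routing).
#' @param min_impurity_decrease Minimum decrease for admissibility.
#' @param schema Attribute schema (fixes the tie-break order).
#' @return `NULL` when no admissible split exists, else a list:
#'   `attribute`, `kind`, `threshold` (`NA` for binary), `decrease`,
#'   `na_left` (whether Missing routes to the low/`FALSE` side).
#' @export
best_split <- function(cohort, attributes = NULL, labels = NULL,
                       min_samples_leaf = 1, min_impurity_decrease = 0,
                       schema = default_schema()) {
  if (is.null(labels)) labels <- cohort$gold_diagnosis
  stopifnot(length(labels) == nrow(cohort))
  if (nrow(cohort) < 2) return(NULL)
  if (is.null(attributes)) attributes <- intersect(schema$name, names(cohort))
  attributes <- schema$name[schema$name %in% attributes]  # schema order
  f <- factor(labels, levels = hf_labels())
  y <- matrix(0, nrow(cohort), 4)
  y[cbind(seq_len(nrow(cohort)), as.integer(f))] <- 1
  parent <- gini_impurity(labels)
  floor_dec <- max(min_impurity_decrease, 1e-12)
  best <- NULL
  for (a in attributes) {
    cand <- attribute_splits(cohort[[a]], y, schema_kind(a, schema),
                             min_samples_leaf)
    if (is.null(cand)) next
    cand$decrease <- parent - cand$child_impurity
    cand <- cand[cand$decrease >= floor_dec, , drop = FALSE]
    if (!nrow(cand)) next
    top <- which(cand$decrease >= max(cand$decrease) - 1e-12)[1]
    if (is.null(best) || cand$decrease[top] > best$decrease + 1e-12) {
      best <- list(attribute = a, kind = schema_kind(a, schema),
                   threshold = cand$threshold[top],
                   decrease = cand$decrease[top],
                   na_left = cand$na_left[top])
    }
  }
  best
}

#' Induce a CART-style decision tree
#'
#' Recursive greedy partitioning with [best_split()] until a stopping
#' rule fires (pure node, `max_depth`, `min_samples_leaf`, or no
#' admissible split).  Leaves take the majority class, ties resolved in
#' [hf_labels()] order.  Every internal node records the side its
#' Missing values were routed to as an explicit Missing path
#' (`na_route`), so induced trees reach a leaf for every record; all
#' nodes carry provenance `"learned"`.
#'
#' @param cohort Cohort data frame with labels.
#' @param params See [induction_params()].
#' @param attributes Attributes available for splitting (default: full
#'   schema).
#' @param labels Diagnosis labels (default `cohort$gold_diagnosis`;
#'   must be complete).
#' @param schema Attribute schema.
#' @param tree_id Identifier for the induced model.
#' @return An `hf_tree`.
#' @export
induce_cart <- function(cohort, params = induction_params(),
                        attributes = NULL, labels = NULL,
                        schema = default_schema(), tree_id = "cart-pm") {
  if (is.null(labels)) labels <- cohort$gold_diagnosis
  if (is.null(labels) || !nrow(cohort))
    stop("induction needs a non-empty labeled cohort", call. = FALSE)
  if (anyNA(labels))
    stop("every training record needs a diagnosis label", call. = FALSE)
  if (is.null(attributes)) attributes <- intersect(schema$name, names(cohort))

  build <- function(idx, depth) {
    lab <- labels[idx]
    counts <- tabulate(factor(lab, levels = hf_labels()), nbins = 4)
    majority <- hf_labels()[which.max(counts)]
    if (length(unique(lab)) == 1 || depth >= params$max_depth)
      return(tree_leaf(majority, provenance = "learned"))
    sp <- best_split(cohort[idx, , drop = FALSE], attributes = attributes,
                     labels = lab,
                     min_samples_leaf = params$min_samples_leaf,
                     min_impurity_decrease = params$min_impurity_decrease,
                     schema = schema)
    if (is.null(sp)) return(tree_leaf(majority, provenance = "learned"))
    v <- cohort[[sp$attribute]][idx]
    if (sp$kind == "binary") {
      go_left <- !is.na(v) & !v
      go_right <- !is.na(v) & v
    } else {
      go_left <- !is.na(v) & v < sp$threshold
      go_right <- !is.na(v) & v >= sp$threshold
    }
    miss <- is.na(v)
    if (sp$na_left) go_left <- go_left | miss else go_right <- go_right | miss
    left <- build(idx[go_left], depth + 1)
    right <- build(idx[go_right], depth + 1)
    left$n <- sum(go_left); right$n <- sum(go_right)
    branches <- if (sp$kind == "binary") {
      list(list(value = FALSE, node = left), list(value = TRUE, node = right))
    } else {
      list(list(lo = -Inf, hi = sp$threshold, node = left),
           list(lo = sp$threshold, hi = Inf, node = right))
    }
    node <- tree_node(sp$attribute, branches,
                      na_route = if (sp$na_left) 1L else 2L,
                      provenance = "learned")
    node$n <- length(idx)
    node$decrease <- sp$decrease
    node
  }

  root <- build(seq_len(nrow(cohort)), 0)
  root$n <- nrow(cohort)
  decision_tree(root, tree_id = tree_id, schema = schema)
}

#' Rank attributes by their contribution to an induced tree
#'
#' Importance of an attribute is the total weighted Gini decrease of the
#' splits it supports in a tree induced from the cohort, normalized to
#' sum 1 (the usual CART impurity importance).
#'
#' @inheritParams induce_cart
#' @return Data frame (`attribute`, `importance`) in descending
#'   importance; all-zero importances in schema order when the labels
#'   are single-class.
#' @export
rank_features <- function(cohort, params = induction_params(),
                          attributes = NULL, labels = NULL,
                          schema = default_schema()) {
  if (is.null(labels)) labels <- cohort$gold_diagnosis
  if (is.null(attributes)) attributes <- intersect(schema$name, names(cohort))
  attributes <- schema$name[schema$name %in% attributes]
  imp <- stats::setNames(numeric(length(attributes)), attributes)
  if (length(unique(labels[!is.na(labels)])) >= 2) {
    tree <- induce_cart(cohort, params, attributes = attributes,
                        labels = labels, schema = schema)
    n_total <- nrow(cohort)
    walk_nodes(tree$root, function(node, depth) {
      if (!is_leaf(node) && !is.null(node$decrease))
        imp[node$attribute] <<- imp[node$attribute] +
          node$n / n_total * node$decrease
    })
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  out <- data.frame(attribute = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Cross-validated accuracy of the CART learner on a cohort
#'
#' Stratified k-fold cross-validation, seeded from `params$seed`:
#' records are assigned to folds within each diagnosis class, a tree is
#' induced on each training portion and scored on the held-out portion.
#'
#' @inheritParams induce_cart
#' @param k Number of folds.
#' @return Pooled held-out accuracy in percent.
#' @export
cv_accuracy <- function(cohort, params = induction_params(), k = 5,
                        attributes = NULL, schema = default_schema()) {
  labels <- cohort$gold_diagnosis
  stopifnot(!is.null(labels), !anyNA(labels))
  n <- nrow(cohort)
  fold <- integer(n)
  withr::with_seed(params$seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  correct <- 0L
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test) || all(test)) next
    tree <- induce_cart(cohort[!test, , drop = FALSE], params,
                        attributes = attributes, schema = schema)
    pred <- diagnose_cohort(tree, cohort[test, , drop = FALSE])
    correct <- correct + sum(pred == labels[test])
  }
  100 * correct / n
}

#' Summarize a candidate learner for algorithm ranking
#'
#' Convenience producing the `(accuracy, n_rules, n_attributes)` inputs
#' [rank_algorithms()] consumes, for the package's own CART learner.
#'
#' @inheritParams cv_accuracy
#' @param name Algorithm name to report.
#' @return One-row data frame: `algorithm`, `accuracy`, `n_rules`,
#'   `n_attributes`.
#' @export
cart_rank_input <- function(cohort, params = induction_params(), k = 5,
                            name = "CART", schema = default_schema()) {
  tree <- induce_cart(cohort, params, schema = schema)
  data.frame(algorithm = name,
             accuracy = cv_accuracy(cohort, params, k = k, schema = schema),
             n_rules = n_leaves(tree),
             n_attributes = length(unique(
               tree_splits(tree)$attribute)),
             stringsAsFactors = FALSE)
}

#' Rank candidate learning algorithms
#'
#' Candidates are compared on held-out accuracy (higher is better),
#' number of extracted rules and number of attributes involved (fewer is
#' better — a compact rule base is easier to audit).  Each quantity is
#' min-max normalized across the candidates and combined as
#' `rank = w_a * acc + w_r * (1 - rules) + w_t * (1 - attrs)`.
#' When a quantity has zero range across candidates its normalized value
#' is 1 for accuracy and 0 for the two counts, so a lone candidate
#' scores `sum(weights)`.
#'
#' @param candidates Data frame (or list of lists) with columns
#'   `algorithm`, `accuracy` (percent), `n_rules`, `n_attributes`.
#' @param weights Numeric weights `(accuracy, rules, attributes)`.
#' @return The candidates with a `rank_value` column, sorted by
#'   descending `rank_value`, ties by accuracy then name.
#' @export
#' @examples
#' rank_algorithms(data.frame(
#'   algorithm = c("CART", "CHAID"), accuracy = c(88.5, 82.1),
#'   n_rules = c(12, 30), n_attributes = c(4, 9)))
rank_algorithms <- function(candidates, weights = c(0.6, 0.2, 0.2)) {
  if (is.list(candidates) && !is.data.frame(candidates))
    candidates <- do.call(rbind, lapply(candidates, as.data.frame))
  stopifnot(is.data.frame(candidates),
            all(c("algorithm", "accuracy", "n_rules", "n_attributes")
                %in% names(candidates)),
            length(weights) == 3)
  if (!nrow(candidates)) stop("no candidates to rank", call. = FALSE)
  if (any(candidates$accuracy < 0 | candidates$accuracy > 100))
    stop("accuracy must lie in [0, 100] percent", call. = FALSE)
  if (any(candidates$n_rules < 1 | candidates$n_attributes < 1))
    stop("rule and attribute counts must be positive", call. = FALSE)
  norm <- function(x, degenerate) {
    r <- range(x)
    if (diff(r) == 0) rep(degenerate, length(x)) else (x - r[1]) / diff(r)
  }
  a <- norm(candidates$accuracy, 1)
  r <- norm(candidates$n_rules, 0)
  t <- norm(candidates$n_attributes, 0)
  candidates$rank_value <- weights[1] * a + weights[2] * (1 - r) +
    weights[3] * (1 - t)
  o <- order(-candidates$rank_value, -candidates$accuracy,
             candidates$algorithm)
  candidates[o, , drop = FALSE]
}
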