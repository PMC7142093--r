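#' Coverage of a knowledge model over a cohort
#'
#' A record is covered iff [diagnose()] reaches a leaf (i.e. does not
#' return `"Uncovered"`).  The report lists, for each uncovered record,
#' the node where traversal stopped, the attribute tested there, and
#' whether the failure was a Missing value or a domain gap.  An empty
#' cohort is vacuously covered (coverage 1).
#'
#' @param tree An `hf_tree`.
#' @param cohort Cohort data frame.
#' @return An `hf_coverage` list: `n_records`, `n_covered`, `coverage`,
#'   and `uncovered` (data frame `patient_id`, `failure_node`,
#'   `failure_attribute`, `failure_reason`, `row`).
#' @export
coverage <- function(tree, cohort) {
  n <- nrow(cohort)
  unc <- list()
  covered <- 0L
  for (i in seq_len(n)) {
    tr <- diagnose(tree, cohort[i, , drop = FALSE])
    if (identical(tr$outcome, "Uncovered")) {
      unc[[length(unc) + 1L]] <- data.frame(
        patient_id = as.character(cohort$patient_id[i]),
        failure_node = tr$failure_node,
        failure_attribute = tr$failure_attribute,
        failure_reason = tr$failure_reason,
        row = i, stringsAsFactors = FALSE)
    } else covered <- covered + 1L
  }
  uncovered <- if (length(unc)) do.call(rbind, unc) else
    data.frame(patient_id = character(), failure_node = character(),
               failure_attribute = character(), failure_reason = character(),
               row = integer(), stringsAsFactors = FALSE)
  structure(list(n_records = n, n_covered = covered,
                 coverage = if (n == 0) 1 else covered / n,
                 uncovered = uncovered),
            class = "hf_coverage")
}

#' @export
print.hf_coverage <- function(x, ...) {
  cat(sprintf("Coverage: %d/%d records (%.1f%%)\n", x$n_covered,
              x$n_records, 100 * x$coverage))
  if (nrow(x$uncovered)) {
    tab <- table(paste(x$uncovered$failure_node,
                       x$uncovered$failure_attribute,
                       x$uncovered$failure_reason))
    for (k in names(tab))
      cat(sprintf("  %s: %d record(s)\n", k, tab[[k]]))
  }
  invisible(x)
}

# interval gaps left by a continuous node's branches
node_gaps <- function(node) {
  lo <- vapply(node$branches, function(b) b$lo, numeric(1))
  hi <- vapply(node$branches, function(b) b$hi, numeric(1))
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  gaps <- list()
  if (lo[1] > -Inf) gaps[[length(gaps) + 1L]] <- c(-Inf, lo[1])
  for (j in seq_len(length(lo) - 1))
    if (hi[j] < lo[j + 1])
      gaps[[length(gaps) + 1L]] <- c(hi[j], lo[j + 1])
  if (hi[length(hi)] < Inf)
    gaps[[length(gaps) + 1L]] <- c(hi[length(hi)], Inf)
  gaps
}

modify_node <- function(node, id, fn) {
  if (identical(node$node_id, id)) return(fn(node))
  if (is_leaf(node)) return(node)
  node$branches <- lapply(node$branches, function(b) {
    b$node <- modify_node(b$node, id, fn)
    b
  })
  if (!is.null(node$na_branch))
    node$na_branch <- modify_node(node$na_branch, id, fn)
  node
}

# Learned subtree for an uncovered sub-population: labels come from the
# gold standard where available, else from dropping the record down the
# prediction model.  Too-small or unlabeled groups get a majority leaf.
graft_subtree <- function(subpop, pm, params, exclude_attribute, schema) {
  labels <- if ("gold_diagnosis" %in% names(subpop))
    subpop$gold_diagnosis else rep(NA_character_, nrow(subpop))
  need <- is.na(labels)
  if (any(need)) {
    pm_pred <- diagnose_cohort(pm, subpop[need, , drop = FALSE])
    labels[need] <- ifelse(pm_pred == "Uncovered", NA, pm_pred)
  }
  keep <- !is.na(labels)
  majority <- function(lab) {
    if (!length(lab)) return("NoHF")
    hf_labels()[which.max(tabulate(factor(lab, levels = hf_labels()),
                                   nbins = 4))]
  }
  if (sum(keep) < max(2, params$min_samples_leaf)) {
    node <- tree_leaf(majority(labels[keep]), provenance = "grafted")
  } else {
    attrs <- setdiff(intersect(schema$name, names(subpop)),
                     exclude_attribute)
    sub <- induce_cart(subpop[keep, , drop = FALSE], params,
                       attributes = attrs, labels = labels[keep],
                       schema = schema)
    node <- set_provenance(sub$root, "grafted")
  }
  node$node_id <- NULL  # fresh ids assigned when the refined tree is built
  map_nodes(node, function(n) { n$node_id <- NULL; n })
}

#' Hybridize an expert model with a learned prediction model
#'
#' The core refinement step: find every point where the expert clinical
#' knowledge model (CKM) fails to cover the cohort — typically a Missing
#' value meeting a node with no "Not Available" path — and graft a
#' learned subtree there, producing the refined model (R-CKM).  For each
#' distinct failure node, the uncovered sub-population reaching it is
#' collected and a subtree is re-fit on it over the attributes still
#' usable at that point (labels from the gold standard, else from
#' dropping the records down `pm`); the subtree is attached as the
#' node's `na_branch` (Missing failures) or as a new branch over the
#' uncovered interval (domain-gap failures).  All grafted nodes carry
#' provenance `"grafted"`.  Pre-existing nodes, tests and leaves are
#' untouched: the expert keeps precedence, so every record the CKM
#' already covered receives the identical diagnosis from the R-CKM, and
#' coverage can only increase.
#'
#' @param ckm Expert model (`hf_tree`).
#' @param pm Learned prediction model (`hf_tree`), used to label
#'   records without a gold diagnosis.
#' @param cohort Cohort driving the refinement (Missing values
#'   included), usually the training set.
#' @param params Induction parameters for the re-fit subtrees; groups
#'   smaller than `min_samples_leaf` get a majority-class leaf.
#' @param schema Attribute schema.
#' @return The refined `hf_tree` (tree id `<ckm id>-refined`).
#' @export
#' @examples
#' spec <- table1_default_spec(n = 120, seed = 3,
#'                             missingness = c(hf_symptoms_signs = 0.3))
#' cohort <- generate_cohort(spec)
#' pm <- induce_cart(cohort)
#' rckm <- hybridize(default_hf_ckm(), pm, cohort)
#' coverage(rckm, cohort)$coverage
hybridize <- function(ckm, pm, cohort, params = induction_params(),
                      schema = default_schema()) {
  stopifnot(inherits(ckm, "hf_tree"), inherits(pm, "hf_tree"))
  ckm_clean <- length(validate_tree(ckm, schema)) == 0
  cov <- coverage(ckm, cohort)
  if (!nrow(cov$uncovered)) return(ckm)
  root <- ckm$root
  unc <- cov$uncovered
  for (id in unique(unc$failure_node)) {
    here <- unc[unc$failure_node == id, , drop = FALSE]
    miss_rows <- here$row[here$failure_reason == "missing"]
    gap_rows <- here$row[here$failure_reason == "gap"]
    root <- modify_node(root, id, function(node) {
      if (length(miss_rows)) {
        node$na_branch <- graft_subtree(
          cohort[miss_rows, , drop = FALSE], pm, params,
          exclude_attribute = node$attribute, schema = schema)
      }
      if (length(gap_rows)) {
        vals <- cohort[[node$attribute]][gap_rows]
        fallback <- if (all(is.na(cohort$gold_diagnosis[gap_rows])))
          "NoHF" else hf_labels()[which.max(tabulate(
            factor(cohort$gold_diagnosis[gap_rows], levels = hf_labels()),
            nbins = 4))]
        for (g in node_gaps(node)) {
          in_gap <- gap_rows[vals >= g[1] & vals < g[2]]
          # gaps no record fell into still need a branch so the touched
          # node ends up fully partitioned
          sub <- if (length(in_gap))
            graft_subtree(cohort[in_gap, , drop = FALSE], pm, params,
                          exclude_attribute = character(0), schema = schema)
          else tree_leaf(fallback, provenance = "grafted")
          node$branches[[length(node$branches) + 1L]] <-
            list(lo = g[1], hi = g[2], node = sub)
        }
      }
      node
    })
  }
  out <- assign_node_ids(structure(
    list(tree_id = paste0(ckm$tree_id, "-refined"), root = root),
    class = "hf_tree"))
  if (ckm_clean) {
    issues <- validate_tree(out, schema)
    if (length(issues))
      stop("hybridization produced an invalid model:\n  ",
           paste(issues, collapse = "\n  "), call. = FALSE)
  }
  out
}

# ---- production rules ---------------------------------------------------

term_interval <- function(attribute, lo, hi, or_missing = FALSE) {
  list(attribute = attribute, kind = "interval", lo = lo, hi = hi,
       or_missing = or_missing)
}
term_equals <- function(attribute, value, or_missing = FALSE) {
  list(attribute = attribute, kind = "equals", value = value,
       or_missing = or_missing)
}
term_missing <- function(attribute) {
  list(attribute = attribute, kind = "missing")
}

term_text <- function(term) {
  txt <- switch(term$kind,
    missing = sprintf("%s is Missing", term$attribute),
    equals = sprintf("%s = %s", term$attribute, tolower(term$value)),
    interval = {
      if (is.infinite(term$lo) && is.infinite(term$hi)) "TRUE"
      else if (is.infinite(term$lo))
        sprintf("%s < %g", term$attribute, term$hi)
      else if (is.infinite(term$hi))
        sprintf("%s >= %g", term$attribute, term$lo)
      else sprintf("%g <= %s < %g", term$lo, term$attribute, term$hi)
    })
  if (isTRUE(term$or_missing)) paste0(txt, " (or Missing)") else txt
}

rule_text <- function(rule) {
  cond <- if (length(rule$conditions))
    paste(vapply(rule$conditions, term_text, character(1)),
          collapse = " AND ") else "TRUE"
  sprintf("IF %s THEN %s", cond, rule$conclusion)
}

#' Flatten a knowledge model into production rules
#'
#' One conjunctive IF-THEN rule per root-to-leaf path, terms in
#' root-to-leaf order.  Traversals through a dedicated `na_branch` emit
#' an "attribute is Missing" term; a branch that also receives routed
#' Missing values (`na_route`) has its term flagged `or_missing`, so the
#' rule set decides every record exactly the way tree traversal does.
#' The extracted rules are mutually exclusive, and their number equals
#' the tree's leaf count.  A rule is `"grafted"` if any node on its path
#' is, else `"learned"` if any node is, else `"expert"`.
#'
#' @param tree An `hf_tree`.
#' @param code_map Optional named character vector mapping attribute
#'   names to terminology code strings, carried through to the exported
#'   rule base.
#' @return An `hf_rulebase`: list with `rules`, `source_tree_id`,
#'   `code_map`.
#' @export
extract_rules <- function(tree, code_map = NULL) {
  stopifnot(inherits(tree, "hf_tree"))
  rules <- list()
  walk <- function(node, conds, provs) {
    provs <- c(provs, node$provenance)
    if (is_leaf(node)) {
      prov <- if ("grafted" %in% provs) "grafted"
              else if ("learned" %in% provs) "learned" else "expert"
      rules[[length(rules) + 1L]] <<- list(
        rule_id = sprintf("R%03d", length(rules) + 1L),
        conditions = conds, conclusion = node$leaf, provenance = prov,
        leaf_id = node$node_id)
      return(invisible(NULL))
    }
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      or_na <- identical(node$na_route, i) || isTRUE(node$na_route == i)
      term <- if (branch_is_binary(b))
        term_equals(node$attribute, b$value, or_missing = or_na)
      else term_interval(node$attribute, b$lo, b$hi, or_missing = or_na)
      walk(b$node, c(conds, list(term)), provs)
    }
    if (!is.null(node$na_branch))
      walk(node$na_branch, c(conds, list(term_missing(node$attribute))),
           provs)
  }
  walk(tree$root, list(), character(0))
  structure(list(rules = rules, source_tree_id = tree$tree_id,
                 code_map = code_map),
            class = "hf_rulebase")
}

#' @export
print.hf_rulebase <- function(x, ...) {
  cat(sprintf("Rule base from '%s': %d rules\n", x$source_tree_id,
              length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  [%s|%s] %s\n", r$rule_id, r$provenance, rule_text(r)))
  invisible(x)
}

term_matches <- function(term, value) {
  if (term$kind == "missing") return(is.na(value))
  if (is.na(value)) return(isTRUE(term$or_missing))
  if (term$kind == "equals") return(isTRUE(value == term$value))
  value >= term$lo && value < term$hi
}

#' Execute a rule base on a patient record
#'
#' Scans the mutually exclusive rules for the single one whose
#' conditions the record satisfies.  For any record the source tree
#' covers, the matching rule's conclusion equals the tree traversal
#' outcome.
#'
#' @param rb An `hf_rulebase`.
#' @param record Named list or one-row data frame.
#' @return List with `outcome` (diagnosis or `"Uncovered"`), `rule_id`
#'   and `rule_text` (NA when uncovered).
#' @export
apply_rules <- function(rb, record) {
  stopifnot(inherits(rb, "hf_rulebase"))
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  for (r in rb$rules) {
    ok <- TRUE
    for (term in r$conditions) {
      v <- if (term$attribute %in% names(record)) record[[term$attribute]]
           else NA
      if (!term_matches(term, v)) { ok <- FALSE; break }
    }
    if (ok)
      return(list(outcome = r$conclusion, rule_id = r$rule_id,
                  rule_text = rule_text(r)))
  }
  list(outcome = "Uncovered", rule_id = NA_character_,
       rule_text = NA_character_)
}

#' Export / import a shareable rule base
#'
#' Writes the rule base as a JSON document of per-rule blocks: rule id,
#' human-readable condition text, machine-readable condition terms,
#' conclusion, provenance, and (when a `code_map` is set) the
#' terminology code of each condition's attribute.  This is a
#' deliberately simplified analogue of a Medical Logic Module style
#' knowledge exchange format: the logic/condition/action intent is kept,
#' formal slot grammar and standards bindings are not.  The round-trip
#' `import_rule_base(export_rule_base(rb, p))` is lossless.
#'
#' @param rb An `hf_rulebase`.
#' @param path JSON file path.
#' @return `export_rule_base()` returns `path` invisibly;
#'   `import_rule_base()` returns the `hf_rulebase`.
#' @export
export_rule_base <- function(rb, path) {
  stopifnot(inherits(rb, "hf_rulebase"))
  code_of <- function(a)
    if (!is.null(rb$code_map) && a %in% names(rb$code_map))
      as.character(rb$code_map[[a]]) else NULL
  doc <- list(
    format = "hfcdss-rules", version = 1L,
    source_tree_id = rb$source_tree_id,
    code_map = as.list(rb$code_map),
    rules = lapply(rb$rules, function(r) list(
      rule_id = r$rule_id,
      text = rule_text(r),
      conclusion = r$conclusion,
      provenance = r$provenance,
      leaf_id = r$leaf_id,
      conditions = lapply(r$conditions, function(term) {
        out <- term
        if (!is.null(out$lo) && is.infinite(out$lo)) out$lo <- NULL
        if (!is.null(out$hi) && is.infinite(out$hi)) out$hi <- NULL
        out$code <- code_of(term$attribute)
        out
      }))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname export_rule_base
#' @export
import_rule_base <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "hfcdss-rules"))
    stop("not a rule-base document", call. = FALSE)
  rules <- lapply(doc$rules, function(r) list(
    rule_id = r$rule_id,
    conditions = lapply(r$conditions, function(term) {
      t <- list(attribute = term$attribute, kind = term$kind)
      if (term$kind == "interval") {
        t$lo <- if (is.null(term$lo)) -Inf else as.numeric(term$lo)
        t$hi <- if (is.null(term$hi)) Inf else as.numeric(term$hi)
        t$or_missing <- isTRUE(term$or_missing)
      } else if (term$kind == "equals") {
        t$value <- term$value
        t$or_missing <- isTRUE(term$or_missing)
      }
      t
    }),
    conclusion = r$conclusion, provenance = r$provenance,
    leaf_id = r$leaf_id))
  code_map <- if (length(doc$code_map)) unlist(doc$code_map) else NULL
  structure(list(rules = rules, source_tree_id = doc$source_tree_id,
                 code_map = code_map),
            class = "hf_rulebase")
}
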