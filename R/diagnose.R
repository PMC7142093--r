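#' Execute a knowledge model on a patient record
#'
#' Deterministic top-down traversal with a white-box explanation trace.
#' At each internal node the tested attribute's value selects the unique
#' matching branch; a Missing value follows the node's `na_route` or
#' `na_branch` when one exists.  Traversal never throws on Missing
#' values: if a Missing value meets a node with no Missing path, or a
#' present value matches no branch (a domain gap), the outcome is
#' `"Uncovered"` and the failure point is reported.
#'
#' @param tree An `hf_tree`.
#' @param record A named list or one-row data frame holding the schema
#'   attributes (`NA` = Missing).
#' @return An object of class `hf_trace`: a list with `outcome` (a
#'   diagnosis label or `"Uncovered"`), `path` (data frame of `node_id`,
#'   `attribute`, `observed`, `branch` in traversal order), and — when
#'   uncovered — `failure_node`, `failure_attribute` and
#'   `failure_reason` (`"missing"` or `"gap"`).
#' @export
#' @examples
#' ckm <- default_hf_ckm()
#' diagnose(ckm, list(hf_symptoms_signs = TRUE, lvef = 27.1))
diagnose <- function(tree, record) {
  stopifnot(inherits(tree, "hf_tree"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  path <- list()
  node <- tree$root
  repeat {
    if (is_leaf(node)) {
      return(structure(list(outcome = node$leaf, leaf_id = node$node_id,
                            path = path_frame(path)),
                       class = "hf_trace"))
    }
    a <- node$attribute
    v <- if (a %in% names(record)) record[[a]] else NA
    if (length(v) != 1) v <- NA
    if (is.na(v)) {
      if (!is.null(node$na_route)) {
        path[[length(path) + 1L]] <- list(node$node_id, a, NA,
                                          sprintf("missing -> branch %d",
                                                  node$na_route))
        node <- node$branches[[node$na_route]]$node
        next
      }
      if (!is.null(node$na_branch)) {
        path[[length(path) + 1L]] <- list(node$node_id, a, NA,
                                          "missing -> NA branch")
        node <- node$na_branch
        next
      }
      return(uncovered_trace(node, a, path, "missing"))
    }
    i <- match_branch(node, v)
    if (is.na(i))
      return(uncovered_trace(node, a, path, "gap"))
    path[[length(path) + 1L]] <- list(node$node_id, a, v,
                                      branch_label(node, i))
    node <- node$branches[[i]]$node
  }
}

match_branch <- function(node, value) {
  for (i in seq_along(node$branches)) {
    b <- node$branches[[i]]
    if (branch_is_binary(b)) {
      if (isTRUE(value == b$value)) return(i)
    } else if (value >= b$lo && value < b$hi) {
      return(i)
    }
  }
  NA_integer_
}

uncovered_trace <- function(node, attribute, path, reason) {
  structure(list(outcome = "Uncovered", path = path_frame(path),
                 failure_node = node$node_id,
                 failure_attribute = attribute,
                 failure_reason = reason),
            class = "hf_trace")
}

path_frame <- function(path) {
  if (!length(path))
    return(data.frame(node_id = character(), attribute = character(),
                      observed = character(), branch = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    node_id = vapply(path, function(p) p[[1]], character(1)),
    attribute = vapply(path, function(p) p[[2]], character(1)),
    observed = vapply(path, function(p) {
      v <- p[[3]]
      if (is.na(v)) NA_character_ else format(v)
    }, character(1)),
    branch = vapply(path, function(p) p[[4]], character(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.hf_trace <- function(x, ...) {
  cat("Diagnosis:", x$outcome, "\n")
  if (nrow(x$path)) {
    for (i in seq_len(nrow(x$path)))
      cat(sprintf("  %s: %s = %s  [%s]\n", x$path$node_id[i],
                  x$path$attribute[i],
                  ifelse(is.na(x$path$observed[i]), "Missing",
                         x$path$observed[i]),
                  x$path$branch[i]))
  }
  if (identical(x$outcome, "Uncovered"))
    cat(sprintf("  uncovered at node %s: attribute '%s' (%s)\n",
                x$failure_node, x$failure_attribute, x$failure_reason))
  invisible(x)
}

#' Diagnose every record of a cohort
#'
#' @param tree An `hf_tree` (or a rule base, see [apply_rules()]).
#' @param cohort Validated cohort data frame.
#' @return Character vector of outcomes, one per row (`"Uncovered"`
#'   where the model reaches no leaf).
#' @export
diagnose_cohort <- function(tree, cohort) {
  one <- if (inherits(tree, "hf_rulebase"))
    function(i) apply_rules(tree, cohort[i, , drop = FALSE])$outcome
  else
    function(i) diagnose(tree, cohort[i, , drop = FALSE])$outcome
  vapply(seq_len(nrow(cohort)), one, character(1))
}
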