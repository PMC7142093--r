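#' @name decision_tree
#' @title Decision-tree knowledge models
#'
#' @description
#' Knowledge models are single-rooted attribute-test trees.  An internal
#' node tests one schema attribute; its branches partition the attribute's
#' domain (half-open intervals `[lo, hi)` for continuous attributes,
#' `FALSE`/`TRUE` for binary ones), so for any present value exactly one
#' branch applies.  A node may additionally route Missing values, either
#' to one of its existing branches (`na_route`, the policy learned trees
#' use) or down a dedicated subtree (`na_branch`, the "Not Available"
#' path that hybridization grafts).  Leaves carry one of the four
#' diagnoses.  Every node records its provenance: `"expert"` for nodes
#' authored from clinical guidelines, `"learned"` for induced nodes, and
#' `"grafted"` for nodes added by hybridization.
#'
#' `tree_leaf()` and `tree_node()` build nodes; `decision_tree()` wraps a
#' root node, assigns any missing node ids (pre-order `n1`, `n2`, ...)
#' and checks the structural invariants.
#'
#' @param label Leaf diagnosis, one of [hf_labels()].
#' @param attribute Name of the tested schema attribute.
#' @param branches For `tree_node()`: list of branches, each a list with
#'   `node` (child) plus either `lo`/`hi` (continuous interval, `-Inf` /
#'   `Inf` allowed) or `value` (logical, binary attribute).
#' @param na_route Optional integer: index of the branch that also
#'   receives records whose tested value is Missing.
#' @param na_branch Optional node: dedicated subtree for Missing values.
#' @param provenance `"expert"`, `"learned"` or `"grafted"`.
#' @param node_id Optional explicit node identifier.
#' @param root Root node.
#' @param tree_id Identifier for the whole model.
#' @param schema Attribute schema, see [default_schema()].
#' @return `tree_leaf()`/`tree_node()` return node lists; `decision_tree()`
#'   returns an object of class `hf_tree`.
NULL

PROVENANCE <- c("expert", "learned", "grafted")

#' @rdname decision_tree
#' @export
tree_leaf <- function(label, provenance = "expert", node_id = NULL) {
  stopifnot(label %in% hf_labels(), provenance %in% PROVENANCE)
  structure(list(node_id = node_id, leaf = label, provenance = provenance),
            class = "hf_node")
}

#' @rdname decision_tree
#' @export
tree_node <- function(attribute, branches, na_route = NULL, na_branch = NULL,
                      provenance = "expert", node_id = NULL) {
  stopifnot(is.list(branches), length(branches) >= 1,
            provenance %in% PROVENANCE)
  if (!is.null(na_route))
    stopifnot(length(na_route) == 1, na_route >= 1,
              na_route <= length(branches))
  structure(list(node_id = node_id, attribute = attribute,
                 branches = branches, na_route = na_route,
                 na_branch = na_branch, provenance = provenance),
            class = "hf_node")
}

#' Make a set of interval branches from cut points
#'
#' Convenience for multiway continuous nodes: `cuts = c(40, 50)` with
#' three children yields branches `[-Inf, 40)`, `[40, 50)`, `[50, Inf)`.
#'
#' @param cuts Strictly increasing numeric cut points.
#' @param children List of `length(cuts) + 1` child nodes.
#' @return List of branches suitable for [tree_node()].
#' @export
interval_branches <- function(cuts, children) {
  stopifnot(length(children) == length(cuts) + 1,
            !is.unsorted(cuts, strictly = TRUE))
  bounds <- c(-Inf, cuts, Inf)
  lapply(seq_along(children), function(i)
    list(lo = bounds[i], hi = bounds[i + 1], node = children[[i]]))
}

is_leaf <- function(node) !is.null(node$leaf)

#' @rdname decision_tree
#' @export
decision_tree <- function(root, tree_id = "tree", schema = default_schema()) {
  tree <- structure(list(tree_id = tree_id, root = root), class = "hf_tree")
  tree <- assign_node_ids(tree)
  issues <- validate_tree(tree, schema)
  if (length(issues))
    stop("invalid decision tree:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  tree
}

# Pre-order walk over nodes (na_branch subtrees included, after branches).
walk_nodes <- function(node, fn, depth = 0) {
  fn(node, depth)
  if (!is_leaf(node)) {
    for (b in node$branches) walk_nodes(b$node, fn, depth + 1)
    if (!is.null(node$na_branch)) walk_nodes(node$na_branch, fn, depth + 1)
  }
  invisible(NULL)
}

map_nodes <- function(node, fn) {
  node <- fn(node)
  if (!is_leaf(node)) {
    node$branches <- lapply(node$branches, function(b) {
      b$node <- map_nodes(b$node, fn)
      b
    })
    if (!is.null(node$na_branch))
      node$na_branch <- map_nodes(node$na_branch, fn)
  }
  node
}

assign_node_ids <- function(tree) {
  counter <- new.env()
  counter$i <- 0L
  used <- character(0)
  walk_nodes(tree$root, function(n, d)
    if (!is.null(n$node_id)) used <<- c(used, n$node_id))
  fresh <- function() {
    repeat {
      counter$i <- counter$i + 1L
      id <- paste0("n", counter$i)
      if (!id %in% used) return(id)
    }
  }
  tree$root <- map_nodes(tree$root, function(n) {
    if (is.null(n$node_id)) n$node_id <- fresh()
    n
  })
  tree
}

#' Count the leaves of a knowledge model
#'
#' Leaves inside dedicated `na_branch` subtrees count; `na_route`
#' references do not add leaves (they reuse an existing branch).
#'
#' @param tree An `hf_tree`.
#' @return Integer leaf count (equals the number of production rules
#'   [extract_rules()] yields).
#' @export
n_leaves <- function(tree) {
  n <- 0L
  walk_nodes(tree$root, function(node, depth) {
    if (is_leaf(node)) n <<- n + 1L
  })
  n
}

#' List the splits of a knowledge model
#'
#' @param tree An `hf_tree`.
#' @return Data frame with one row per internal node: `node_id`,
#'   `attribute`, `thresholds` (interior cut points, comma-separated),
#'   `depth`, `provenance`.
#' @export
tree_splits <- function(tree) {
  rows <- list()
  walk_nodes(tree$root, function(node, depth) {
    if (!is_leaf(node)) {
      los <- vapply(node$branches, function(b)
        if (is.null(b$lo)) NA_real_ else b$lo, numeric(1))
      cuts <- sort(los[is.finite(los)])
      rows[[length(rows) + 1L]] <<- data.frame(
        node_id = node$node_id, attribute = node$attribute,
        thresholds = paste(cuts, collapse = ","), depth = depth,
        provenance = node$provenance, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows))
    return(data.frame(node_id = character(), attribute = character(),
                      thresholds = character(), depth = integer(),
                      provenance = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

branch_is_binary <- function(branch) !is.null(branch$value)

#' Validate a knowledge model's structural invariants
#'
#' Reports (rather than throws) structural problems: unknown or
#' kind-mismatched attributes, branch sets that overlap or leave gaps in
#' the attribute domain, duplicate node ids, invalid leaf labels or
#' provenance, bad `na_route` indices.  Nodes that neither route nor
#' branch Missing values are reported as informational `na-gap` notes —
#' they are legal (the expert model ships that way on purpose) but mark
#' where hybridization has work to do.
#'
#' @param tree An `hf_tree`.
#' @param schema Attribute schema.
#' @param na_notes If `TRUE`, include the informational `na-gap` notes.
#' @return Character vector of issues; empty iff all invariants hold.
#'   `na-gap` notes are prefixed `"note:"` and do not count as failures
#'   for [decision_tree()] or [load_tree()].
#' @export
validate_tree <- function(tree, schema = default_schema(), na_notes = FALSE) {
  issues <- character(0)
  notes <- character(0)
  ids <- character(0)
  walk_nodes(tree$root, function(node, depth) {
    id <- if (is.null(node$node_id)) "<unset>" else node$node_id
    ids <<- c(ids, id)
    if (!node$provenance %in% PROVENANCE)
      issues <<- c(issues, sprintf("node %s: invalid provenance '%s'",
                                   id, node$provenance))
    if (is_leaf(node)) {
      if (!node$leaf %in% hf_labels())
        issues <<- c(issues, sprintf("node %s: invalid leaf label '%s'",
                                     id, node$leaf))
      return(invisible(NULL))
    }
    a <- node$attribute
    k <- match(a, schema$name)
    if (is.na(k)) {
      issues <<- c(issues, sprintf("node %s: unknown attribute '%s'", id, a))
      return(invisible(NULL))
    }
    binary_branches <- vapply(node$branches, branch_is_binary, logical(1))
    if (schema$kind[k] == "binary") {
      if (!all(binary_branches)) {
        issues <<- c(issues,
                     sprintf("node %s: interval branch on binary '%s'", id, a))
      } else {
        vals <- vapply(node$branches, function(b) b$value, logical(1))
        if (anyDuplicated(vals))
          issues <<- c(issues,
                       sprintf("node %s: duplicate binary branch on '%s'",
                               id, a))
        if (!setequal(vals, c(TRUE, FALSE)))
          issues <<- c(issues,
                       sprintf("node %s: binary branches on '%s' leave a gap",
                               id, a))
      }
    } else {
      if (any(binary_branches)) {
        issues <<- c(issues,
                     sprintf("node %s: binary branch on continuous '%s'",
                             id, a))
      } else {
        lo <- vapply(node$branches, function(b) b$lo, numeric(1))
        hi <- vapply(node$branches, function(b) b$hi, numeric(1))
        if (any(hi <= lo)) {
          issues <<- c(issues, sprintf("node %s: empty interval branch", id))
        } else {
          o <- order(lo)
          slo <- lo[o]; shi <- hi[o]
          if (slo[1] != -Inf)
            issues <<- c(issues, sprintf(
              "node %s: gap below %g on '%s'", id, slo[1], a))
          if (shi[length(shi)] != Inf)
            issues <<- c(issues, sprintf(
              "node %s: gap above %g on '%s'", id, shi[length(shi)], a))
          if (length(slo) > 1) {
            for (j in seq_len(length(slo) - 1)) {
              if (shi[j] > slo[j + 1])
                issues <<- c(issues, sprintf(
                  "node %s: overlapping branches on '%s' around %g",
                  id, a, slo[j + 1]))
              if (shi[j] < slo[j + 1])
                issues <<- c(issues, sprintf(
                  "node %s: gap on '%s' over [%g, %g)",
                  id, a, shi[j], slo[j + 1]))
            }
          }
        }
      }
    }
    if (!is.null(node$na_route) &&
        (node$na_route < 1 || node$na_route > length(node$branches)))
      issues <<- c(issues, sprintf("node %s: na_route out of range", id))
    if (!is.null(node$na_route) && !is.null(node$na_branch))
      issues <<- c(issues,
                   sprintf("node %s: both na_route and na_branch set", id))
    if (is.null(node$na_route) && is.null(node$na_branch))
      notes <<- c(notes, sprintf(
        "note: node %s ('%s') has no Missing-value path", id, a))
    invisible(NULL)
  })
  if (anyDuplicated(ids))
    issues <- c(issues, sprintf("duplicate node id '%s'",
                                ids[duplicated(ids)][1]))
  if (na_notes) c(issues, notes) else issues
}

# ---- JSON serialization -------------------------------------------------

node_to_list <- function(node) {
  if (is_leaf(node))
    return(list(node_id = node$node_id, leaf = node$leaf,
                provenance = node$provenance))
  out <- list(node_id = node$node_id, attribute = node$attribute,
              provenance = node$provenance)
  out$branches <- lapply(node$branches, function(b) {
    child <- node_to_list(b$node)
    if (branch_is_binary(b)) {
      list(value = b$value, node = child)
    } else {
      # JSON has no Inf: open interval ends are simply omitted
      br <- list()
      if (is.finite(b$lo)) br$lo <- b$lo
      if (is.finite(b$hi)) br$hi <- b$hi
      br$node <- child
      br
    }
  })
  if (!is.null(node$na_route)) out$na_route <- node$na_route
  if (!is.null(node$na_branch)) out$na_branch <- node_to_list(node$na_branch)
  out
}

list_to_node <- function(x) {
  absent <- function(v) is.null(v) || length(v) == 0
  if (!absent(x$leaf))
    return(tree_leaf(x$leaf, provenance = x$provenance, node_id = x$node_id))
  branches <- lapply(x$branches, function(b) {
    child <- list_to_node(b$node)
    if (!absent(b$value)) {
      list(value = isTRUE(b$value), node = child)
    } else {
      list(lo = if (absent(b$lo)) -Inf else as.numeric(b$lo),
           hi = if (absent(b$hi)) Inf else as.numeric(b$hi),
           node = child)
    }
  })
  tree_node(x$attribute, branches,
            na_route = if (absent(x$na_route)) NULL else as.integer(x$na_route),
            na_branch = if (absent(x$na_branch)) NULL
                        else list_to_node(x$na_branch),
            provenance = x$provenance, node_id = x$node_id)
}

#' Save / load a knowledge model as JSON
#'
#' The JSON round-trip is lossless on structure, tests, node ids and
#' provenance: `load_tree(save_tree(t, p))` is structurally identical to
#' `t`.  Loading validates the model and refuses trees that violate the
#' structural invariants (e.g. overlapping branch intervals).
#'
#' @param tree An `hf_tree`.
#' @param path JSON file path.
#' @param schema Attribute schema used for validation on load.
#' @return `save_tree()` returns `path` invisibly; `load_tree()` returns
#'   the `hf_tree`.
#' @export
save_tree <- function(tree, path) {
  stopifnot(inherits(tree, "hf_tree"))
  doc <- list(format = "hfcdss-tree", version = 1L, tree_id = tree$tree_id,
              root = node_to_list(tree$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path, schema = default_schema()) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed knowledge-model JSON: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(doc$root))
    stop("malformed knowledge-model JSON: no root node", call. = FALSE)
  root <- tryCatch(list_to_node(doc$root),
                   error = function(e) stop("malformed knowledge-model JSON: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  tree_id <- if (is.null(doc$tree_id)) "tree" else doc$tree_id
  decision_tree(root, tree_id = tree_id, schema = schema)
}

set_provenance <- function(node, provenance) {
  map_nodes(node, function(n) {
    n$provenance <- provenance
    n
  })
}

branch_label <- function(node, i) {
  b <- node$branches[[i]]
  if (branch_is_binary(b))
    return(sprintf("%s = %s", node$attribute, tolower(b$value)))
  if (is.infinite(b$lo) && is.infinite(b$hi)) return("always")
  if (is.infinite(b$lo)) return(sprintf("%s < %g", node$attribute, b$hi))
  if (is.infinite(b$hi)) return(sprintf("%s >= %g", node$attribute, b$lo))
  sprintf("%g <= %s < %g", b$lo, node$attribute, b$hi)
}

#' @export
print.hf_tree <- function(x, ...) {
  cat(sprintf("Decision tree '%s' (%d leaves)\n", x$tree_id, n_leaves(x)))
  show <- function(node, indent, prefix) {
    pad <- strrep("  ", indent)
    if (is_leaf(node)) {
      cat(sprintf("%s%s-> %s  [%s %s]\n", pad, prefix, node$leaf,
                  node$provenance, node$node_id))
      return(invisible(NULL))
    }
    cat(sprintf("%s%s%s?  [%s %s]\n", pad, prefix, node$attribute,
                node$provenance, node$node_id))
    for (i in seq_along(node$branches))
      show(node$branches[[i]]$node, indent + 1,
           paste0(branch_label(node, i), ": "))
    if (!is.null(node$na_route))
      cat(sprintf("%s  %s missing: -> branch %d\n", pad, node$attribute,
                  node$na_route))
    if (!is.null(node$na_branch))
      show(node$na_branch, indent + 1,
           sprintf("%s missing: ", node$attribute))
  }
  show(x$root, 0, "")
  invisible(x)
}

#' Render a knowledge model as Graphviz DOT text
#'
#' @param tree An `hf_tree`.
#' @return A character scalar of DOT source (write it to a `.dot` file
#'   and render with graphviz).
#' @export
tree_to_dot <- function(tree) {
  lines <- c(sprintf("digraph \"%s\" {", tree$tree_id),
             "  node [shape=box, fontname=\"Helvetica\"];")
  colour <- c(expert = "lightblue", learned = "lightyellow",
              grafted = "lightsalmon")
  emit <- function(node) {
    lab <- if (is_leaf(node)) node$leaf else paste0(node$attribute, "?")
    lines <<- c(lines, sprintf(
      "  %s [label=\"%s\", style=filled, fillcolor=%s];",
      node$node_id, lab, colour[[node$provenance]]))
    if (is_leaf(node)) return(invisible(NULL))
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      lines <<- c(lines, sprintf("  %s -> %s [label=\"%s\"];",
                                 node$node_id, b$node$node_id,
                                 branch_label(node, i)))
      emit(b$node)
    }
    if (!is.null(node$na_route))
      lines <<- c(lines, sprintf(
        "  %s -> %s [label=\"missing\", style=dashed];",
        node$node_id, node$branches[[node$na_route]]$node$node_id))
    if (!is.null(node$na_branch)) {
      lines <<- c(lines, sprintf(
        "  %s -> %s [label=\"missing\", style=dashed];",
        node$node_id, node$na_branch$node_id))
      emit(node$na_branch)
    }
  }
  emit(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}
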