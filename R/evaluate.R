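#' Diagnostic-accuracy report against a gold standard
#'
#' Builds the 4x4 confusion matrix (gold x predicted, fixed label order
#' HFrEF, HFmrEF, HFpEF, NoHF), the overall and per-gold-class
#' concordance (percent agreement), the sensitivity and specificity of
#' the binary HF-vs-no-HF collapse, and the product-moment association
#' (phi) between the binary gold and predicted codes.
#'
#' Predictions of `"Uncovered"` (the engine reached no leaf) are handled
#' per `uncovered`: `"exclude"` (default) drops them from the confusion
#' matrix and all metrics and reports them in `n_uncovered`;
#' `"discordant"` keeps them in every denominator as automatic
#' disagreements — the right convention when engines of different
#' coverage are compared on the same cohort.
#'
#' @param gold Character vector of gold diagnoses.
#' @param predicted Character vector of predicted diagnoses, may contain
#'   `"Uncovered"`.
#' @param uncovered `"exclude"` or `"discordant"`.
#' @return An `hf_eval` list: `confusion`, `overall_concordance`
#'   (percent), `per_class_concordance` (percent per gold label),
#'   `sensitivity`, `specificity`, `association`, `n`, `n_covered`,
#'   `n_uncovered`.
#' @export
#' @examples
#' gold <- c(rep("HFrEF", 3), rep("NoHF", 3))
#' evaluate(gold, c("HFrEF", "HFrEF", "NoHF", "NoHF", "NoHF", "NoHF"))
evaluate <- function(gold, predicted, uncovered = c("exclude", "discordant")) {
  uncovered <- match.arg(uncovered)
  if (length(gold) != length(predicted))
    stop("gold and predicted must have equal length", call. = FALSE)
  stopifnot(all(gold %in% hf_labels()),
            all(predicted %in% c(hf_labels(), "Uncovered")))
  cov <- predicted != "Uncovered"
  if (!any(cov))
    stop("no covered predictions to evaluate", call. = FALSE)
  confusion <- table(
    gold = factor(gold[cov], levels = hf_labels()),
    predicted = factor(predicted[cov], levels = hf_labels()))
  agree <- gold == predicted   # Uncovered never equals a label
  denom_all <- if (uncovered == "exclude") sum(cov) else length(gold)
  overall <- 100 * sum(agree) / denom_all
  per_class <- vapply(hf_labels(), function(cl) {
    in_cl <- gold == cl & (uncovered == "discordant" | cov)
    if (!any(in_cl)) return(NA_real_)
    100 * sum(agree[in_cl]) / sum(in_cl)
  }, numeric(1))
  # binary HF (any subtype) vs no-HF collapse
  use <- if (uncovered == "exclude") cov else rep(TRUE, length(gold))
  g_hf <- gold[use] != "NoHF"
  p_hf <- ifelse(predicted[use] == "Uncovered",
                 !g_hf,               # discordant: scored as the wrong class
                 predicted[use] != "NoHF")
  tp <- sum(g_hf & p_hf); fn <- sum(g_hf & !p_hf)
  tn <- sum(!g_hf & !p_hf); fp <- sum(!g_hf & p_hf)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  assoc <- if (stats::var(g_hf) > 0 && stats::var(p_hf) > 0)
    stats::cor(as.numeric(g_hf), as.numeric(p_hf)) else NA_real_
  structure(list(confusion = confusion,
                 overall_concordance = overall,
                 per_class_concordance = per_class,
                 sensitivity = sens, specificity = spec,
                 association = assoc,
                 n = length(gold), n_covered = sum(cov),
                 n_uncovered = sum(!cov), uncovered_policy = uncovered),
            class = "hf_eval")
}

#' @export
print.hf_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d records (%d uncovered, policy: %s)\n",
              x$n, x$n_uncovered, x$uncovered_policy))
  print(x$confusion)
  cat(sprintf("Overall concordance: %.1f%%\n", x$overall_concordance))
  pc <- x$per_class_concordance
  cat("Per-class: ",
      paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", "), "\n")
  cat(sprintf("HF vs no-HF: sensitivity %.3f, specificity %.3f, phi %.3f\n",
              x$sensitivity, x$specificity, x$association))
  invisible(x)
}

#' Compare diagnostic engines on one cohort
#'
#' Runs each engine (decision tree or rule base) on the identical cohort
#' and evaluates it against the gold diagnoses.  Uncovered records are
#' scored as discordant by default so that engines of different coverage
#' are compared on the same denominator; engines failing on more than
#' half the cohort are flagged, not fatal.
#'
#' @param cohort Cohort with `gold_diagnosis` set.
#' @param engines Named list of `hf_tree` / `hf_rulebase` objects.
#' @param uncovered Scoring policy, see [evaluate()].
#' @return An `hf_comparison`: list with `reports` (one `hf_eval` per
#'   engine), `table` (side-by-side data frame: engine, coverage,
#'   overall and per-class concordance, sensitivity, specificity) and
#'   `flags`.
#' @export
compare_engines <- function(cohort, engines,
                            uncovered = c("discordant", "exclude")) {
  uncovered <- match.arg(uncovered)
  stopifnot(length(engines) >= 1, !is.null(names(engines)),
            all(nzchar(names(engines))))
  gold <- cohort$gold_diagnosis
  stopifnot(!is.null(gold), !anyNA(gold))
  reports <- list()
  rows <- list()
  flags <- character(0)
  for (nm in names(engines)) {
    pred <- diagnose_cohort(engines[[nm]], cohort)
    n_unc <- sum(pred == "Uncovered")
    if (n_unc > nrow(cohort) / 2)
      flags <- c(flags, sprintf(
        "engine '%s' failed on %d/%d records", nm, n_unc, nrow(cohort)))
    rep <- if (n_unc < nrow(cohort)) {
      evaluate(gold, pred, uncovered = uncovered)
    } else {
      # engine reached no leaf for any record: no confusion matrix exists
      list(overall_concordance = if (uncovered == "discordant") 0 else
             NA_real_,
           per_class_concordance = stats::setNames(rep(NA_real_, 4),
                                                   hf_labels()),
           sensitivity = NA_real_, specificity = NA_real_)
    }
    reports[[nm]] <- rep
    rows[[nm]] <- data.frame(
      engine = nm,
      coverage = 1 - n_unc / nrow(cohort),
      overall = rep$overall_concordance,
      HFrEF = rep$per_class_concordance[["HFrEF"]],
      HFmrEF = rep$per_class_concordance[["HFmrEF"]],
      HFpEF = rep$per_class_concordance[["HFpEF"]],
      NoHF = rep$per_class_concordance[["NoHF"]],
      sensitivity = rep$sensitivity,
      specificity = rep$specificity,
      stringsAsFactors = FALSE)
  }
  structure(list(reports = reports, table = do.call(rbind, rows),
                 flags = flags, uncovered_policy = uncovered),
            class = "hf_comparison")
}

#' @export
print.hf_comparison <- function(x, ...) {
  cat(sprintf("Engine comparison (uncovered scored as %s)\n",
              x$uncovered_policy))
  print(x$table, row.names = FALSE, digits = 4)
  for (f in x$flags) cat("flag:", f, "\n")
  invisible(x)
}

#' Subgroup evaluation: echo subsets and age strata
#'
#' `subset = "setA"` evaluates on the cohort as given (all
#' echocardiographic parameters available).  `subset = "setB"` masks
#' every echo attribute except LVEF, LAVI and LVMI (i.e. E/e', septal
#' e', TRV, GLS become Missing) before diagnosis, emulating a reduced
#' echo protocol.  Alternatively `age_breaks` partitions the cohort
#' into age strata, each evaluated separately; stratum counts sum to
#' the cohort size, and empty strata are reported with `n = 0` and no
#' metrics.
#'
#' @param cohort Cohort with `gold_diagnosis`.
#' @param engine An `hf_tree` or `hf_rulebase`.
#' @param subset `"setA"` or `"setB"` (ignored when `age_breaks` given).
#' @param age_breaks Optional numeric break points (passed to `cut`,
#'   right-open, extended to cover the data).
#' @param uncovered Scoring policy, see [evaluate()].
#' @return For echo subsets: one `hf_eval`.  For age strata: a named
#'   list of `hf_eval` (or `list(n = 0)` for empty strata).
#' @export
subgroup_eval <- function(cohort, engine, subset = c("setA", "setB"),
                          age_breaks = NULL,
                          uncovered = c("exclude", "discordant")) {
  uncovered <- match.arg(uncovered)
  if (!is.null(age_breaks)) {
    strata <- cut(cohort$age, breaks = age_breaks, right = FALSE,
                  include.lowest = TRUE)
    out <- list()
    for (lv in levels(strata)) {
      rows <- which(!is.na(strata) & strata == lv)
      out[[lv]] <- if (!length(rows)) list(n = 0L) else
        evaluate(cohort$gold_diagnosis[rows],
                 diagnose_cohort(engine, cohort[rows, , drop = FALSE]),
                 uncovered = uncovered)
    }
    return(out)
  }
  subset <- match.arg(subset)
  if (subset == "setB") {
    for (a in c("e_over_eprime", "septal_eprime", "trv", "gls"))
      cohort[[a]] <- NA_real_
  }
  evaluate(cohort$gold_diagnosis, diagnose_cohort(engine, cohort),
           uncovered = uncovered)
}

#' Cohort summary table, HF vs no-HF
#'
#' Per attribute: mean +- SD per group with an unpaired two-sample
#' t-test for continuous attributes; percent per group with a
#' chi-squared test (Fisher's exact test when any expected cell count
#' is below 5) for binary ones.  Groups are the binary collapse of the
#' gold diagnosis.  Attributes with degenerate variance in both groups
#' get P = 1 and a flag.
#'
#' @param cohort Cohort with `gold_diagnosis`.
#' @param schema Attribute schema.
#' @param var_equal Passed to [stats::t.test()]; the classic unpaired
#'   Student test pools variances.
#' @return Data frame: `attribute`, `kind`, `hf` and `no_hf` summary
#'   strings, `hf_mean`/`no_hf_mean` (means or proportions),
#'   `p_value`, `test`, `flag`.
#' @export
summarize_cohort <- function(cohort, schema = default_schema(),
                             var_equal = TRUE) {
  gold <- cohort$gold_diagnosis
  stopifnot(!is.null(gold), !anyNA(gold))
  hf <- gold != "NoHF"
  if (!any(hf) || !any(!hf))
    stop("both groups (HF and no-HF) must be non-empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(schema)), function(i) {
    a <- schema$name[i]
    v <- cohort[[a]]
    flag <- ""
    if (schema$kind[i] == "continuous") {
      x <- v[hf & !is.na(v)]; y <- v[!hf & !is.na(v)]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::sd(x) == 0 && stats::sd(y) == 0)) {
        p <- 1; flag <- "degenerate"
      } else {
        p <- stats::t.test(x, y, var.equal = var_equal)$p.value
      }
      data.frame(
        attribute = a, kind = "continuous",
        hf = sprintf("%.1f ± %.1f", mean(x), stats::sd(x)),
        no_hf = sprintf("%.1f ± %.1f", mean(y), stats::sd(y)),
        hf_mean = mean(x), no_hf_mean = mean(y),
        p_value = p, test = "t", flag = flag, stringsAsFactors = FALSE)
    } else {
      x <- v[hf & !is.na(v)]; y <- v[!hf & !is.na(v)]
      tab <- rbind(c(sum(x), length(x) - sum(x)),
                   c(sum(y), length(y) - sum(y)))
      if (any(rowSums(tab) == 0) || all(tab[, 1] == rowSums(tab)) ||
          all(tab[, 1] == 0)) {
        p <- 1; test <- "chisq"; flag <- "degenerate"
      } else {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          p <- stats::fisher.test(tab)$p.value
          test <- "fisher"
        } else {
          p <- stats::chisq.test(tab, correct = FALSE)$p.value
          test <- "chisq"
        }
      }
      data.frame(
        attribute = a, kind = "binary",
        hf = sprintf("%.1f%%", 100 * mean(x)),
        no_hf = sprintf("%.1f%%", 100 * mean(y)),
        hf_mean = mean(x), no_hf_mean = mean(y),
        p_value = p, test = test, flag = flag, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
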