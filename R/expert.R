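#' Classify LVEF into the guideline ejection-fraction strata
#'
#' Heart failure is phenotyped by left ventricular ejection fraction:
#' reduced (LVEF < 40%), mid-range (40% <= LVEF < 50%) and preserved
#' (LVEF >= 50%).  Boundaries are exactly as the guideline states: 40.0
#' is mid-range, 50.0 is preserved.
#'
#' @param lvef Numeric LVEF in percent, in `[0, 100]`.  Vectorized.
#' @return Character vector over `{"REDUCED", "MID_RANGE", "PRESERVED"}`.
#' @export
#' @examples
#' classify_lvef(c(39.9, 40, 49.9, 50))
classify_lvef <- function(lvef) {
  if (anyNA(lvef))
    stop("LVEF is Missing: stratum undefined; route via the model's ",
         "Missing path instead", call. = FALSE)
  if (any(lvef < 0 | lvef > 100))
    stop("LVEF must lie in [0, 100] percent", call. = FALSE)
  ifelse(lvef < 40, "REDUCED", ifelse(lvef < 50, "MID_RANGE", "PRESERVED"))
}

#' Default supporting-evidence thresholds for the expert model
#'
#' The HF definition requires, besides symptoms or signs, at least one
#' objective criterion (elevated natriuretic peptide, structural heart
#' disease, or diastolic dysfunction).  The expert model operationalizes
#' this on the captured attributes with configurable cut-offs in the
#' spirit of the 2016 ESC guideline: NT-proBNP >= 125 pg/L, LAVI >= 34
#' mL/m2, LVMI >= 115 (male) / 95 (female) mg/m2, E/e' >= 13, or an
#' abnormal ECG.
#'
#' @param nt_probnp NT-proBNP cut-off, pg/L.
#' @param lavi Left atrial volume index cut-off, mL/m2.
#' @param lvmi_male,lvmi_female Sex-specific LV mass index cut-offs, mg/m2.
#' @param e_over_eprime E/e' ratio cut-off (dimensionless).
#' @return Named list of thresholds, validated.
#' @export
hf_thresholds <- function(nt_probnp = 125, lavi = 34, lvmi_male = 115,
                          lvmi_female = 95, e_over_eprime = 13) {
  th <- list(nt_probnp = nt_probnp, lavi = lavi, lvmi_male = lvmi_male,
             lvmi_female = lvmi_female, e_over_eprime = e_over_eprime)
  bad <- !vapply(th, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))
  if (any(bad))
    stop("thresholds must be positive finite numbers: ",
         paste(names(th)[bad], collapse = ", "), call. = FALSE)
  if (lvmi_male < lvmi_female)
    stop("male LVMI threshold must be >= female threshold", call. = FALSE)
  th
}

#' The expert-authored clinical knowledge model (CKM)
#'
#' Encodes the guideline HF definition as a decision tree.  The root
#' requires symptoms or signs of HF (dyspnea, orthopnea, rales, edema):
#' without them the diagnosis is no-HF regardless of imaging, because
#' asymptomatic dysfunction is not HF under the definition.  Symptomatic
#' patients are stratified by LVEF ([classify_lvef()]): a reduced LVEF
#' alone establishes HFrEF, whereas mid-range and preserved LVEF
#' additionally require at least one supporting-evidence criterion
#' ([hf_thresholds()]) to conclude HFmrEF / HFpEF, otherwise no-HF.
#'
#' The expert model deliberately ships with no Missing-value paths: a
#' record whose tested attribute is Missing is Uncovered.  Supplying
#' those "Not Available" paths is the job of [hybridize()].
#'
#' @param thresholds Supporting-evidence configuration, see
#'   [hf_thresholds()].
#' @return An `hf_tree` with all nodes of provenance `"expert"`.
#' @export
#' @examples
#' ckm <- default_hf_ckm()
#' diagnose(ckm, list(hf_symptoms_signs = TRUE, lvef = 27.1))$outcome
default_hf_ckm <- function(thresholds = hf_thresholds()) {
  if (!is.list(thresholds) ||
      !all(c("nt_probnp", "lavi", "lvmi_male", "lvmi_female",
             "e_over_eprime") %in% names(thresholds)))
    stop("thresholds must come from hf_thresholds()", call. = FALSE)
  th <- do.call(hf_thresholds, thresholds)  # re-validate

  # evidence chain, built innermost-out; `dx` is the diagnosis concluded
  # when any criterion fires
  evidence_subtree <- function(dx) {
    ecg <- tree_node("abnormal_ecg", list(
      list(value = TRUE, node = tree_leaf(dx)),
      list(value = FALSE, node = tree_leaf("NoHF"))))
    ee <- tree_node("e_over_eprime", interval_branches(
      th$e_over_eprime, list(ecg, tree_leaf(dx))))
    lvmi_for <- function(cut) tree_node("lvmi", interval_branches(
      cut, list(ee, tree_leaf(dx))))
    sex <- tree_node("male", list(
      list(value = TRUE, node = lvmi_for(th$lvmi_male)),
      list(value = FALSE, node = lvmi_for(th$lvmi_female))))
    lavi <- tree_node("lavi", interval_branches(
      th$lavi, list(sex, tree_leaf(dx))))
    tree_node("nt_probnp", interval_branches(
      th$nt_probnp, list(lavi, tree_leaf(dx))))
  }

  lvef_node <- tree_node("lvef", interval_branches(
    c(40, 50),
    list(tree_leaf("HFrEF"),
         evidence_subtree("HFmrEF"),
         evidence_subtree("HFpEF"))))
  root <- tree_node("hf_symptoms_signs", list(
    list(value = TRUE, node = lvef_node),
    list(value = FALSE, node = tree_leaf("NoHF"))))
  decision_tree(root, tree_id = "expert-ckm")
}
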