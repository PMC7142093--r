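#' Default generative specification for a synthetic HF cohort
#'
#' The study data behind the method are not public, so the package ships
#' a seeded generative stand-in parameterized from the published
#' per-phenotype summary table: class priors from the test-set
#' composition (108 no-HF, 199 HFrEF, 63 HFmrEF, 228 HFpEF of 598),
#' per-class means and SDs for the continuous attributes, and per-class
#' prevalences for the binary ones.  Continuous attributes are sampled
#' from truncated normals (truncated to the attribute's valid range);
#' NT-proBNP, whose distribution is heavily right-skewed, uses a
#' lognormal with the printed mean and SD.  LVEF is truncated per class
#' to `[5, 40)` (HFrEF), `[40, 50)` (HFmrEF) and `[50, 85]` (HFpEF and,
#' as a modeling choice, no-HF), so generative labels are consistent
#' with the ejection-fraction phenotype definitions.  Attributes are
#' sampled independently within class (the source table gives only
#' marginals).  Missingness is 0 by default; see [inject_missingness()].
#'
#' @param n Cohort size.
#' @param seed Generation seed.
#' @param missingness Named per-attribute Missing probabilities (may be
#'   partial; unnamed scalar applies to every attribute).
#' @return A `cohort_spec` list: `n`, `seed`, `class_priors`,
#'   `continuous` (attribute -> class -> `mean`, `sd`, `lo`, `hi`,
#'   `family`), `binary` (attribute -> class -> prevalence),
#'   `missingness`.
#' @export
table1_default_spec <- function(n = 598, seed = 1L, missingness = NULL) {
  classes <- hf_labels()
  # order everywhere: HFrEF, HFmrEF, HFpEF, NoHF
  cont <- function(means, sds, lo, hi, family = "normal") {
    stats::setNames(lapply(1:4, function(i)
      list(mean = means[i], sd = sds[i], lo = lo[i], hi = hi[i],
           family = family)), classes)
  }
  sch <- default_schema()
  rng <- function(a) unlist(sch[sch$name == a, c("lo", "hi")], use.names = FALSE)
  r4 <- function(a) list(rep(rng(a)[1], 4), rep(rng(a)[2], 4))
  continuous <- list(
    age = cont(c(70.3, 74.7, 75.2, 64.8), c(14.6, 14.1, 10.6, 13.8),
               r4("age")[[1]], r4("age")[[2]]),
    nt_probnp = cont(c(15665, 8634, 5595, 82.4),
                     c(12604, 9666, 9306, 68.0),
                     r4("nt_probnp")[[1]], r4("nt_probnp")[[2]],
                     family = "lognormal"),
    lvef = cont(c(27.1, 45.3, 61.6, 64.1), c(7.5, 2.6, 6.5, 6.5),
                lo = c(5, 40, 50, 50), hi = c(40, 50, 85, 85)),
    lavi = cont(c(60.5, 52.6, 48.0, 31.2), c(18.6, 27.5, 19.4, 8.5),
                r4("lavi")[[1]], r4("lavi")[[2]]),
    lvmi = cont(c(151.0, 129.0, 106.0, 83.4), c(41.5, 50.7, 33.9, 18.3),
                r4("lvmi")[[1]], r4("lvmi")[[2]]),
    e_over_eprime = cont(c(22.9, 17.4, 15.6, 9.8), c(10.34, 8.6, 8.3, 3.5),
                         r4("e_over_eprime")[[1]], r4("e_over_eprime")[[2]]),
    septal_eprime = cont(c(4.2, 5.1, 5.6, 6.9), c(1.7, 2.3, 2.2, 2.4),
                         r4("septal_eprime")[[1]], r4("septal_eprime")[[2]]),
    trv = cont(c(3.0, 2.8, 2.8, 2.6), c(0.7, 0.5, 0.7, 1.5),
               r4("trv")[[1]], r4("trv")[[2]]),
    gls = cont(c(7.1, 10.4, 14.6, 16.4), c(2.7, 2.8, 4.3, 3.9),
               r4("gls")[[1]], r4("gls")[[2]]))
  bin <- function(p) stats::setNames(as.list(p / 100), classes)
  binary <- list(
    male = bin(c(54.3, 52.4, 50.0, 37)),
    hf_symptoms_signs = bin(c(94.0, 84.1, 87.7, 81.5)),
    clinical_history = bin(c(66.3, 55.6, 37.7, 14.8)),
    physical_exam = bin(c(60.8, 49.2, 43.9, 9.3)),
    abnormal_ecg = bin(c(99.5, 96.8, 86.2, 46.0)))
  miss <- stats::setNames(rep(0, nrow(sch)), sch$name)
  if (!is.null(missingness)) {
    if (is.null(names(missingness)) && length(missingness) == 1) {
      miss[] <- missingness
    } else {
      unknown <- setdiff(names(missingness), sch$name)
      if (length(unknown))
        stop("missingness names unknown attribute(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      miss[names(missingness)] <- missingness
    }
  }
  spec <- list(
    n = as.integer(n), seed = as.integer(seed),
    class_priors = stats::setNames(c(199, 63, 228, 108) / 598, classes),
    continuous = continuous, binary = binary, missingness = miss)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec, schema = default_schema()) {
  stopifnot(is.list(spec), spec$n >= 0)
  if (abs(sum(spec$class_priors) - 1) > 1e-8)
    stop("class priors must sum to 1", call. = FALSE)
  if (any(spec$class_priors < 0))
    stop("class priors must be non-negative", call. = FALSE)
  for (a in names(spec$continuous)) {
    k <- match(a, schema$name)
    if (is.na(k) || schema$kind[k] != "continuous")
      stop("spec names non-continuous attribute '", a, "'", call. = FALSE)
    for (cls in names(spec$continuous[[a]])) {
      p <- spec$continuous[[a]][[cls]]
      if (!is.finite(p$sd) || p$sd <= 0)
        stop(sprintf("'%s' (%s): sd must be positive", a, cls),
             call. = FALSE)
      if (p$lo >= p$hi)
        stop(sprintf("'%s' (%s): empty truncation interval", a, cls),
             call. = FALSE)
      if (p$lo < schema$lo[k] || p$hi > schema$hi[k])
        stop(sprintf("'%s' (%s): truncation outside valid range", a, cls),
             call. = FALSE)
      if (!p$family %in% c("normal", "lognormal"))
        stop(sprintf("'%s' (%s): unknown family '%s'", a, cls, p$family),
             call. = FALSE)
    }
  }
  for (a in names(spec$binary)) {
    k <- match(a, schema$name)
    if (is.na(k) || schema$kind[k] != "binary")
      stop("spec names non-binary attribute '", a, "'", call. = FALSE)
    pv <- unlist(spec$binary[[a]])
    if (any(pv < 0 | pv > 1))
      stop(sprintf("'%s': prevalence outside [0, 1]", a), call. = FALSE)
  }
  if (any(spec$missingness < 0 | spec$missingness > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  invisible(spec)
}

# Lognormal (mu, sigma) matched to an arithmetic mean and SD
lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# Inverse-CDF sampling from a truncated normal / mean-SD-matched lognormal
sample_truncated <- function(n, p) {
  if (n == 0) return(numeric(0))
  if (p$family == "lognormal") {
    lp <- lognormal_pars(p$mean, p$sd)
    a <- stats::plnorm(p$lo, lp$mu, lp$sigma)
    b <- stats::plnorm(p$hi, lp$mu, lp$sigma)
    stats::qlnorm(stats::runif(n, a, b), lp$mu, lp$sigma)
  } else {
    a <- stats::pnorm(p$lo, p$mean, p$sd)
    b <- stats::pnorm(p$hi, p$mean, p$sd)
    stats::qnorm(stats::runif(n, a, b), p$mean, p$sd)
  }
}

#' Generate a synthetic patient cohort
#'
#' Draws each record's diagnosis class from the spec's priors, then its
#' attribute values from the class's distributions, then injects
#' Missing values at the spec's per-attribute rates.  Fully reproducible:
#' the same spec (including seed) yields the identical cohort,
#' byte-for-byte after CSV serialization.
#'
#' @param spec A `cohort_spec`, see [table1_default_spec()].
#' @param schema Attribute schema.
#' @return Validated cohort data frame with `patient_id`, the 14
#'   attributes and `gold_diagnosis` set to the generative class.
#' @export
#' @examples
#' cohort <- generate_cohort(table1_default_spec(n = 50, seed = 7))
#' table(cohort$gold_diagnosis)
generate_cohort <- function(spec, schema = default_schema()) {
  validate_cohort_spec(spec, schema)
  n <- spec$n
  withr::with_seed(spec$seed, {
    cls <- sample(names(spec$class_priors), n, replace = TRUE,
                  prob = spec$class_priors)
    cohort <- data.frame(patient_id = sprintf("p%04d", seq_len(n)),
                         stringsAsFactors = FALSE)
    for (a in schema$name) {   # fixed order => reproducibility
      if (a %in% names(spec$continuous)) {
        v <- numeric(n)
        for (g in names(spec$continuous[[a]])) {
          idx <- which(cls == g)
          v[idx] <- sample_truncated(length(idx), spec$continuous[[a]][[g]])
        }
        cohort[[a]] <- v
      } else if (a %in% names(spec$binary)) {
        v <- logical(n)
        for (g in names(spec$binary[[a]])) {
          idx <- which(cls == g)
          v[idx] <- stats::runif(length(idx)) < spec$binary[[a]][[g]]
        }
        cohort[[a]] <- v
      } else {
        stop("spec covers no distribution for attribute '", a, "'",
             call. = FALSE)
      }
    }
    cohort$gold_diagnosis <- cls
    if (any(spec$missingness > 0))
      cohort <- inject_missingness(cohort, spec$missingness,
                                   seed = NULL, schema = schema)
  })
  validate_cohort(cohort, schema)
}

#' Replace present values by Missing at given rates
#'
#' Each present value is independently replaced by Missing (`NA`) with
#' its attribute's rate (missing completely at random); already-Missing
#' values stay Missing.  `gold_diagnosis` is never masked.
#'
#' @param cohort Cohort data frame.
#' @param rates Named per-attribute rates in `[0, 1]` (unnamed scalar:
#'   every attribute).
#' @param seed Seed; `NULL` continues the caller's RNG stream (used
#'   internally by [generate_cohort()]).
#' @param schema Attribute schema.
#' @return The cohort with Missing values injected.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L,
                               schema = default_schema()) {
  if (is.null(names(rates))) {
    if (length(rates) != 1)
      stop("unnamed rates must be a single scalar", call. = FALSE)
    rates <- stats::setNames(rep(rates, nrow(schema)), schema$name)
  }
  unknown <- setdiff(names(rates), schema$name)
  if (length(unknown))
    stop("rates name unknown attribute(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  inject <- function() {
    for (a in names(rates)) {
      if (rates[[a]] <= 0) next
      hit <- stats::runif(nrow(cohort)) < rates[[a]]
      cohort[[a]][hit] <- NA
    }
    cohort
  }
  if (is.null(seed)) inject() else withr::with_seed(seed, inject())
}

#' Composition of the reference validation cohorts
#'
#' The per-phenotype record counts of the retrospective test cohort
#' (n = 598) that parameterize the default generator's class priors,
#' and the HF count of the prospective dyspnea cohort (43 of 97).
#' Useful for recomputing the published composition arithmetic, e.g.
#' the HF-subtype proportions among the 490 HF test patients.
#'
#' @return List with `test` (named counts per diagnosis label),
#'   `prospective_hf` and `prospective_n`.
#' @export
#' @examples
#' comp <- cohort_composition()
#' round(100 * comp$test[c("HFrEF", "HFmrEF", "HFpEF")] /
#'       sum(comp$test[c("HFrEF", "HFmrEF", "HFpEF")]), 1)
cohort_composition <- function() {
  list(test = c(HFrEF = 199L, HFmrEF = 63L, HFpEF = 228L, NoHF = 108L),
       prospective_hf = 43L, prospective_n = 97L)
}
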