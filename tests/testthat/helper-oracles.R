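# Independent oracles, deliberately written as plain enumeration /
# closed forms so they share no code with the implementation.

# Gini impurity by direct proportion arithmetic
oracle_gini <- function(labels) {
  props <- as.numeric(table(labels)) / length(labels)
  1 - sum(props^2)
}

# Exhaustive enumeration of every (attribute, threshold) candidate with
# majority-side Missing routing; returns the best decrease and the
# set of (attribute, threshold) achieving it.
oracle_best_split <- function(cohort, labels, attributes,
                              min_samples_leaf = 1) {
  n <- length(labels)
  parent <- oracle_gini(labels)
  best <- NULL
  for (a in attributes) {
    v <- cohort[[a]]
    miss <- is.na(v)
    if (is.logical(v)) {
      cand_assign <- list(list(thr = NA, left = !miss & !v,
                               right = !miss & v))
    } else {
      sv <- sort(unique(v[!miss]))
      if (length(sv) < 2) next
      thr <- (sv[-length(sv)] + sv[-1]) / 2
      cand_assign <- lapply(thr, function(t)
        list(thr = t, left = !miss & v < t, right = !miss & v >= t))
    }
    for (cand in cand_assign) {
      nl <- sum(cand$left); nr <- sum(cand$right)
      if (nl == 0 || nr == 0) next
      if (nl >= nr) left <- cand$left | miss else left <- cand$left
      right <- !left
      if (sum(left) < min_samples_leaf || sum(right) < min_samples_leaf)
        next
      dec <- parent - (sum(left) * oracle_gini(labels[left]) +
                       sum(right) * oracle_gini(labels[right])) / n
      if (dec <= 1e-12) next
      row <- data.frame(attribute = a, threshold = cand$thr,
                        decrease = dec, stringsAsFactors = FALSE)
      best <- if (is.null(best)) row else rbind(best, row)
    }
  }
  if (is.null(best)) return(NULL)
  best[best$decrease >= max(best$decrease) - 1e-9, , drop = FALSE]
}

# Moments of a normal(mean, sd) truncated to [a, b]
oracle_truncnorm_mean <- function(mean, sd, a, b) {
  al <- (a - mean) / sd; be <- (b - mean) / sd
  Z <- pnorm(be) - pnorm(al)
  mean + sd * (dnorm(al) - dnorm(be)) / Z
}
oracle_truncnorm_sd <- function(mean, sd, a, b) {
  al <- (a - mean) / sd; be <- (b - mean) / sd
  Z <- pnorm(be) - pnorm(al)
  t1 <- (al * dnorm(al) - be * dnorm(be)) / Z
  t2 <- ((dnorm(al) - dnorm(be)) / Z)^2
  sd * sqrt(1 + t1 - t2)
}

# Moments of a lognormal matched to arithmetic mean/sd, truncated to [a, b]
oracle_trunclnorm_moments <- function(mean, sd, a, b) {
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  s <- sqrt(s2)
  Z <- plnorm(b, mu, s) - plnorm(a, mu, s)
  la <- if (a <= 0) -Inf else (log(a) - mu) / s
  lb <- (log(b) - mu) / s
  m1 <- exp(mu + s2 / 2) * (pnorm(lb - s) - pnorm(la - s)) / Z
  m2 <- exp(2 * mu + 2 * s2) * (pnorm(lb - 2 * s) - pnorm(la - 2 * s)) / Z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# Expectation of a spec entry (dispatch on family)
oracle_spec_moments <- function(p) {
  if (p$family == "lognormal")
    oracle_trunclnorm_moments(p$mean, p$sd, p$lo, p$hi)
  else
    list(mean = oracle_truncnorm_mean(p$mean, p$sd, p$lo, p$hi),
         sd = oracle_truncnorm_sd(p$mean, p$sd, p$lo, p$hi))
}
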