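#' Normalize a qMSP signal to control DNA
#'
#' `percent = 100 * raw / control`, capped at 100 (with a warning) since the
#' fully methylated commercial control defines the upper bound.
#'
#' @param raw_level raw methylation-specific signal(s).
#' @param control_level region-matched signal of the control DNA (> 0).
#' @return methylation percent in \[0, 100\].
#' @export
normalize_qmsp <- function(raw_level, control_level) {
  if (any(control_level <= 0)) stop("control_level must be positive")
  pct <- 100 * raw_level / control_level
  if (any(pct > 100)) {
    warning("normalized methylation above 100% capped")
    pct <- pmin(pct, 100)
  }
  pct
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' U counts the pairs in which a first-group value exceeds a second-group
#' value (ties count 1/2). For combined n <= 20 without ties the two-sided
#' p-value is exact by full enumeration of all group assignments
#' (`P(|U - n1 n2 / 2| >= |u - n1 n2 / 2|)` under the permutation null);
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param values numeric vector.
#' @param labels two-level grouping (factor/character/logical) along
#'   `values`; both groups must be non-empty.
#' @return list `U`, `p_value`, `n`, `method`.
#' @export
compare_groups <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must define exactly two non-empty groups")
  g1 <- values[labels == levels(labels)[1L]]
  g2 <- values[labels == levels(labels)[2L]]
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  u_stat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u <- u_stat(g1, g2)
  has_ties <- anyDuplicated(c(g1, g2)) > 0
  centre <- n1 * n2 / 2
  if (n <= 20L && !has_ties) {
    pool <- c(g1, g2)
    sel <- utils::combn(n, n1)
    u_perm <- apply(sel, 2L, function(i) u_stat(pool[i], pool[-i]))
    p <- mean(abs(u_perm - centre) >= abs(u - centre) - 1e-9)
    method <- "exact enumeration"
  } else if (n <= 20L && has_ties &&
             length(unique(c(g1, g2))) == 1L) {
    p <- 1
    method <- "degenerate (all values tied)"
  } else {
    r <- rank(c(g1, g2))
    ties <- table(c(g1, g2))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - centre) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal approximation"
  }
  list(U = u, p_value = min(p, 1), n = c(n1, n2), method = method)
}

#' Confusion-matrix metrics
#'
#' Positives are non-responders (relapse); a positive test call is
#' methylation at or above the threshold. Stored metrics are exact;
#' `percent` gives the integer-rounded display values.
#'
#' @param tp,fn,tn,fp non-negative counts with `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return list `sensitivity`, `specificity`, `accuracy`, `percent`
#'   (named integer vector).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop("both classes must be represented (empty margin)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / sum(counts)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       percent = c(sensitivity = round(100 * sens),
                   specificity = round(100 * spec),
                   accuracy = round(100 * acc)))
}

#' Maximum-accuracy threshold classifier
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values plus one candidate below the minimum (classifying everyone
#' test-positive). The candidate maximizing accuracy is returned; ties are
#' broken towards the smallest threshold.
#'
#' @param values methylation percent per patient.
#' @param labels positives = non-responders: logical
#'   (`TRUE` = non-responder) or factor/character where the label
#'   `"non_responder"` (or `FALSE` on `responder` semantics) marks
#'   positives — pass a logical to avoid ambiguity.
#' @return list of class `classifier_eval`: `threshold`, `tp`, `fn`, `tn`,
#'   `fp`, `sensitivity`, `specificity`, `accuracy`.
#' @export
select_threshold <- function(values, labels) {
  pos <- as.logical(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  sv <- sort(unique(values))
  cand <- c(sv[1L] - 1, if (length(sv) > 1L) (sv[-1L] + sv[-length(sv)]) / 2)
  best <- NULL
  for (thr in cand) {
    call_pos <- values >= thr
    tp <- sum(call_pos & pos); fn <- sum(!call_pos & pos)
    tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
    acc <- (tp + tn) / length(values)
    if (is.null(best) || acc > best$accuracy + 1e-12) {
      m <- confusion_metrics(tp, fn, tn, fp)
      best <- list(threshold = thr, tp = tp, fn = fn, tn = tn, fp = fp,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   accuracy = acc)
    }
  }
  class(best) <- "classifier_eval"
  best
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects leave the risk set after their time; at tied times
#' events are handled before censorings (both are in the risk set at that
#' time). The curve is right-continuous and starts at 1.
#'
#' @param times positive follow-up times.
#' @param events logical event indicators (`FALSE` = censored).
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (a time-0 row with survival 1 is included).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  events <- as.logical(events)
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & !events), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = c(0, ut), n_risk = c(length(times), n_risk),
                    n_event = c(0, n_event), n_censor = c(0, n_censor),
                    survival = c(1, surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve` from [km_estimate].
#' @param t times at which to read the (right-continuous) survival.
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  curve$survival[pmax(idx, 1L)]
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' accumulated over distinct event times, referred to chi-square with 1 df.
#' Exchanging the group labels leaves the statistic unchanged.
#'
#' @param time_a,event_a,time_b,event_b follow-up times and logical event
#'   indicators of the two groups (at least one event overall).
#' @return list `chi_square`, `df`, `p_value`, `observed` (per group),
#'   `expected` (per group), `n` (group sizes).
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) stop("no events in either group")
  ut <- sort(unique(c(time_a[event_a], time_b[event_b])))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t); nt <- n1 + n2
    d1 <- sum(time_a == t & event_a); d2 <- sum(time_b == t & event_b)
    dt <- d1 + d2
    if (nt == 0 || dt == 0) next
    o1 <- o1 + d1
    e1 <- e1 + dt * n1 / nt
    if (nt > 1) v <- v + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chi_square = chi, df = 1L,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = c(o1, sum(event_a) + sum(event_b) - o1),
       expected = c(e1, sum(event_a) + sum(event_b) - e1),
       n = c(length(time_a), length(time_b)))
}
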