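#' Classify an antibiotic day as control or impact for a scenario
#'
#' Every day the patient receives treatment is a stop-impact and
#' continue-control day; the cessation day (the first antibiotic-free day,
#' for stays that stop in-ICU) is a stop-control and continue-impact day.
#' Stays discharged on antibiotics have no stop-control / continue-impact
#' day. Non-antibiotic days are `not_applicable`.
#'
#' @param course a `stay_timeline`, or a list with `treatment_length` and
#'   `stop_day` (NA if never stopping in-ICU).
#' @param day day index.
#' @param scenario `"stop"` or `"continue"`.
#' @return `"control"`, `"impact"` or `"not_applicable"`.
#' @export
classify_day <- function(course, day, scenario = c("stop", "continue")) {
  scenario <- match.arg(scenario)
  if (inherits(course, "stay_timeline")) {
    trt <- sum(course$abx_status)
    stopd <- course$course$stop_day
  } else {
    trt <- course$treatment_length
    stopd <- course$stop_day
  }
  is_treat <- day >= 1 && day <= trt
  is_cess <- !is.na(stopd) && day == stopd
  if (is_treat) {
    if (scenario == "stop") "impact" else "control"
  } else if (is_cess) {
    if (scenario == "stop") "control" else "impact"
  } else {
    "not_applicable"
  }
}

# role column for an estimate table: scenario x day-status truth table
add_day_roles <- function(est) {
  est <- data.table::as.data.table(est)
  est[, role := data.table::fifelse(
    scenario == "stop",
    data.table::fifelse(status == "treat", "impact", "control"),
    data.table::fifelse(status == "treat", "control", "impact"))]
  est[]
}

#' Mean delta between labels and estimates (stay-first averaging)
#'
#' \deqn{\mu_\Delta = \frac{1}{n}\sum_i \frac{1}{T_i}\sum_t
#'   \left[Y_i^t - \tilde Y_i^t\right]}
#' where `T_i` counts the qualifying days of stay `i`. Positive values mean
#' the true label exceeds the estimate.
#'
#' @param y true labels per qualifying day.
#' @param yhat estimates, aligned with `y`.
#' @param stay_id stay of each day.
#' @return list: `mu_delta`, `per_stay` (named per-stay day-means), `n_stays`,
#'   `n_days`. `mu_delta` is `NA` (flagged) when no qualifying days exist.
#' @export
mean_delta <- function(y, yhat, stay_id) {
  keep <- !is.na(yhat) & !is.na(y)
  y <- y[keep]; yhat <- yhat[keep]; stay_id <- stay_id[keep]
  if (length(y) == 0L) {
    return(list(mu_delta = NA_real_, per_stay = numeric(0), n_stays = 0L,
                n_days = 0L))
  }
  per_stay <- tapply(y - yhat, stay_id, mean)
  list(mu_delta = mean(per_stay), per_stay = per_stay,
       n_stays = length(per_stay), n_days = length(y))
}

#' Estimation error metrics (MAPE, MAE, RMSE)
#'
#' MAPE and MAE use the stay-first nesting (per-stay day-mean, then mean over
#' stays); RMSE is pooled over all qualifying days (a global average). Days
#' with `y == 0` are excluded from MAPE, with the count reported.
#'
#' @inheritParams mean_delta
#' @return list `mape, mae, rmse, n_mape_excluded`.
#' @export
error_metrics <- function(y, yhat, stay_id) {
  keep <- !is.na(yhat) & !is.na(y)
  y <- y[keep]; yhat <- yhat[keep]; stay_id <- stay_id[keep]
  if (length(y) == 0L) {
    return(list(mape = NA_real_, mae = NA_real_, rmse = NA_real_,
                n_mape_excluded = 0L))
  }
  abs_err <- abs(y - yhat)
  mae <- mean(tapply(abs_err, stay_id, mean))
  rmse <- sqrt(mean((y - yhat)^2))
  nz <- y != 0
  mape <- if (any(nz)) {
    mean(tapply(abs_err[nz] / abs(y[nz]), stay_id[nz], mean))
  } else NA_real_
  list(mape = mape, mae = mae, rmse = rmse, n_mape_excluded = sum(!nz))
}

#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' @param x,y the two samples (e.g. true labels vs estimates on the
#'   qualifying days).
#' @param alpha significance level (default 0.05).
#' @return list `p_value`, `significant`; `p_value` is `NA` (flagged) when a
#'   sample is empty.
#' @export
rank_sum_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    return(list(p_value = NA_real_, significant = NA))
  }
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  list(p_value = p, significant = is.finite(p) && p < alpha)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation; ties contribute 1/2.
#'
#' @param labels binary 0/1 labels.
#' @param scores predicted scores/probabilities.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(labels, scores) {
  labels <- as.numeric(labels)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' @inheritParams auroc
#' @return AUPRC, or `NA` if no positives.
#' @export
auprc <- function(labels, scores) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / n1
  # average precision: sum of precision at each positive, weighted by
  # recall increments
  sum(prec[lab == 1]) / n1
}

#' Mortality classification metrics with bootstrap confidence intervals
#'
#' Computes AUROC, AUPRC, accuracy, precision, recall, specificity and F1
#' (probability threshold `threshold`), with percentile 95% confidence
#' intervals from `n_boot` bootstrap resamples of size `boot_n`.
#'
#' @param labels binary labels.
#' @param probs estimated probabilities in `[0, 1]`.
#' @param n_boot number of bootstrap resamples (default 1000; 0 disables).
#' @param boot_n resample size (default `min(length(labels), 1000)`).
#' @param seed bootstrap RNG seed.
#' @param threshold probability cutoff for the thresholded metrics.
#' @return a `data.frame` with columns `metric, value, ci_lo, ci_hi`.
#' @export
classification_report <- function(labels, probs, n_boot = 1000L,
                                  boot_n = NULL, seed = 1L,
                                  threshold = 0.5) {
  stopifnot(length(labels) == length(probs))
  labels <- as.numeric(labels)
  keep <- !is.na(probs) & !is.na(labels)
  labels <- labels[keep]; probs <- probs[keep]
  if (is.null(boot_n)) boot_n <- min(length(labels), 1000L)
  one <- function(lab, p) {
    pred <- as.numeric(p >= threshold)
    tp <- sum(pred == 1 & lab == 1); fp <- sum(pred == 1 & lab == 0)
    tn <- sum(pred == 0 & lab == 0); fn <- sum(pred == 0 & lab == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    c(auroc = auroc(lab, p), auprc = auprc(lab, p),
      accuracy = mean(pred == lab), precision = prec, recall = rec,
      specificity = spec, f1 = f1)
  }
  point <- one(labels, probs)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(labels), boot_n, replace = TRUE)
        one(labels[idx], probs[idx])
      }, numeric(7))
    })
    ci <- apply(boots, 1L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  } else {
    ci <- matrix(NA_real_, 2L, length(point))
  }
  data.frame(metric = names(point), value = unname(point),
             ci_lo = ci[1L, ], ci_hi = ci[2L, ], row.names = NULL)
}

#' Evaluate an estimate table with the control/impact framework
#'
#' Joins each estimate to its day role (control or impact per scenario),
#' then computes, per scenario x role: the stay-first mean delta, the
#' Mann-Whitney rank-sum p-value between pooled labels and estimates, MAPE,
#' MAE and pooled RMSE for LOS; for mortality, mean delta, MAE, AUROC (and
#' the full classification family with bootstrap CIs when `n_boot > 0`).
#' Flagged no-estimates (empty donor pools) are excluded, with counts
#' reported.
#'
#' @param estimates output of [estimate_all()] (one outcome type).
#' @param alpha rank-sum significance level.
#' @param n_boot bootstrap resamples for mortality CIs (0 disables).
#' @param seed bootstrap seed.
#' @return an `abx_eval_report`: `table` (one row per scenario x role),
#'   `outcome_type`, `n_no_estimate`.
#' @export
evaluate_estimates <- function(estimates, alpha = 0.05, n_boot = 0L,
                               seed = 1L) {
  est <- add_day_roles(estimates)
  outcome <- est$outcome_type[1L]
  n_missing <- sum(is.na(est$estimate))
  est <- est[!is.na(estimate)]
  rows <- list()
  for (sc in c("stop", "continue")) {
    for (ro in c("impact", "control")) {
      e <- est[scenario == sc & role == ro]
      if (nrow(e) == 0L) {
        rows[[paste(sc, ro)]] <- data.table::data.table(
          scenario = sc, role = ro, n_stays = 0L, n_days = 0L,
          mean_delta = NA_real_, p_value = NA_real_, significant = NA)
        next
      }
      md <- mean_delta(e$label, e$estimate, e$stay_id)
      rs <- rank_sum_test(e$label, e$estimate, alpha)
      base <- data.table::data.table(
        scenario = sc, role = ro, n_stays = md$n_stays, n_days = md$n_days,
        mean_delta = md$mu_delta, p_value = rs$p_value,
        significant = rs$significant)
      if (outcome == "los") {
        em <- error_metrics(e$label, e$estimate, e$stay_id)
        base[, `:=`(mape = em$mape, mae = em$mae, rmse = em$rmse)]
      } else {
        em <- error_metrics(e$label, e$estimate, e$stay_id)
        base[, `:=`(mae = em$mae,
                    auroc = auroc(e$label, e$estimate))]
        if (n_boot > 0) {
          cr <- classification_report(e$label, e$estimate, n_boot = n_boot,
                                      seed = seed)
          base[, `:=`(auroc_lo = cr$ci_lo[cr$metric == "auroc"],
                      auroc_hi = cr$ci_hi[cr$metric == "auroc"])]
        }
      }
      rows[[paste(sc, ro)]] <- base
    }
  }
  out <- list(table = data.table::rbindlist(rows, fill = TRUE),
              outcome_type = outcome, n_no_estimate = n_missing,
              alpha = alpha)
  class(out) <- "abx_eval_report"
  out
}

#' @export
print.abx_eval_report <- function(x, ...) {
  cat("<abx_eval_report> outcome:", x$outcome_type,
      "| flagged no-estimates:", x$n_no_estimate, "\n")
  print(x$table)
  invisible(x)
}

#' What-if analysis: stopping after a fixed treatment duration
#'
#' Selects stays whose realised treatment length exceeds `day_cutoff`
#' (or equals it, with `longer_than = FALSE`, for shorter-course queries on
#' standard-of-care patients) and compares their realised outcome — the
#' factual continuation — with the stop-scenario estimate at `query_day`,
#' the first hypothetical antibiotic-free day (default `day_cutoff + 1`).
#'
#' @param estimates output of [estimate_all()] (stop estimates are used);
#'   must contain `treatment_length` (it does when produced by this package).
#' @param day_cutoff treatment-duration cutoff in days.
#' @param query_day the hypothetical cessation day whose stop estimate is
#'   compared (default `day_cutoff + 1`).
#' @param longer_than select treatment length `> day_cutoff` (default) or
#'   `== day_cutoff`.
#' @param alpha rank-sum significance level.
#' @return list: `n_stays`, `mean_delta` (realised minus estimated,
#'   positive = stopping earlier estimated to shorten the outcome), `rmse`,
#'   `p_value`, `significant`, `per_stay` table; `empty = TRUE` when no stay
#'   qualifies.
#' @export
whatif_stop_after <- function(estimates, day_cutoff, query_day = NULL,
                              longer_than = TRUE, alpha = 0.05) {
  stopifnot(day_cutoff >= 1)
  if (is.null(query_day)) query_day <- day_cutoff + 1L
  est <- data.table::as.data.table(estimates)
  if (!"treatment_length" %in% names(est)) {
    stop("estimates must carry a treatment_length column")
  }
  sel <- if (longer_than) est$treatment_length > day_cutoff
         else est$treatment_length == day_cutoff
  e <- est[sel & scenario == "stop" & day == query_day & !is.na(estimate)]
  if (nrow(e) == 0L) {
    return(list(n_stays = 0L, mean_delta = NA_real_, rmse = NA_real_,
                p_value = NA_real_, significant = NA, empty = TRUE,
                per_stay = e))
  }
  md <- mean_delta(e$label, e$estimate, e$stay_id)
  rs <- rank_sum_test(e$label, e$estimate, alpha)
  list(n_stays = md$n_stays, mean_delta = md$mu_delta,
       rmse = sqrt(mean((e$label - e$estimate)^2)),
       p_value = rs$p_value, significant = rs$significant, empty = FALSE,
       per_stay = e[, .(stay_id, day, label, estimate,
                        delta = label - estimate)])
}
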