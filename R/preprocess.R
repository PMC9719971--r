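#' Aggregate long-format events into per-stay daily feature matrices
#'
#' Collapses multiple same-day observations of a variable to their mean (or
#' median) and marks absent (stay, day, variable) cells as missing. The day
#' grid of each stay is taken from `day_grid` (typically the antibiotic
#' administration table, which covers every ICU day) when supplied, otherwise
#' from the days present in the events.
#'
#' @param events `data.frame` with columns `stay_id, day, variable, value`.
#' @param day_grid optional `data.frame` with columns `stay_id, day` defining
#'   the full day grid of each stay.
#' @param collapse how same-day duplicates collapse: `"mean"` (default) or
#'   `"median"`.
#' @param feature_names optional character vector fixing the feature order;
#'   defaults to the sorted set of observed variables.
#' @return named list (by stay) of lists with `features` (T x D matrix, NA
#'   where missing), `missing_mask` (T x D, 1 = missing) and `days`.
#' @export
aggregate_daily <- function(events, day_grid = NULL,
                            collapse = c("mean", "median"),
                            feature_names = NULL) {
  collapse <- match.arg(collapse)
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L && is.null(day_grid)) return(structure(list(), names = character()))
  req <- c("stay_id", "day", "variable", "value")
  if (!all(req %in% names(ev)) && nrow(ev) > 0L) {
    stop("events must have columns stay_id, day, variable, value")
  }
  if (nrow(ev) > 0L && !is.numeric(ev$value)) {
    suppressWarnings(num <- as.numeric(ev$value))
    bad <- which(is.na(num) & !is.na(ev$value))
    if (length(bad)) {
      b <- ev[bad[1L]]
      stop("non-numeric value for variable '", b$variable, "' at (",
           b$stay_id, ", day ", b$day, ")", call. = FALSE)
    }
    ev[, value := num]
  }
  fun <- if (collapse == "mean") mean else median
  agg <- if (nrow(ev)) {
    ev[, .(value = fun(value)), by = .(stay_id, day, variable)]
  } else ev
  if (is.null(feature_names)) {
    feature_names <- sort(unique(agg$variable))
  }
  grid <- if (is.null(day_grid)) {
    agg[, .(T_i = max(day)), by = stay_id]
  } else {
    dg <- data.table::as.data.table(day_grid)
    dg[, .(T_i = max(day)), by = stay_id]
  }
  data.table::setorder(grid, stay_id)
  out <- vector("list", nrow(grid))
  names(out) <- grid$stay_id
  D <- length(feature_names)
  fidx <- setNames(seq_len(D), feature_names)
  agg_by_stay <- if (nrow(agg)) split(agg, by = "stay_id", keep.by = FALSE) else list()
  for (i in seq_len(nrow(grid))) {
    sid <- grid$stay_id[i]
    T_i <- grid$T_i[i]
    X <- matrix(NA_real_, T_i, D, dimnames = list(NULL, feature_names))
    a <- agg_by_stay[[sid]]
    if (!is.null(a)) {
      a <- a[day >= 1L & day <= T_i & variable %in% feature_names]
      X[cbind(a$day, fidx[a$variable])] <- a$value
    }
    out[[i]] <- list(features = X,
                     missing_mask = matrix(as.numeric(is.na(X)), T_i, D,
                                           dimnames = list(NULL, feature_names)),
                     days = seq_len(T_i))
  }
  out
}

#' Derive the treatment course from daily antibiotic flags
#'
#' Computes the per-day cumulative consecutive-treatment length, the initial
#' course, the stop day (first antibiotic-free day after treatment) and the
#' re-treatment indicator.
#'
#' @param abx_flags binary vector over days `1..T`.
#' @return list with `cum_treatment_len` (length T),
#'   `first_abx_day`, `initial_course_length`, `stop_day` (NA if the patient
#'   never stops in-ICU or was never treated), and `retreatment`.
#' @examples
#' compute_treatment_course(c(1, 1, 1, 0))  # cum 1,2,3,0; stop day 4
#' compute_treatment_course(c(1, 1, 0, 1))  # re-treatment
#' @export
compute_treatment_course <- function(abx_flags) {
  f <- as.integer(abx_flags)
  stopifnot(all(f %in% c(0L, 1L)))
  T_i <- length(f)
  cum <- integer(T_i)
  run <- 0L
  for (t in seq_len(T_i)) {
    run <- if (f[t] == 1L) run + 1L else 0L
    cum[t] <- run
  }
  first <- if (any(f == 1L)) which(f == 1L)[1L] else NA_integer_
  initial <- if (is.na(first)) 0L else {
    len <- 0L
    for (t in first:T_i) {
      if (f[t] == 1L) len <- len + 1L else break
    }
    len
  }
  stop_day <- NA_integer_
  if (!is.na(first)) {
    after <- which(f == 0L & seq_len(T_i) > first)
    if (length(after)) stop_day <- after[1L]
  }
  # re-treatment: a 1-run starting after a 0-day that follows a 1-day
  retreat <- FALSE
  if (!is.na(stop_day) && stop_day < T_i) {
    retreat <- any(f[(stop_day + 1L):T_i] == 1L)
  }
  list(cum_treatment_len = cum, first_abx_day = first,
       initial_course_length = initial, stop_day = stop_day,
       retreatment = retreat)
}

#' Assemble per-stay timelines from simulator-style tables
#'
#' Joins aggregated daily features, antibiotic flags and outcome labels into
#' one timeline object per stay (raw, un-normalised values).
#'
#' @param events,abx,labels tables in the schemas written by
#'   [simulate_cohort()].
#' @param feature_names optional fixed feature order.
#' @inheritParams aggregate_daily
#' @return named list of `stay_timeline` lists.
#' @export
build_timelines <- function(events, abx, labels, feature_names = NULL,
                            collapse = "mean") {
  abx <- data.table::as.data.table(abx)
  labels <- data.table::as.data.table(labels)
  daily <- aggregate_daily(events, day_grid = abx[, .(stay_id, day)],
                           collapse = collapse, feature_names = feature_names)
  data.table::setkey(labels, stay_id)
  abx_split <- split(abx, by = "stay_id", keep.by = FALSE)
  out <- vector("list", length(daily))
  names(out) <- names(daily)
  for (sid in names(daily)) {
    d <- daily[[sid]]
    a <- abx_split[[sid]]
    data.table::setorder(a, day)
    flags <- a$on_antibiotics
    stopifnot(length(flags) == length(d$days))
    course <- compute_treatment_course(flags)
    lab <- labels[sid]
    age <- if ("age" %in% colnames(d$features)) d$features[1L, "age"] else NA_real_
    tl <- list(stay_id = sid, days = d$days, features = d$features,
               missing_mask = d$missing_mask, abx_status = as.integer(flags),
               cum_treatment_len = course$cum_treatment_len,
               course = course, retreatment = course$retreatment,
               age_at_admission = age,
               los_label = lab$los_days, mortality_label = lab$mortality)
    class(tl) <- "stay_timeline"
    out[[sid]] <- tl
  }
  out
}

#' Apply the cohort inclusion filters
#'
#' Retains stays whose initial antibiotic course length lies in
#' `[min_course, max_course]` days and whose per-day fraction of missing
#' feature values never exceeds `max_missing_frac` (with `missing_rule =
#' "any"`, the default strict reading, a single violating day drops the
#' stay; `"all"` requires every day to violate). A stay failing both rules
#' counts once, under the course-length rule.
#'
#' @param timelines named list of timelines from [build_timelines()].
#' @param min_course,max_course inclusive course-length bounds in days.
#' @param max_missing_frac maximum tolerated per-day missing fraction.
#' @param missing_rule `"any"` or `"all"` (which days must violate to drop).
#' @param quiet suppress the removal-count log line.
#' @return the retained timelines, with attribute `removed` holding the
#'   per-rule removal counts.
#' @export
filter_cohort <- function(timelines, min_course = 1L, max_course = 21L,
                          max_missing_frac = 0.5,
                          missing_rule = c("any", "all"), quiet = FALSE) {
  missing_rule <- match.arg(missing_rule)
  bad_course <- vapply(timelines, function(tl) {
    len <- tl$course$initial_course_length
    len < min_course || len > max_course
  }, logical(1))
  bad_missing <- vapply(timelines, function(tl) {
    frac <- rowMeans(tl$missing_mask)
    if (missing_rule == "any") any(frac > max_missing_frac)
    else all(frac > max_missing_frac)
  }, logical(1))
  removed <- c(course_length = sum(bad_course),
               missingness = sum(bad_missing & !bad_course))
  if (!quiet) {
    message("filter_cohort: removed ", removed[["course_length"]],
            " stays by course length, ", removed[["missingness"]],
            " by per-day missingness; ", sum(!(bad_course | bad_missing)),
            " retained")
  }
  out <- timelines[!(bad_course | bad_missing)]
  attr(out, "removed") <- removed
  out
}

#' Stay-level train/validation/test split specification
#'
#' @param fractions train/validation/test proportions summing to 1.
#' @param seed RNG seed for the stay permutation.
#' @param oversample_factor number of *extra* replicas of each
#'   positive-mortality training stay in the mortality sampling index
#'   (3 extra, i.e. 4 total appearances, by default).
#' @return a `split_spec` list.
#' @export
split_spec <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                       seed = 1L, oversample_factor = 3L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, oversample_factor >= 0)
  names(fractions) <- c("train", "val", "test")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 oversample_factor = as.integer(oversample_factor)),
            class = "split_spec")
}

#' Partition stays into train/validation/test sets
#'
#' Splits by stay identifier (no stay straddles sets) with largest-remainder
#' rounding of the target set sizes; seeded and reproducible.
#'
#' @param stay_ids character vector of stay identifiers.
#' @param spec a [split_spec()].
#' @return list with character vectors `train`, `val`, `test`.
#' @export
split_by_stay <- function(stay_ids, spec = split_spec()) {
  stay_ids <- sort(unique(as.character(stay_ids)))
  n <- length(stay_ids)
  if (n < 3L) stop("need at least 3 stays to split", call. = FALSE)
  exact <- spec$fractions * n
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    # largest remainder; ties broken by set order train > val > test
    add <- order(-rem)[seq_len(short)]
    sizes[add] <- sizes[add] + 1L
  }
  perm <- with_seed(spec$seed, sample(stay_ids))
  list(train = sort(perm[seq_len(sizes[1L])]),
       val = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
       test = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]))
}

#' Oversample positive-mortality stays in the training index
#'
#' Returns a sampling index over `train_ids` in which every positive stay
#' appears `1 + factor` times and every negative stay once. Only the index is
#' replicated; the underlying data is never duplicated.
#'
#' @param train_ids character vector of training stay identifiers.
#' @param positive logical/0-1 vector aligned with `train_ids`.
#' @param factor number of extra replicas per positive stay.
#' @return character vector of stay ids (the sampling index).
#' @export
oversample_positive_mortality <- function(train_ids, positive, factor = 3L) {
  stopifnot(length(train_ids) == length(positive), factor >= 0)
  positive <- as.logical(positive)
  if (!any(positive)) {
    warning("no positive-mortality stays in the training set; index unchanged")
    return(train_ids)
  }
  reps <- ifelse(positive, 1L + as.integer(factor), 1L)
  rep(train_ids, times = reps)
}

#' Normalise features with statistics frozen on the training set
#'
#' Per feature: clip at the training 1st/99th percentiles, z-score by the
#' training mean/SD of the clipped values, forward-fill missing cells within
#' each stay, and set remaining leading-missing cells to 0 (the training
#' mean) with the missing indicator left at 1. Zero-variance training
#' features get scale 1 with a warning. The returned `stats` object is
#' sufficient to reapply the identical transform at inference time.
#'
#' @param timelines named list of raw timelines.
#' @param train_ids stay ids whose values define the statistics.
#' @param clip_probs lower/upper clipping percentiles.
#' @param stats optional pre-computed stats (from a previous call) to apply
#'   as-is, for inference on new data.
#' @return list with `timelines` (normalised; gains `features_norm`) and
#'   `stats`.
#' @export
normalise_features <- function(timelines, train_ids,
                               clip_probs = c(0.01, 0.99), stats = NULL) {
  feat_names <- colnames(timelines[[1L]]$features)
  D <- length(feat_names)
  if (is.null(stats)) {
    train_ids <- intersect(train_ids, names(timelines))
    train_vals <- lapply(seq_len(D), function(j) {
      unlist(lapply(timelines[train_ids], function(tl) {
        v <- tl$features[, j]
        v[!is.na(v)]
      }), use.names = FALSE)
    })
    lo <- hi <- mu <- sc <- numeric(D)
    zero_var <- character(0)
    for (j in seq_len(D)) {
      v <- train_vals[[j]]
      if (length(v) == 0L) {
        lo[j] <- -Inf; hi[j] <- Inf; mu[j] <- 0; sc[j] <- 1
        zero_var <- c(zero_var, feat_names[j])
        next
      }
      q <- quantile(v, clip_probs, names = FALSE, type = 7)
      lo[j] <- q[1L]; hi[j] <- q[2L]
      vc <- pmin(hi[j], pmax(lo[j], v))
      mu[j] <- mean(vc)
      s <- sd(vc)
      if (!is.finite(s) || s == 0) {
        s <- 1
        zero_var <- c(zero_var, feat_names[j])
      }
      sc[j] <- s
    }
    if (length(zero_var)) {
      warning("zero-variance training feature(s), scale forced to 1: ",
              paste(zero_var, collapse = ", "))
    }
    stats <- list(feature_names = feat_names, lower = lo, upper = hi,
                  mean = mu, sd = sc, clip_probs = clip_probs)
    class(stats) <- "feature_stats"
  } else {
    stopifnot(identical(stats$feature_names, feat_names))
  }
  for (sid in names(timelines)) {
    tl <- timelines[[sid]]
    X <- tl$features
    Z <- X
    for (j in seq_len(D)) {
      v <- pmin(stats$upper[j], pmax(stats$lower[j], X[, j]))
      Z[, j] <- (v - stats$mean[j]) / stats$sd[j]
    }
    # forward fill within the stay, leading missing -> 0 (training mean)
    if (nrow(Z) > 1L) {
      for (t in 2:nrow(Z)) {
        nas <- is.na(Z[t, ])
        Z[t, nas] <- Z[t - 1L, nas]
      }
    }
    Z[is.na(Z)] <- 0
    tl$features_norm <- Z
    timelines[[sid]] <- tl
  }
  list(timelines = timelines, stats = stats)
}

#' End-to-end preprocessing of a cohort
#'
#' Runs aggregation, treatment-course derivation, cohort filtering, the
#' stay-level split, training-set-frozen normalisation and the mortality
#' oversampling index, producing the dataset object consumed by
#' [train_autoencoder()] and [estimate_all()].
#'
#' @param events,abx,labels input tables (see [simulate_cohort()]).
#' @param split a [split_spec()].
#' @param min_course,max_course,max_missing_frac,missing_rule see
#'   [filter_cohort()].
#' @param collapse same-day duplicate collapse rule.
#' @param quiet suppress log lines.
#' @return an `abx_dataset` list: `stays` (normalised timelines), `split`,
#'   `stats`, `mortality_index` (oversampled training index),
#'   `feature_names`.
#' @export
preprocess_cohort <- function(events, abx, labels, split = split_spec(),
                              min_course = 1L, max_course = 21L,
                              max_missing_frac = 0.5, missing_rule = "any",
                              collapse = "mean", quiet = FALSE) {
  tls <- build_timelines(events, abx, labels, collapse = collapse)
  tls <- filter_cohort(tls, min_course = min_course, max_course = max_course,
                       max_missing_frac = max_missing_frac,
                       missing_rule = missing_rule, quiet = quiet)
  removed <- attr(tls, "removed")
  if (length(tls) < 3L) stop("fewer than 3 stays remain after filtering")
  sp <- split_by_stay(names(tls), split)
  norm <- normalise_features(tls, sp$train)
  train_pos <- vapply(norm$timelines[sp$train],
                      function(tl) tl$mortality_label == 1, logical(1))
  mort_idx <- oversample_positive_mortality(sp$train, train_pos,
                                            split$oversample_factor)
  ds <- list(stays = norm$timelines, split = sp, stats = norm$stats,
             mortality_index = mort_idx,
             feature_names = norm$stats$feature_names,
             removed = removed)
  class(ds) <- "abx_dataset"
  ds
}

#' @export
print.abx_dataset <- function(x, ...) {
  cat("<abx_dataset> ", length(x$stays), " stays (",
      length(x$split$train), " train / ", length(x$split$val), " val / ",
      length(x$split$test), " test), ", length(x$feature_names),
      " features\n", sep = "")
  invisible(x)
}
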