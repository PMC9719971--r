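#' Embed every antibiotic day of a cohort
#'
#' An antibiotic day is each day the patient receives treatment plus, for
#' stays that cease antibiotics in-ICU, the first antibiotic-free day (the
#' cessation day). Each such (stay, day) gets one embedding computed from
#' days `1..t`.
#'
#' @param model an `abx_encoder`.
#' @param dataset an `abx_dataset`.
#' @param stay_ids stays to embed (default: all stays in the dataset).
#' @return an `abx_embeddings` object: `meta`
#'   (`stay_id, day, status ("treat"/"cess"), treatment_length, stop_day,
#'   label_los, label_mort`) and `Z` (rows = embeddings).
#' @export
embed_antibiotic_days <- function(model, dataset, stay_ids = NULL) {
  stopifnot(inherits(model, "abx_encoder"), inherits(dataset, "abx_dataset"))
  if (is.null(stay_ids)) stay_ids <- names(dataset$stays)
  metas <- vector("list", length(stay_ids))
  zs <- vector("list", length(stay_ids))
  for (i in seq_along(stay_ids)) {
    sid <- stay_ids[i]
    tl <- dataset$stays[[sid]]
    treat_days <- which(tl$abx_status == 1L)
    stopd <- tl$course$stop_day
    days <- treat_days
    status <- rep("treat", length(treat_days))
    if (!is.na(stopd)) {
      days <- c(days, stopd)
      status <- c(status, "cess")
    }
    o <- order(days)
    days <- days[o]; status <- status[o]
    X <- build_input_matrix(tl)
    Z <- cpp_encode_prefixes(model$params, X, days)
    metas[[i]] <- data.table::data.table(
      stay_id = sid, day = as.integer(days), status = status,
      treatment_length = sum(tl$abx_status),
      stop_day = if (is.na(stopd)) NA_integer_ else as.integer(stopd),
      label_los = tl$los_label, label_mort = as.numeric(tl$mortality_label))
    zs[[i]] <- t(Z)
  }
  meta <- data.table::rbindlist(metas)
  meta[, row := .I]
  out <- list(meta = meta[], Z = do.call(rbind, zs),
              task = model$config$task,
              embedding_dim = model$config$embedding_dim)
  class(out) <- "abx_embeddings"
  out
}

#' Build day- and treatment-status-partitioned donor pools
#'
#' For each day `t`, the "continue" pool holds the embeddings of stays that
#' receive antibiotics on day `t`, and the "stop" pool holds the embeddings
#' of stays whose cessation day is `t`. Every antibiotic (stay, day) record
#' therefore belongs to exactly one pool for its day. With
#' `ablation = TRUE`, segregation is disabled: a single merged pool (all
#' antibiotic days, both statuses) backs every query, reproducing the
#' no-segregation ablation.
#'
#' @param embeddings an `abx_embeddings` object.
#' @param ablation disable day/status segregation.
#' @return a `donor_pools` object.
#' @export
build_donor_index <- function(embeddings, ablation = FALSE) {
  stopifnot(inherits(embeddings, "abx_embeddings"))
  structure(list(meta = embeddings$meta, Z = embeddings$Z,
                 ablation = isTRUE(ablation)),
            class = "donor_pools")
}

# candidate donor rows for a (day, scenario) query
pool_rows <- function(pools, day, scenario) {
  m <- pools$meta
  if (pools$ablation) return(m$row)
  if (scenario == "continue") m$row[m$status == "treat" & m$day == day]
  else m$row[m$status == "cess" & m$day == day]
}

#' Select the k nearest donors from a pool
#'
#' Euclidean nearest neighbours of the subject embedding among the pool
#' members, ties broken by ascending stay id then day. If the pool holds
#' fewer than `k` members, all are returned.
#'
#' @param z subject embedding (numeric vector).
#' @param pools a `donor_pools` object.
#' @param day day index of the query.
#' @param scenario `"stop"` or `"continue"`.
#' @param k number of donors (default 10).
#' @param exclude_stay stay id(s) never used as donors (the subject's own).
#' @return a `data.table` of donors ordered by distance
#'   (`stay_id, day, distance, row`), with attribute `n_available`; zero
#'   rows when the pool is empty.
#' @export
select_donors <- function(z, pools, day, scenario = c("stop", "continue"),
                          k = 10L, exclude_stay = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(k >= 1)
  rows <- pool_rows(pools, day, scenario)
  if (!is.null(exclude_stay)) {
    rows <- rows[!(pools$meta$stay_id[rows] %in% exclude_stay)]
  }
  n_avail <- length(rows)
  if (n_avail == 0L) {
    out <- data.table::data.table(stay_id = character(), day = integer(),
                                  distance = numeric(), row = integer())
    attr(out, "n_available") <- 0L
    return(out)
  }
  d2 <- colSums((t(pools$Z[rows, , drop = FALSE]) - z)^2)
  m <- pools$meta[rows]
  o <- order(d2, m$stay_id, m$day)
  take <- o[seq_len(min(k, n_avail))]
  out <- data.table::data.table(stay_id = m$stay_id[take],
                                day = m$day[take],
                                distance = sqrt(d2[take]),
                                row = rows[take])
  attr(out, "n_available") <- n_avail
  out
}

#' Ridge donor weights
#'
#' Minimises the ridge objective
#' \deqn{\sum_d \left[z_d - \sum_j x_{j,d} w_j\right]^2 + \lambda \sum_j w_j^2}
#' over donor weights `w`, returning the closed-form unique minimiser
#' `(X'X + lambda I)^{-1} X'z`. The L2 penalty distributes weight across
#' donors instead of concentrating it on the single nearest one.
#'
#' @param z subject embedding (length D).
#' @param X D x k matrix whose columns are donor embeddings.
#' @param lambda ridge penalty (default 1, the unit penalty of the
#'   objective above).
#' @return numeric weight vector of length k.
#' @export
ridge_weights <- function(z, X, lambda = 1) {
  X <- as.matrix(X)
  if (length(z) != nrow(X)) stop("z and donor columns differ in dimension")
  if (!all(is.finite(z)) || !all(is.finite(X))) {
    stop("non-finite entries in ridge system")
  }
  if (lambda < 0) stop("lambda must be non-negative")
  k <- ncol(X)
  A <- crossprod(X) + diag(lambda, k)
  drop(solve(A, crossprod(X, z)))
}

#' Weighted-average donor outcome
#'
#' The scenario outcome is the weighted average of the donor labels. Weights
#' are renormalised to sum to 1 by default so that the estimate is a true
#' weighted average lying within the donor label range; with
#' `normalise = FALSE` the raw ridge weights are used as-is.
#'
#' @param w donor weights from [ridge_weights()].
#' @param labels donor outcome labels, aligned with `w`.
#' @param normalise renormalise weights to sum to 1.
#' @return the estimated outcome, with attribute `uniform_fallback` set when
#'   the weights summed to ~0 and a uniform average was used instead.
#' @export
estimate_outcome <- function(w, labels, normalise = TRUE) {
  stopifnot(length(w) == length(labels), length(w) >= 1)
  fallback <- FALSE
  if (normalise) {
    s <- sum(w)
    if (abs(s) < 1e-10) {
      warning("donor weights sum to ~0; falling back to uniform weights")
      w <- rep(1 / length(w), length(w))
      fallback <- TRUE
    } else {
      w <- w / s
    }
  }
  structure(sum(w * labels), uniform_fallback = fallback)
}

#' Estimate stop and continue outcomes for every antibiotic day
#'
#' For each subject (stay, antibiotic day) and each scenario, selects the k
#' nearest donors from the relevant pool (always excluding the subject's own
#' stay), solves the ridge weighting problem and returns the weighted-average
#' donor outcome. Days whose pool is empty yield flagged no-estimates.
#'
#' @param embeddings an `abx_embeddings` object (the donor population is the
#'   full set of embedded stays; restrict via `donor_stays` for e.g. a
#'   test-only donor mode).
#' @param outcome which label the donors contribute: `"los"` or
#'   `"mortality"` (the latter clamped to `[0, 1]`).
#' @param k donors per estimate (default 10).
#' @param lambda ridge penalty (default 1).
#' @param subject_stays stays to estimate (default: all embedded stays).
#' @param donor_stays stays allowed as donors (default: all embedded stays).
#' @param ablation disable embedding-space segregation (see
#'   [build_donor_index()]).
#' @param normalise renormalise ridge weights before averaging.
#' @param keep_donors retain per-estimate donor ids and raw weights as list
#'   columns (off by default; they dominate memory at cohort scale).
#' @return a `data.table` with one row per (stay, day, scenario):
#'   `stay_id, day, status, scenario, outcome_type, estimate, label,
#'   n_donors_available, flag` (+ `donor_ids`, `raw_weights` if requested).
#' @export
estimate_all <- function(embeddings, outcome = c("los", "mortality"),
                         k = 10L, lambda = 1, subject_stays = NULL,
                         donor_stays = NULL, ablation = FALSE,
                         normalise = TRUE, keep_donors = FALSE) {
  stopifnot(inherits(embeddings, "abx_embeddings"))
  outcome <- match.arg(outcome)
  meta <- embeddings$meta
  if (is.null(subject_stays)) subject_stays <- unique(meta$stay_id)
  donor_meta_rows <- if (is.null(donor_stays)) meta$row
                     else meta$row[meta$stay_id %in% donor_stays]
  pools <- structure(list(meta = meta[donor_meta_rows], Z = embeddings$Z,
                          ablation = isTRUE(ablation)),
                     class = "donor_pools")
  label_col <- if (outcome == "los") "label_los" else "label_mort"
  subj <- meta[meta$stay_id %in% subject_stays]

  res <- list()
  for (scenario in c("stop", "continue")) {
    # group subjects by day so each pool is assembled once
    for (d in sort(unique(subj$day))) {
      sub_d <- subj[day == d]
      ns <- nrow(sub_d)
      rows <- pool_rows(pools, d, scenario)
      cand_meta <- pools$meta[match(rows, pools$meta$row)]
      cand_labels <- cand_meta[[label_col]]
      Zc <- embeddings$Z[rows, , drop = FALSE]
      Zs <- embeddings$Z[sub_d$row, , drop = FALSE]
      # squared distances subjects x candidates
      if (length(rows)) {
        D2 <- outer(rowSums(Zs^2), rowSums(Zc^2), "+") - 2 * tcrossprod(Zs, Zc)
      }
      est_v <- rep(NA_real_, ns)
      nav_v <- integer(ns)
      flag_v <- rep("empty_pool", ns)
      don_v <- if (keep_donors) rep(list(character(0)), ns) else NULL
      wts_v <- if (keep_donors) rep(list(numeric(0)), ns) else NULL
      for (si in seq_len(ns)) {
        ok <- if (length(rows)) cand_meta$stay_id != sub_d$stay_id[si]
              else logical(0)
        n_avail <- sum(ok)
        nav_v[si] <- n_avail
        if (n_avail == 0L) next
        widx <- which(ok)
        d2 <- pmax(D2[si, widx], 0)
        o <- order(d2, cand_meta$stay_id[widx], cand_meta$day[widx])
        take <- widx[o[seq_len(min(k, n_avail))]]
        X <- t(Zc[take, , drop = FALSE])            # D x k
        w <- ridge_weights(Zs[si, ], X, lambda)
        est <- suppressWarnings(
          estimate_outcome(w, cand_labels[take], normalise = normalise))
        flag_v[si] <- if (isTRUE(attr(est, "uniform_fallback")))
          "uniform_fallback" else "ok"
        est <- as.numeric(est)
        if (outcome == "mortality") est <- min(1, max(0, est))
        est_v[si] <- est
        if (keep_donors) {
          don_v[[si]] <- cand_meta$stay_id[take]
          wts_v[[si]] <- w
        }
      }
      grp <- data.table::data.table(
        stay_id = sub_d$stay_id, day = sub_d$day, status = sub_d$status,
        treatment_length = sub_d$treatment_length,
        scenario = scenario, outcome_type = outcome,
        estimate = est_v, label = sub_d[[label_col]],
        n_donors_available = nav_v, flag = flag_v)
      if (keep_donors) {
        grp[, donor_ids := don_v]
        grp[, raw_weights := wts_v]
      }
      res[[length(res) + 1L]] <- grp
    }
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, stay_id, day, scenario)
  out[]
}
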