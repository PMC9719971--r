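test_that("donor pools partition antibiotic days by day and status", {
  # stay A treated days 1-3, stops day 4; stay B discharged on antibiotics
  meta <- data.table::data.table(
    stay_id = c(rep("A", 4), rep("B", 2)),
    day = c(1:4, 1:2),
    status = c("treat", "treat", "treat", "cess", "treat", "treat"),
    label_los = c(rep(5, 4), rep(2, 2)))
  emb <- make_embeddings(meta, matrix(0, 6, 2))
  pools <- build_donor_index(emb)
  for (t in 1:3) {
    expect_true(any(emb$meta$stay_id[abxsc:::pool_rows(pools, t, "continue")] == "A"))
  }
  expect_false(any(emb$meta$stay_id[abxsc:::pool_rows(pools, 4, "continue")] == "A"))
  expect_identical(emb$meta$stay_id[abxsc:::pool_rows(pools, 4, "stop")], "A")
  # B never appears in any stop pool
  for (t in 1:4) {
    expect_false(any(emb$meta$stay_id[abxsc:::pool_rows(pools, t, "stop")] == "B"))
  }
  # each record lives in exactly one pool for its day
  n_mem <- sum(vapply(1:4, function(t) {
    length(abxsc:::pool_rows(pools, t, "stop")) +
      length(abxsc:::pool_rows(pools, t, "continue"))
  }, 1L))
  expect_equal(n_mem, nrow(meta))
  # degenerate: everyone stopping at day 2 empties later continue pools
  meta2 <- data.table::data.table(stay_id = c("X", "X", "Y", "Y"),
                                  day = c(1, 2, 1, 2),
                                  status = rep(c("treat", "cess"), 2))
  pools2 <- build_donor_index(make_embeddings(meta2, matrix(0, 4, 2)))
  expect_length(abxsc:::pool_rows(pools2, 2, "continue"), 0L)
})

test_that("donor selection matches exhaustive distance sorting", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 25L
    Z <- matrix(round(rnorm(n * 3), 1), n, 3)  # rounding forces ties
    meta <- data.table::data.table(
      stay_id = sprintf("d%02d", sample(n)), day = 3L,
      status = "cess", label_los = runif(n))
    emb <- make_embeddings(meta, Z)
    pools <- build_donor_index(emb)
    z <- round(rnorm(3), 1)
    got <- select_donors(z, pools, 3, "stop", k = 5)
    d2 <- colSums((t(Z) - z)^2)
    o <- order(d2, meta$stay_id, meta$day)
    expect_identical(got$row, seq_len(n)[o[1:5]])
    expect_equal(attr(got, "n_available"), n)
  }
  # whole pool returned when k equals (or exceeds) the pool size
  emb <- make_embeddings(data.table::data.table(
    stay_id = sprintf("d%d", 1:10), day = 2L, status = "cess"),
    matrix(rnorm(20), 10, 2))
  pools <- build_donor_index(emb)
  expect_equal(nrow(select_donors(rnorm(2), pools, 2, "stop", k = 10)), 10L)
  # coincident donor ranks first
  gotc <- select_donors(emb$Z[4, ], pools, 2, "stop", k = 3)
  expect_equal(gotc$row[1], 4L)
  expect_equal(gotc$distance[1], 0)
  # empty pool flagged, not an exception
  none <- select_donors(rnorm(2), pools, 9, "stop", k = 3)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_available"), 0L)
})

test_that("ridge weights solve the penalised objective in closed form", {
  # single donor: w = x'z / (x'x + lambda)
  expect_equal(ridge_weights(c(1, 0), matrix(c(1, 0), 2, 1), lambda = 1), 0.5)
  # orthonormal donors, z their sum, no penalty: exact interpolation
  X <- diag(3)
  expect_equal(ridge_weights(c(1, 1, 1), X, lambda = 0), rep(1, 3))
  # random instances match a numerical minimiser of the printed objective
  set.seed(5)
  for (rep in 1:10) {
    D <- 4L; k <- 6L
    X <- matrix(rnorm(D * k), D, k)
    z <- rnorm(D)
    w <- ridge_weights(z, X, lambda = 1)
    obj <- function(w) sum((z - X %*% w)^2) + sum(w^2)
    opt <- optim(rep(0, k), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(max(abs(w - opt$par)), 1e-6)
  }
  expect_error(ridge_weights(c(1, NA), matrix(1, 2, 1)), "non-finite")
  expect_error(ridge_weights(1, matrix(1, 1, 1), lambda = -1), "non-negative")
})

test_that("outcome estimates are weighted donor averages", {
  # constant labels are invariant to the weights
  expect_equal(as.numeric(estimate_outcome(c(0.2, -3, 7), rep(4, 3))), 4)
  # hand example with normalisation
  expect_equal(as.numeric(estimate_outcome(c(1, 3), c(2, 6))), 5)
  # single donor returns that donor's label
  expect_equal(as.numeric(estimate_outcome(0.3, 9)), 9)
  # degenerate weights fall back to the uniform average, flagged
  expect_warning(est <- estimate_outcome(c(1, -1), c(2, 6)), "uniform")
  expect_equal(as.numeric(est), 4)
  expect_true(attr(est, "uniform_fallback"))
  # raw (unnormalised) mode
  expect_equal(as.numeric(estimate_outcome(c(0.5, 0.25), c(2, 4),
                                           normalise = FALSE)), 2)
})

test_that("cohort-wide estimation covers both scenarios on every antibiotic day", {
  emb <- tiny_embeddings()
  est <- tiny_estimates()
  expect_equal(nrow(est), 2L * nrow(emb$meta))
  expect_setequal(unique(est$scenario), c("stop", "continue"))
  # flagged no-estimates are exactly the empty-pool queries
  expect_identical(is.na(est$estimate), est$flag == "empty_pool")
  expect_true(all(est$n_donors_available[est$flag == "empty_pool"] == 0L))
  # unconstrained ridge weights may extrapolate beyond the donor label
  # range (documented); estimates must still be finite
  expect_true(all(is.finite(est$estimate[!is.na(est$estimate)])))
})

test_that("k saturation uses the whole pool and records availability", {
  emb <- tiny_embeddings()
  est <- estimate_all(emb, outcome = "los", k = 10000L)
  ok <- est[!is.na(est$estimate)]
  expect_true(all(ok$n_donors_available < 10000L))
})

test_that("disabling segregation merges pools across days and scenarios", {
  emb <- tiny_embeddings()
  est <- estimate_all(emb, outcome = "los", k = 5, ablation = TRUE)
  # every subject now sees the full (minus own stay) donor population
  per_stay_days <- table(emb$meta$stay_id)
  ok <- est[!is.na(est$estimate)]
  expect_true(all(ok$n_donors_available ==
                    nrow(emb$meta) - per_stay_days[ok$stay_id]))
  # stop and continue estimates coincide (one merged pool)
  wide <- data.table::dcast(ok, stay_id + day ~ scenario, value.var = "estimate")
  expect_equal(wide$stop, wide$continue)
})

test_that("estimates are invariant to pool order and to removing non-donors", {
  emb <- tiny_embeddings()
  est <- estimate_all(emb, outcome = "los", k = 5, keep_donors = TRUE)
  # permute the embedding rows
  set.seed(99)
  perm <- sample(nrow(emb$meta))
  emb2 <- emb
  emb2$meta <- emb$meta[perm]
  emb2$meta[, row := .I]
  emb2$Z <- emb$Z[perm, , drop = FALSE]
  est2 <- estimate_all(emb2, outcome = "los", k = 5)
  j <- c("stay_id", "day", "scenario")
  merged <- merge(est[, c(j, "estimate"), with = FALSE],
                  est2[, c(j, "estimate"), with = FALSE], by = j)
  expect_equal(merged$estimate.x, merged$estimate.y)

  # removing a stay that donated to nothing of subject s leaves s unchanged
  subj <- est[!is.na(estimate) & flag == "ok"][1]
  donors_used <- unlist(est[stay_id == subj$stay_id, donor_ids])
  bystander <- setdiff(unique(emb$meta$stay_id),
                       c(subj$stay_id, donors_used))[1]
  expect_false(is.na(bystander))
  est3 <- estimate_all(emb, outcome = "los", k = 5,
                       subject_stays = subj$stay_id,
                       donor_stays = setdiff(unique(emb$meta$stay_id), bystander))
  row3 <- est3[day == subj$day & scenario == subj$scenario]
  expect_equal(row3$estimate, subj$estimate)
})

test_that("large penalties converge to the penalty-free weight profile", {
  # as lambda grows the raw weights shrink like X'z / lambda, so after
  # renormalisation the estimate converges to the lambda-independent
  # weighted mean with weights proportional to X'z
  emb <- tiny_embeddings()
  est_inf <- estimate_all(emb, outcome = "los", k = 5, lambda = 1e9,
                          keep_donors = TRUE)
  r <- est_inf[!is.na(estimate) & flag == "ok"][5]
  don <- unlist(r$donor_ids)
  want_status <- if (r$scenario == "stop") "cess" else "treat"
  drows <- emb$meta[stay_id %in% don & day == r$day & status == want_status]
  drows <- drows[match(don, drows$stay_id)]
  subj <- emb$meta[stay_id == r$stay_id & day == r$day][1]
  z <- emb$Z[subj$row, ]
  X <- t(emb$Z[drows$row, , drop = FALSE])
  w_lim <- drop(crossprod(X, z))          # limiting raw-weight profile
  w_lim <- w_lim / sum(w_lim)
  expect_equal(r$estimate, sum(w_lim * drows$label_los), tolerance = 1e-6)
  est_inf2 <- estimate_all(emb, outcome = "los", k = 5, lambda = 1e8)
  r2 <- est_inf2[stay_id == r$stay_id & day == r$day & scenario == r$scenario]
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-4)
  # and k = 1 returns the nearest donor's label exactly
  est1 <- estimate_all(emb, outcome = "los", k = 1, keep_donors = TRUE)
  r1 <- est1[!is.na(estimate)][3]
  expect_equal(r1$estimate,
               emb$meta$label_los[match(unlist(r1$donor_ids), emb$meta$stay_id)])
})
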