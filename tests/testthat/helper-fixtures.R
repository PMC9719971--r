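# Shared fixtures, memoised so expensive objects (small trained encoders)
# are built once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fix)) assign(key, builder(), envir = .fix)
  get(key, envir = .fix)
}

tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    simulate_cohort(sim_config(n_stays = 80, seed = 7))
  })
}

tiny_dataset <- function() {
  memo("tiny_dataset", function() {
    co <- tiny_cohort()
    preprocess_cohort(co$events, co$abx, co$labels,
                      split = split_spec(seed = 8), quiet = TRUE)
  })
}

# a small trained LOS encoder shared by embedding / estimation tests
tiny_model <- function() {
  memo("tiny_model", function() {
    train_autoencoder(tiny_dataset(),
                      encoder_config("los", embedding_dim = 6,
                                     hidden_size = 12, epochs = 2,
                                     batch_size = 16, seed = 9))
  })
}

tiny_embeddings <- function() {
  memo("tiny_embeddings", function() {
    embed_antibiotic_days(tiny_model(), tiny_dataset())
  })
}

tiny_estimates <- function() {
  memo("tiny_estimates", function() {
    estimate_all(tiny_embeddings(), outcome = "los", k = 5, lambda = 1)
  })
}

# hand-built embeddings object for donor-pool unit tests
make_embeddings <- function(meta, Z) {
  meta <- data.table::as.data.table(meta)
  if (!"treatment_length" %in% names(meta)) meta[, treatment_length := NA_integer_]
  if (!"stop_day" %in% names(meta)) meta[, stop_day := NA_integer_]
  if (!"label_los" %in% names(meta)) meta[, label_los := 0]
  if (!"label_mort" %in% names(meta)) meta[, label_mort := 0]
  meta[, row := .I]
  structure(list(meta = meta[], Z = as.matrix(Z), task = "los",
                 embedding_dim = ncol(Z)),
            class = "abx_embeddings")
}

# raw-table builders for preprocess tests
events_row <- function(stay, day, var, val) {
  data.table::data.table(stay_id = stay, day = as.integer(day),
                         variable = var, value = val)
}
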