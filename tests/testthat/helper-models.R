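# Shared heavyweight fixtures, computed once per test session.
# The maneuver-trained predictors are reused by several efficacy tests.

.model_cache <- new.env(parent = emptyenv())

# histories and held-out examples from the maneuver (turn + oscillation)
# preset; training and test scenarios differ only by seed
maneuver_examples <- function(L = 10L) {
  key <- paste0("ex_L", L)
  if (is.null(.model_cache[[key]])) {
    tr <- make_history_examples(generate_truth(preset("maneuver", seed = 101L)), L = L)
    te <- make_history_examples(generate_truth(preset("maneuver", seed = 202L)), L = L)
    set.seed(1)
    te <- te[sample(nrow(te), 600L), ]
    .model_cache[[key]] <- list(train = tr, test = te)
  }
  .model_cache[[key]]
}

maneuver_model <- function(L = 10L) {
  key <- paste0("mod_L", L)
  if (is.null(.model_cache[[key]])) {
    ex <- maneuver_examples(L)
    cfg <- predictor_config(
      L = L, model_dim = 16L, epochs = 40L, batch_size = 256L,
      learning_rate = 3e-3, seed = 5L
    )
    .model_cache[[key]] <- train_predictor(ex$train, cfg)
  }
  .model_cache[[key]]
}
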