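# Heavy pipeline results shared across test files, computed once per run.
.pipeline_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .pipeline_cache)) {
    assign(name, fn(), envir = .pipeline_cache)
  }
  get(name, envir = .pipeline_cache)
}

# The default 13-study training collection and its fitted model.
training_collection <- function() {
  cached("coll_train", function() simulate_collection(synthetic_config(seed = 1)))
}
training_fit <- function() {
  cached("fit_train", function() metasig_fit(training_collection()$studies))
}

# A 15-study collection split into 13 training + 2 held-out cohorts.
holdout_collection <- function() {
  cached("coll_holdout", function()
    simulate_collection(synthetic_config(n_studies = 15L, seed = 2)))
}
holdout_fit <- function() {
  cached("fit_holdout", function() {
    sp <- split_train_test(holdout_collection(), 2L)
    metasig_fit(sp$train)
  })
}
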