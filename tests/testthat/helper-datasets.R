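# Shared simulated datasets and DE runs, memoized so independent tests can
# reuse the same realizations without regenerating them.

# micro community: fast enough for structural tests
micro_args <- function() {
  list(n_species = 6L, pool_size = 60L, genes_per_species = 30L,
       n_samples = 40L, depth_range = c(800, 2000))
}

.fixture_cache <- new.env(parent = emptyenv())

shared_dataset <- function(preset, seed, args = desk_scale()) {
  key <- paste("ds", preset, seed, paste(unlist(args), collapse = ","),
               sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      do.call(make_dataset, c(list(preset = preset, seed = seed), args))
  }
  .fixture_cache[[key]]
}

# pooled evaluation of one (preset, model, filter, response) cell over seeds
shared_eval <- function(preset, model, filter = "strict",
                        response = "linear", seeds = 1:3,
                        args = desk_scale()) {
  key <- paste("ev", preset, model, filter, response,
               paste(seeds, collapse = ","),
               paste(unlist(args), collapse = ","), sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    evs <- lapply(seeds, function(s) {
      d <- shared_dataset(preset, 1000 + s, args)
      score_de(run_de(d, model_spec(model, filter, response)), d$truth)
    })
    .fixture_cache[[key]] <- do.call(rbind, evs)
  }
  .fixture_cache[[key]]
}

pooled_fpr <- function(ev) sum(ev$fp) / sum(ev$n_neg_tested)
pooled_tpr <- function(ev) sum(ev$tp) / sum(ev$n_pos)

# binomial CI half-width for a proportion p0 observed over n trials
binom_halfwidth <- function(p0, n) 1.96 * sqrt(p0 * (1 - p0) / n)
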