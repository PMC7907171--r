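# Neuroevolution runs are the most expensive shared ingredient of the
# suite; cache them per (gate, lambda, seed) so the exactness, parsimony
# and size-ordering checks reuse the same runs.
nn_cache <- new.env(parent = emptyenv())

run_nn <- function(gate, lambda, seed) {
  key <- paste(gate, lambda, seed, sep = "|")
  if (is.null(nn_cache[[key]]))
    nn_cache[[key]] <- evolve_networks(evo_config(lambda = lambda,
                                                  seed = seed),
                                       gate_truth_tables()[[gate]])
  nn_cache[[key]]
}
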