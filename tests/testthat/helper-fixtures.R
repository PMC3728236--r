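# Small instruments and data builders shared across test files.

make_instrument <- function(n_items, max_category = 4L,
                            subscale = "impact") {
  do.call(instrument, lapply(seq_len(n_items), function(i) {
    item_spec(sprintf("i%02d", i), paste("test item", i),
              max_category, subscale)
  }))
}

make_responses <- function(values, max_category = max(values, na.rm = TRUE)) {
  values <- as.matrix(values)
  inst <- make_instrument(ncol(values), max_category = max(1L, max_category))
  colnames(values) <- inst$item_id
  response_matrix(values, inst)
}

default_rule_for_tests <- function() {
  inst <- absst_instrument()
  pivot_rule(inst$item_id, pmin(3L, inst$max_category))
}

# independent PCM probability oracle: direct summation of the defining
# formula, no shared code with pcm_category_probs
oracle_pcm_probs <- function(theta, steps) {
  m <- length(steps)
  num <- vapply(0:m, function(h) {
    if (h == 0) 1 else exp(sum(theta - steps[seq_len(h)]))
  }, numeric(1))
  num / sum(num)
}
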