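# Shared fixtures: all built in code, no files.

default_params <- function() {
  mpt_parameters(C = 0.4, P_Moral = 0.6, P_Hypocritical = 0.3,
                 P_Antisocial = 0.2, b = 0.1)
}

random_params <- function(lo = 0.1, hi = 0.9) {
  v <- stats::runif(5, lo, hi)
  mpt_parameters(v[1], v[2], v[3], v[4], v[5])
}

# Category table with counts exactly proportional to the model probabilities
# (possibly non-integer): the saturated-recovery fixture.
table_from_params <- function(params_by_condition, n_per_tree = 1000) {
  counts <- lapply(params_by_condition, function(p) {
    pr <- category_probabilities(p)
    n_per_tree * as.numeric(pr)
  })
  category_table(counts)
}

cell_key <- function(tree, choice, punished) {
  paste(tree, paste(choice, ifelse(punished, "punished", "unpunished"),
                    sep = "_"), sep = ".")
}
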