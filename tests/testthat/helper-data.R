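# Shared fixtures, all built in code.

# Small deterministic synthetic dataset used across tests.
test_dataset <- function(seed = 101) {
  generate_trial_data(generator_config(seed = seed))
}

# A record set where me > de, a digestibility out of range etc., for
# invariant-violation tests.
broken_records <- function() {
  d <- test_dataset()[1:3, ]
  d$me[1] <- d$de[1] + 1
  d$dmd[2] <- 1.2
  d$ge[3] <- -1
  d
}

ref_ranges <- function() {
  rs <- reference_summary("internal")
  setNames(
    lapply(rs$variable, function(v)
      c(min = rs$min[rs$variable == v], max = rs$max[rs$variable == v])),
    rs$variable)
}
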