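# Shared fixtures, built in code at test time.

# The full demographic target grid: N^ x L^ x delta (27 points).
demographic_grid <- function() {
  expand.grid(n_hat = c(200, 350, 500),
              lifespan = c(3, 5, 7.5),
              delta = c(1 / 550, 1 / 1000, 1 / 1500),
              KEEP.OUT.ATTRS = FALSE)
}

# A small, fast configuration for plumbing tests; any field overridable.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_hat = 200, lifespan = 5, delta = 1e-3, mode = "fertility",
         steps = 300L, burn_in = 100L, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

# A hand-built population state with explicit fields, for phase-level tests.
make_state <- function(age, adapted = rep(FALSE, length(age)),
                       xi = rep(0.5, length(age)),
                       paid_cost = rep(FALSE, length(age)),
                       n_census = NA_integer_) {
  structure(list(age = as.integer(age), adapted = adapted, xi = xi,
                 paid_cost = paid_cost,
                 t = 0L, env_epoch = 0L, steps_since_switch = 0L,
                 n_census = as.integer(n_census), n_births = 0L,
                 n_at_risk = NA_integer_, n_survivors = NA_integer_,
                 switched = FALSE, orphan_learning_events = 0L),
            class = "population_state")
}
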