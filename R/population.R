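# Population state is a plain list of parallel vectors (one slot per living
# individual) plus scalar clocks. All phase functions are pure: they take a
# state and return the updated state, drawing from the global RNG in a fixed
# documented order so a run is bit-reproducible from its seed.

#' Initialize a population
#'
#' Founds the population with `init_n_adults` non-adapted adults (age 1),
#' learning propensities drawn per `init_xi`, and all clocks at zero.
#' Deterministic given the RNG state; [run_sim()] seeds the RNG with
#' `config$seed` immediately before calling this.
#'
#' @param config A [sim_config()] object.
#' @return A `population_state`: list with per-individual vectors `age`,
#'   `adapted`, `xi`, `paid_cost` and scalars `t`, `env_epoch`,
#'   `steps_since_switch`, `n_census`, `n_births`, `n_at_risk`,
#'   `n_survivors`, `switched`, `orphan_learning_events`.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$init_n_adults
  xi <- if (identical(config$init_xi, "uniform")) {
    stats::runif(n)
  } else {
    rep(as.numeric(config$init_xi), n)
  }
  structure(list(
    age = rep(1L, n),
    adapted = rep(FALSE, n),
    xi = xi,
    paid_cost = rep(FALSE, n),
    t = 0L, env_epoch = 0L, steps_since_switch = 0L,
    n_census = NA_integer_, n_births = 0L,
    n_at_risk = NA_integer_, n_survivors = NA_integer_,
    switched = FALSE, orphan_learning_events = 0L
  ), class = "population_state")
}

#' Pre-birth density census
#'
#' Counts every living individual at the start of a time step, before
#' births. This single value feeds both density factors (fertility and
#' mortality) within the step; its fixed point analytically reproduces the
#' closed-form equilibria of the two-age-class recursions under both modes.
#'
#' @param state A `population_state`.
#' @return Non-negative integer count.
#' @export
density_census <- function(state) {
  length(state$age)
}

#' Mutate a learning propensity
#'
#' Offspring inherit the parental propensity xi plus a Gaussian increment
#' with standard deviation `mu_xi`, clamped into \[0, 1\].
#'
#' @param parent_xi Parental xi values in \[0, 1\] (vectorized).
#' @param mu_xi Mutation standard deviation, >= 0.
#' @return Mutated values in \[0, 1\]; equal to `parent_xi` when
#'   `mu_xi = 0`.
#' @export
mutate_xi <- function(parent_xi, mu_xi) {
  stopifnot(mu_xi >= 0)
  n <- length(parent_xi)
  pmin(1, pmax(0, parent_xi + stats::rnorm(n, 0, mu_xi)))
}

#' Birth-and-mutation phase
#'
#' Each adult (age >= 1) gives birth to a single offspring with probability
#' `b` (non-adapted) or `beta * b` (adapted), multiplied by
#' `exp(-delta * N_t)` under fertility regulation, where `N_t` is the
#' pre-birth census. Newborns enter at age 0, non-adapted (learning happens
#' in the next phase), with mutated xi.
#'
#' @param state A `population_state` with `n_census` set (see
#'   [density_census()]; falls back to the current count if unset).
#' @param config A [sim_config()].
#' @return Updated state with newborns appended and `n_births` set.
#' @export
birth_phase <- function(state, config) {
  d <- config$derived
  n_t <- if (is.na(state$n_census)) density_census(state) else state$n_census
  is_adult <- state$age >= 1L
  n_ad <- sum(is_adult)
  if (n_ad == 0L) {
    state$n_births <- 0L
    return(state)
  }
  p <- d$b * (1 + (config$beta - 1) * state$adapted[is_adult])
  if (config$mode == "fertility") p <- p * exp(-d$delta * n_t)
  gives <- stats::runif(n_ad) < p
  nb <- sum(gives)
  state$n_births <- nb
  if (nb > 0L) {
    child_xi <- mutate_xi(state$xi[is_adult][gives], config$mu_xi)
    state$age <- c(state$age, rep(0L, nb))
    state$adapted <- c(state$adapted, rep(FALSE, nb))
    state$xi <- c(state$xi, child_xi)
    state$paid_cost <- c(state$paid_cost, rep(FALSE, nb))
  }
  state
}

#' Learning phase
#'
#' Every age-0 individual learns exactly once: with probability equal to its
#' own xi it attempts individual learning (marking `paid_cost`, becoming
#' adapted with probability `w`); otherwise it learns socially, copying the
#' adapted/non-adapted variant of one adult drawn uniformly with replacement
#' from the demonstrator pool (all individuals of age >= 1 present at this
#' phase, i.e. same-step newborns excluded). If juveniles are present but no
#' demonstrator exists, social learners remain non-adapted and the event is
#' counted in `orphan_learning_events`.
#'
#' @inheritParams birth_phase
#' @return Updated state.
#' @export
learning_phase <- function(state, config) {
  juv <- which(state$age == 0L)
  nj <- length(juv)
  if (nj == 0L) return(state)
  ind <- stats::runif(nj) < state$xi[juv]
  state$paid_cost[juv] <- ind
  n_ind <- sum(ind)
  if (n_ind > 0L) {
    state$adapted[juv[ind]] <- stats::runif(n_ind) < config$w
  }
  soc <- juv[!ind]
  n_soc <- length(soc)
  if (n_soc > 0L) {
    pool <- which(state$age >= 1L)
    if (length(pool) == 0L) {
      state$orphan_learning_events <- state$orphan_learning_events + n_soc
    } else {
      demo <- pool[sample.int(length(pool), n_soc, replace = TRUE)]
      state$adapted[soc] <- state$adapted[demo]
    }
  }
  state
}

#' Survival phase
#'
#' Every individual survives independently with probability `s`
#' (non-adapted) or `sigma * s` (adapted), multiplied by
#' `exp(-gamma * N_t)` under mortality regulation (pre-birth census), and by
#' `1 - cost` for juveniles that attempted individual learning this step.
#' Non-survivors are removed; `n_at_risk` and `n_survivors` are recorded for
#' the effective-survival observable.
#'
#' @inheritParams birth_phase
#' @return Updated state containing only survivors.
#' @export
survival_phase <- function(state, config) {
  d <- config$derived
  n <- length(state$age)
  state$n_at_risk <- n
  if (n == 0L) {
    state$n_survivors <- 0L
    return(state)
  }
  n_t <- if (is.na(state$n_census)) density_census(state) else state$n_census
  p <- d$s * (1 + (config$sigma - 1) * state$adapted)
  if (config$mode == "mortality") p <- p * exp(-d$gamma * n_t)
  if (config$cost > 0) p <- p * (1 - config$cost * state$paid_cost)
  alive <- stats::runif(n) < p
  state$n_survivors <- sum(alive)
  state$age <- state$age[alive]
  state$adapted <- state$adapted[alive]
  state$xi <- state$xi[alive]
  state$paid_cost <- state$paid_cost[alive]
  state
}

#' Ageing phase
#'
#' Every survivor's age increments by one (surviving juveniles are recruited
#' into the adult class) and the once-only learning-cost marker is cleared.
#'
#' @param state A `population_state`.
#' @return Updated state.
#' @export
ageing_phase <- function(state) {
  state$age <- state$age + 1L
  if (any(state$paid_cost)) state$paid_cost[] <- FALSE
  state
}

#' Environmental-stochasticity phase
#'
#' With probability `u` the environment switches to a brand-new state: the
#' epoch counter increments, the steps-since-switch clock resets, and every
#' individual's adapted flag is cleared. Because the environment never
#' reverts to an earlier state, a boolean adapted flag fully describes an
#' individual's standing with respect to the current environment.
#'
#' @inheritParams birth_phase
#' @return Updated state with `switched` set.
#' @export
environment_phase <- function(state, config) {
  if (stats::runif(1) < config$u) {
    state$switched <- TRUE
    state$env_epoch <- state$env_epoch + 1L
    state$steps_since_switch <- 0L
    if (any(state$adapted)) state$adapted[] <- FALSE
  } else {
    state$switched <- FALSE
    state$steps_since_switch <- state$steps_since_switch + 1L
  }
  state
}

#' Advance the population by one time step
#'
#' Executes the life cycle in fixed order: pre-birth census, birth and
#' mutation, learning, survival, ageing, environmental stochasticity; then
#' builds the per-step record. Random draws are consumed in this exact
#' phase order (birth Bernoullis, mutation increments, learning-strategy
#' Bernoullis, invention Bernoullis, demonstrator indices, survival
#' Bernoullis, one environment Bernoulli), so a run is a pure function of
#' `(config, seed)`.
#'
#' @inheritParams birth_phase
#' @return A list with elements `state` (the advanced `population_state`)
#'   and `record` (named numeric vector; see [record_step()]).
#' @export
sim_step <- function(state, config) {
  state$t <- state$t + 1L
  state$n_census <- density_census(state)
  n_adults_at_census <- sum(state$age >= 1L)
  state <- birth_phase(state, config)
  state <- learning_phase(state, config)
  state <- survival_phase(state, config)
  state <- ageing_phase(state)
  state <- environment_phase(state, config)
  rec <- record_step(state, n_adults = n_adults_at_census)
  list(state = state, record = rec)
}
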