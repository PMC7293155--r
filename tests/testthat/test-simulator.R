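# Phase-level behaviour, stochastic kernels, and whole-run invariants.

test_that("population initialization is deterministic given the seed", {
  cfg <- small_config(init_n_adults = 500L, init_xi = 0.5)
  set.seed(cfg$seed)
  st <- initialize_population(cfg)
  expect_equal(length(st$age), 500L)
  expect_true(all(st$age == 1L))
  expect_true(all(!st$adapted))
  expect_true(all(st$xi == 0.5))
  cfg_u <- small_config(init_n_adults = 200L)  # uniform xi
  set.seed(99); a <- initialize_population(cfg_u)
  set.seed(99); b <- initialize_population(cfg_u)
  expect_identical(a$xi, b$xi)
  set.seed(100); c3 <- initialize_population(cfg_u)
  expect_false(identical(a$xi, c3$xi))
})

test_that("the mutation kernel is Gaussian with sd mu_xi, clamped to [0, 1]", {
  expect_equal(mutate_xi(c(0, 0.3, 1), 0), c(0, 0.3, 1))
  set.seed(1)
  big <- mutate_xi(rep(1, 1000), 5)
  expect_true(all(big >= 0 & big <= 1))
  expect_true(any(big == 1))  # upward deviations clamp to the boundary
  expect_true(any(big == 0))
  set.seed(2)
  x <- mutate_xi(rep(0.5, 1e5), 0.01)
  se <- 0.01 / sqrt(1e5)
  expect_lt(abs(mean(x) - 0.5), 3 * se)
  expect_lt(abs(sd(x) - 0.01) / 0.01, 0.05)
})

test_that("birth probabilities compose the stated factors", {
  cfg <- sim_config(n_hat = 500, lifespan = 5, delta = 1e-3,
                    mode = "fertility", beta = 1.1, steps = 10, burn_in = 0)
  b <- cfg$derived$b
  n <- 20000L
  st <- make_state(age = rep(1L, n), adapted = rep(TRUE, n), n_census = 500L)
  set.seed(3)
  out <- birth_phase(st, cfg)
  p_expected <- 1.1 * b * exp(-1e-3 * 500)
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(out$n_births / n - p_expected), 4 * se)
  # mortality mode, non-adapted: probability is exactly b (density-free)
  cfg_m <- sim_config(n_hat = 500, lifespan = 5, delta = 1e-3,
                      mode = "mortality", steps = 10, burn_in = 0)
  st2 <- make_state(age = rep(1L, n), n_census = 500L)
  set.seed(4)
  out2 <- birth_phase(st2, cfg_m)
  se_b <- sqrt(b * (1 - b) / n)
  expect_lt(abs(out2$n_births / n - b), 4 * se_b)
  # newborns: age 0, non-adapted, mutated xi in bounds
  expect_true(all(out$age[-(1:n)] == 0L))
  expect_true(all(!out$adapted[-(1:n)]))
  expect_true(all(out$xi >= 0 & out$xi <= 1))
  # no adults, no births
  st3 <- make_state(age = integer(0))
  expect_equal(birth_phase(st3, cfg)$n_births, 0L)
})

test_that("the learning phase follows the individual/social split exactly", {
  cfg <- small_config(w = 1)
  # all juveniles individual learners with perfect invention
  st <- make_state(age = c(rep(1L, 5), rep(0L, 10)),
                   xi = c(rep(0.2, 5), rep(1, 10)))
  set.seed(5)
  out <- learning_phase(st, cfg)
  expect_true(all(out$adapted[out$age == 0L]))
  expect_true(all(out$paid_cost[out$age == 0L]))
  expect_true(all(!out$paid_cost[out$age >= 1L]))
  # pure social learners copy a uniformly adapted pool, paying nothing
  st2 <- make_state(age = c(rep(1L, 5), rep(0L, 10)),
                    adapted = c(rep(TRUE, 5), rep(FALSE, 10)),
                    xi = c(rep(0.2, 5), rep(0, 10)))
  set.seed(6)
  out2 <- learning_phase(st2, cfg)
  expect_true(all(out2$adapted))
  expect_true(all(!out2$paid_cost[out2$age == 0L]))
  # social learning is parasitic: nothing to copy, nothing learned
  st3 <- make_state(age = c(rep(1L, 5), rep(0L, 10)),
                    xi = rep(0, 15))
  set.seed(7)
  out3 <- learning_phase(st3, cfg)
  expect_true(all(!out3$adapted))
  # juveniles without any demonstrator stay non-adapted, event counted
  st4 <- make_state(age = rep(0L, 4), xi = rep(0, 4))
  out4 <- learning_phase(st4, cfg)
  expect_true(all(!out4$adapted))
  expect_equal(out4$orphan_learning_events, 4L)
})

test_that("survival probabilities compose selection, density and learning cost", {
  n <- 20000L
  cfg <- sim_config(n_hat = 500, lifespan = 5, delta = 1e-3,
                    mode = "fertility", sigma = 1.1, cost = 0.05,
                    steps = 10, burn_in = 0)
  # adapted adults under fertility regulation: sigma * s, density-free
  st <- make_state(age = rep(1L, n), adapted = rep(TRUE, n), n_census = 500L)
  set.seed(8)
  out <- survival_phase(st, cfg)
  p <- 1.1 * 0.8
  expect_lt(abs(out$n_survivors / n - p), 4 * sqrt(p * (1 - p) / n))
  # individual-learning juveniles pay the once-only cost
  st2 <- make_state(age = rep(0L, n), paid_cost = rep(TRUE, n),
                    n_census = 500L)
  set.seed(9)
  out2 <- survival_phase(st2, cfg)
  p2 <- 0.8 * 0.95
  expect_lt(abs(out2$n_survivors / n - p2), 4 * sqrt(p2 * (1 - p2) / n))
  # mortality mode with zero census: bare rates apply (e^0 = 1)
  cfg_m <- sim_config(n_hat = 500, lifespan = 5, delta = 1e-3,
                      mode = "mortality", steps = 10, burn_in = 0)
  st3 <- make_state(age = rep(1L, n), n_census = 0L)
  set.seed(10)
  out3 <- survival_phase(st3, cfg_m)
  expect_lt(abs(out3$n_survivors / n - 0.8), 4 * sqrt(0.8 * 0.2 / n))
})

test_that("increasing the learning cost cannot help attempters (coupled draws)", {
  cfg_lo <- small_config(cost = 0.01)
  cfg_hi <- small_config(cost = 0.30)
  st <- make_state(age = rep(0L, 5000), paid_cost = rep(TRUE, 5000),
                   n_census = 200L)
  set.seed(11); lo <- survival_phase(st, cfg_lo)
  set.seed(11); hi <- survival_phase(st, cfg_hi)
  expect_lte(hi$n_survivors, lo$n_survivors)
})

test_that("ageing recruits juveniles and clears the cost marker", {
  st <- make_state(age = c(0L, 0L, 3L), paid_cost = c(TRUE, FALSE, FALSE))
  out <- ageing_phase(st)
  expect_equal(out$age, c(1L, 1L, 4L))
  expect_true(all(!out$paid_cost))
})

test_that("environmental switches reset adaptation and follow the stated rate", {
  cfg1 <- small_config(u = 1)
  st <- make_state(age = rep(2L, 10), adapted = rep(TRUE, 10))
  out <- environment_phase(st, cfg1)
  expect_true(out$switched)
  expect_true(all(!out$adapted))
  expect_equal(out$env_epoch, 1L)
  expect_equal(out$steps_since_switch, 0L)
  cfg0 <- small_config(u = 0)
  out0 <- environment_phase(st, cfg0)
  expect_false(out0$switched)
  expect_equal(out0$env_epoch, 0L)
  # switch count over 10000 steps is binomial around 100 for u = 0.01
  cfg <- small_config(u = 0.01)
  set.seed(12)
  s <- make_state(age = 1L)
  n_sw <- 0L
  for (i in 1:10000) {
    s <- environment_phase(s, cfg)
    n_sw <- n_sw + s$switched
  }
  expect_lt(abs(n_sw - 100), 3 * sqrt(10000 * 0.01 * 0.99))
})

test_that("runs are bit-reproducible and respect the protocol bookkeeping", {
  cfg <- small_config(steps = 400L, burn_in = 150L)
  r1 <- run_sim(cfg)
  r2 <- run_sim(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$records), 400L)
  expect_equal(r1$summary$n_steps_summarized, 250L)
  # a different seed gives a different trajectory
  cfg3 <- small_config(steps = 400L, burn_in = 150L, seed = 77L)
  expect_false(identical(run_sim(cfg3)$records$mean_xi, r1$records$mean_xi))
})

test_that("per-step invariants hold along a stepped trajectory", {
  cfg <- small_config(u = 0.05, steps = 250L, burn_in = 0L)
  set.seed(cfg$seed)
  st <- initialize_population(cfg)
  for (t in 1:250) {
    out <- sim_step(st, cfg)
    st <- out$state
    expect_true(all(st$xi >= 0 & st$xi <= 1))
    # adapted only since the last switch, and only learned at age 0
    if (any(st$adapted)) {
      expect_true(all(st$age[st$adapted] <= st$steps_since_switch))
    }
    if (st$switched) expect_equal(out$record[["prop_adapted"]], 0)
    expect_true(all(!st$paid_cost))
  }
})

test_that("perfect invention without environmental change fixes adaptation", {
  cfg <- small_config(u = 0, w = 1, init_xi = 1, mu_xi = 0,
                      steps = 300L, burn_in = 100L)
  r <- run_sim(cfg)
  post <- r$records[r$records$t > 100, ]
  expect_true(all(post$prop_adapted > 0.95))
  expect_equal(r$summary$n_switches, 0L)
})

test_that("with w = 0 social learning is parasitic and cost selects against xi", {
  cfg <- small_config(w = 0, cost = 0.1, init_xi = 0.5, u = 0.01,
                      steps = 3000L, burn_in = 500L, seed = 5L)
  r <- run_sim(cfg)
  expect_true(all(r$records$prop_adapted == 0))
  expect_lt(tail(r$records$mean_xi, 1), 0.5)
  expect_lt(r$summary$mean_xi_post_burnin, 0.5)
})

test_that("extinction terminates the run with a flag and truncated records", {
  # a tiny founder population under heavy demographic stochasticity
  found <- NULL
  for (sd in 1:20) {
    cfg <- sim_config(n_hat = 4, lifespan = 2.5, delta = 1e-3,
                      mode = "mortality", sigma = 1, beta = 1,
                      u = 0.5, w = 0, cost = 0.1, steps = 400L,
                      burn_in = 300L, seed = sd, init_n_adults = 2L)
    r <- run_sim(cfg)
    if (r$extinct) { found <- r; break }
  }
  expect_false(is.null(found))
  expect_true(found$extinct)
  expect_lt(nrow(found$records), 400L)
  expect_true(found$summary$extinct)
  # extinct before the end of burn-in: no valid summary window
  if (nrow(found$records) <= 300L) {
    expect_true(is.na(found$summary$mean_xi_post_burnin))
  }
})
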