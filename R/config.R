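#' Simulation configuration
#'
#' Builds and validates the complete specification of one individual-based
#' simulation condition: matched demographic parameters, regulation mode,
#' selection multipliers for adapted individuals, environmental change rate,
#' learning parameters, mutation scale and run control. All probability
#' constraints are checked here, before any run starts, so the phase
#' functions can assume valid rates.
#'
#' @param n_hat Target equilibrium population size (> 0). Ignored when
#'   `derived` is supplied.
#' @param lifespan Target expected lifespan in time steps (> 1). Ignored when
#'   `derived` is supplied.
#' @param delta Fertility-regulation strength (> 0). Ignored when `derived`
#'   is supplied.
#' @param mode Regulation mode, `"fertility"` or `"mortality"`.
#' @param sigma Survival multiplier for adapted individuals (>= 1);
#'   `sigma * s` must not exceed 1.
#' @param beta Fertility multiplier for adapted individuals (>= 1);
#'   `beta * b` must not exceed 1.
#' @param u Per-step probability that the environment changes, in \[0, 1\].
#'   The expected time between changes is `1/u`.
#' @param w Probability that an individual-learning attempt invents the
#'   adaptive variant, in \[0, 1\].
#' @param cost Once-only survival cost of attempting individual learning as
#'   a juvenile: survival is multiplied by `1 - cost`. In \[0, 1).
#' @param mu_xi Mutation scale: standard deviation of the Gaussian increment
#'   added to the parental learning propensity xi at birth (>= 0).
#' @param steps Total number of time steps (>= 1).
#' @param burn_in Initial steps excluded from summaries (0 <= burn_in <
#'   steps).
#' @param seed Integer seed for the run's random number stream.
#' @param init_n_adults Initial number of (non-adapted) adults; defaults to
#'   `round(n_hat)`.
#' @param init_xi Either the string `"uniform"` (initial xi drawn uniformly
#'   on \[0, 1\]) or a single number in \[0, 1\] used for every founder.
#' @param record_age If `TRUE` (default), record per-step adaptation by age
#'   class (single-year bins up to `age_bin_max`, then one open bin).
#' @param age_bin_max Largest single-year age bin (default 10).
#' @param derived Optionally a ready-made `derived_params` object; overrides
#'   `n_hat`, `lifespan`, `delta`.
#' @return An object of class `sim_config`.
#' @seealso [run_sim()], [derive_matched_parameters()]
#' @export
#' @examples
#' cfg <- sim_config(n_hat = 500, lifespan = 5, delta = 1e-3,
#'                   mode = "fertility", steps = 1000, burn_in = 200,
#'                   seed = 1)
#' cfg
sim_config <- function(n_hat = 500, lifespan = 5, delta = 1e-3,
                       mode = c("fertility", "mortality"),
                       sigma = 1.1, beta = 1.1,
                       u = 0.01, w = 0.9, cost = 0.05, mu_xi = 0.01,
                       steps = 7000L, burn_in = 2000L, seed = 1L,
                       init_n_adults = NULL, init_xi = "uniform",
                       record_age = TRUE, age_bin_max = 10L,
                       derived = NULL) {
  mode <- match.arg(mode)
  if (is.null(derived)) {
    derived <- derive_matched_parameters(n_hat, lifespan, delta)
  }
  stopifnot(inherits(derived, "derived_params"))
  if (!isTRUE(derived$feasible)) {
    stop("infeasible demographic parameters: ", derived$reason)
  }
  chk_prob <- function(x, nm, open_top = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
        x > 1 || (open_top && x == 1)) {
      stop(nm, " must be a probability in [0, 1", if (open_top) ")" else "]",
           ", got ", x)
    }
  }
  stopifnot(is.numeric(sigma), sigma >= 1, is.numeric(beta), beta >= 1)
  if (sigma * derived$s > 1 + 1e-12) {
    stop(sprintf("sigma * s = %.6f exceeds 1: adapted survival invalid",
                 sigma * derived$s))
  }
  if (beta * derived$b > 1 + 1e-12) {
    stop(sprintf("beta * b = %.6f exceeds 1: adapted fertility invalid",
                 beta * derived$b))
  }
  chk_prob(u, "u"); chk_prob(w, "w"); chk_prob(cost, "cost", open_top = TRUE)
  stopifnot(is.numeric(mu_xi), mu_xi >= 0)
  steps <- as.integer(steps); burn_in <- as.integer(burn_in)
  stopifnot(steps >= 1L, burn_in >= 0L, burn_in < steps)
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  if (is.null(init_n_adults)) init_n_adults <- as.integer(round(derived$n_hat))
  init_n_adults <- as.integer(init_n_adults)
  if (init_n_adults <= 0L) stop("init_n_adults must be a positive integer")
  if (is.character(init_xi)) {
    if (!identical(init_xi, "uniform")) {
      stop("init_xi must be \"uniform\" or a number in [0, 1]")
    }
  } else {
    chk_prob(init_xi, "init_xi")
  }
  structure(list(derived = derived, mode = mode, sigma = sigma, beta = beta,
                 u = u, w = w, cost = cost, mu_xi = mu_xi,
                 steps = steps, burn_in = burn_in, seed = seed,
                 init_n_adults = init_n_adults, init_xi = init_xi,
                 record_age = isTRUE(record_age),
                 age_bin_max = as.integer(age_bin_max)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  d <- x$derived
  cat("Social-learning simulation configuration\n")
  cat(sprintf("  regulation mode  : %s\n", x$mode))
  cat(sprintf("  N^ = %g, L^ = %g (s = %.4f, b = %.4f, delta = %.4g, gamma = %.4g)\n",
              d$n_hat, d$lifespan, d$s, d$b, d$delta, d$gamma))
  cat(sprintf("  selection        : sigma = %g, beta = %g\n", x$sigma, x$beta))
  cat(sprintf("  learning         : w = %g, cost = %g, mu_xi = %g\n",
              x$w, x$cost, x$mu_xi))
  cat(sprintf("  environment      : u = %g (expected %g steps between changes)\n",
              x$u, if (x$u > 0) 1 / x$u else Inf))
  cat(sprintf("  run              : %d steps, burn-in %d, seed %d, %d founders\n",
              x$steps, x$burn_in, x$seed, x$init_n_adults))
  invisible(x)
}
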