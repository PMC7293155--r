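#' Ricker map parameters
#'
#' Bundle of parameters for the discrete-time logistic (Ricker) map
#' \eqn{N_{t+1} = N_t e^{r(1 - N_t/K)}}, the reference single-class model of
#' density-dependent population growth from which the two-age-class models in
#' this package are developed.
#'
#' @param r Per-step intrinsic growth rate.
#' @param K Carrying capacity; must be strictly positive.
#' @return An object of class `ricker_params`.
#' @seealso [ricker_step()]
#' @export
#' @examples
#' p <- ricker_params(r = 0.5, K = 100)
#' ricker_step(50, p)
ricker_params <- function(r, K) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L, is.finite(K))
  if (K <= 0) stop("carrying capacity K must be > 0, got ", K)
  structure(list(r = r, K = K), class = "ricker_params")
}

#' One step of the Ricker map
#'
#' @param n Current population size (non-negative).
#' @param params A [ricker_params()] object.
#' @return Population size after one step, `n * exp(r * (1 - n / K))`.
#' @export
ricker_step <- function(n, params) {
  stopifnot(inherits(params, "ricker_params"), is.numeric(n), all(n >= 0))
  n * exp(params$r * (1 - n / params$K))
}

#' Per-step survival implied by an expected lifespan
#'
#' Lifetimes are geometric on \{1, 2, ...\}: an individual that is alive at a
#' census survives to the next one with probability `s`, so the expected
#' number of time steps lived is \eqn{1/(1-s)}. Inverting gives
#' \eqn{s = 1 - 1/\hat{L}}. Expected lifespans of 3, 5 and 7.5 steps
#' correspond to s = 0.666..., 0.8 and 0.866... respectively.
#'
#' @param lifespan Target expected lifespan in time steps; must exceed 1
#'   (a lifespan of 1 or less would imply non-positive survival).
#' @return Per-step baseline survival probability in (0, 1).
#' @seealso [lifespan_from_survival()]
#' @export
#' @examples
#' survival_from_lifespan(5)    # 0.8
#' survival_from_lifespan(7.5)  # 0.8666...
survival_from_lifespan <- function(lifespan) {
  stopifnot(is.numeric(lifespan), all(is.finite(lifespan)))
  if (any(lifespan <= 1)) {
    stop("expected lifespan must be > 1 time step (got ",
         paste(lifespan[lifespan <= 1], collapse = ", "),
         "); per-step survival would be <= 0")
  }
  1 - 1 / lifespan
}

#' Expected lifespan implied by a per-step survival probability
#'
#' Inverse of [survival_from_lifespan()]: under the geometric-lifetime
#' convention the expected lifespan is \eqn{1/(1-s)} time steps.
#'
#' @param s Per-step survival probability, strictly inside (0, 1).
#' @return Expected lifespan in time steps.
#' @export
#' @examples
#' lifespan_from_survival(2 / 3)  # 3
lifespan_from_survival <- function(s) {
  stopifnot(is.numeric(s), all(is.finite(s)))
  if (any(s <= 0 | s >= 1)) stop("survival probability must lie in (0, 1)")
  1 / (1 - s)
}

#' Closed-form equilibrium population size under fertility regulation
#'
#' With density acting only on fertility (per-adult birth probability
#' \eqn{b e^{-\delta N}}) and density-independent survival `s`, the total
#' equilibrium size is \eqn{\hat{N} = \log(bs/(1-s))/\delta}.
#'
#' A non-positive value means the population is not viable at low density
#' (\eqn{bs \le 1-s}) and there is no positive equilibrium; the value is
#' returned as-is with a warning so infeasible parameter sets fail loudly.
#'
#' @param s Baseline per-step survival in (0, 1).
#' @param b Baseline per-step birth probability, > 0.
#' @param delta Fertility-regulation strength, > 0.
#' @return Equilibrium total population size (possibly non-positive; see
#'   Details).
#' @export
fertility_equilibrium <- function(s, b, delta) {
  stopifnot(s > 0, s < 1, b > 0, delta > 0)
  n_hat <- log(b * s / (1 - s)) / delta
  if (any(n_hat <= 0)) {
    warning("no positive equilibrium under fertility regulation: b*s <= 1-s")
  }
  n_hat
}

#' Closed-form equilibrium population size under mortality regulation
#'
#' With density acting only on survival (per-individual survival
#' \eqn{s e^{-\gamma N}}) and density-independent fertility `b`, the total
#' equilibrium size is \eqn{\hat{N} = \log(s(1+b))/\gamma}.
#'
#' @inheritParams fertility_equilibrium
#' @param gamma Mortality-regulation strength, > 0.
#' @return Equilibrium total population size; non-positive (with a warning)
#'   when \eqn{s(1+b) \le 1}, i.e. when no positive equilibrium exists.
#' @export
mortality_equilibrium <- function(s, b, gamma) {
  stopifnot(s > 0, s < 1, b > 0, gamma > 0)
  n_hat <- log(s * (1 + b)) / gamma
  if (any(n_hat <= 0)) {
    warning("no positive equilibrium under mortality regulation: s*(1+b) <= 1")
  }
  n_hat
}

#' Baseline fertility that yields a target equilibrium under fertility
#' regulation
#'
#' Inverts the fertility-regulated equilibrium formula:
#' \eqn{b = \frac{1-s}{s} e^{\delta \hat{N}}}. The result must be a valid
#' probability; `b >= 1` signals an infeasible (target size, lifespan,
#' regulation strength) combination and is rejected.
#'
#' @param s Baseline per-step survival in (0, 1).
#' @param delta Fertility-regulation strength, > 0.
#' @param n_hat Target equilibrium population size, > 0.
#' @return Baseline per-step birth probability in (0, 1).
#' @export
#' @examples
#' derive_fertility_rate(s = 0.8, delta = 1e-3, n_hat = 500)  # ~0.41218
derive_fertility_rate <- function(s, delta, n_hat) {
  stopifnot(s > 0, s < 1, delta > 0, n_hat > 0)
  b <- (1 - s) / s * exp(delta * n_hat)
  if (b >= 1) {
    stop(sprintf(paste0(
      "infeasible target: derived fertility b = %.6f >= 1 for ",
      "s = %.6f, delta = %.6g, n_hat = %g; ",
      "no valid birth probability reaches this equilibrium"),
      b, s, delta, n_hat))
  }
  b
}

#' Mortality-regulation strength that yields a target equilibrium
#'
#' Inverts the mortality-regulated equilibrium formula:
#' \eqn{\gamma = \log(s(1+b))/\hat{N}}. Requires \eqn{s(1+b) > 1}
#' (population viable at low density), otherwise no positive equilibrium
#' exists for any \eqn{\gamma}.
#'
#' @param s Baseline per-step survival in (0, 1).
#' @param b Baseline per-step birth probability, > 0.
#' @param n_hat Target equilibrium population size, > 0.
#' @return Mortality-regulation strength gamma, > 0.
#' @export
derive_gamma <- function(s, b, n_hat) {
  stopifnot(s > 0, s < 1, b > 0, n_hat > 0)
  if (s * (1 + b) <= 1) {
    stop(sprintf(paste0(
      "infeasible target: s*(1+b) = %.6f <= 1 for s = %.6f, b = %.6f; ",
      "no positive mortality-regulated equilibrium exists"),
      s * (1 + b), s, b))
  }
  log(s * (1 + b)) / n_hat
}

#' Target life-history specification
#'
#' Validated bundle of the three quantities from which a matched parameter
#' set is derived: target equilibrium population size, expected lifespan and
#' fertility-regulation strength.
#'
#' @param n_hat Target equilibrium population size, > 0.
#' @param lifespan Target expected lifespan in time steps, > 1.
#' @param delta Fertility-regulation strength, > 0.
#' @return An object of class `life_history_spec`.
#' @export
life_history_spec <- function(n_hat, lifespan, delta) {
  stopifnot(is.numeric(n_hat), length(n_hat) == 1L, is.finite(n_hat),
            is.numeric(lifespan), length(lifespan) == 1L, is.finite(lifespan),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (n_hat <= 0) stop("n_hat must be > 0")
  if (lifespan <= 1) stop("lifespan must be > 1 time step")
  if (delta <= 0) stop("delta must be > 0")
  structure(list(n_hat = n_hat, lifespan = lifespan, delta = delta),
            class = "life_history_spec")
}

#' Derive a matched vital-rate parameter set from demographic targets
#'
#' The controlled-comparison device at the heart of the package: given a
#' target equilibrium size, expected lifespan and fertility-regulation
#' strength, derive baseline survival `s` (from the lifespan), baseline
#' fertility `b` (by inverting the fertility-regulated equilibrium) and the
#' mortality-regulation strength `gamma` (by inverting the
#' mortality-regulated equilibrium with the same `s` and `b`). The two
#' regulation modes then share identical baseline vital rates and an
#' identical analytic equilibrium size, so any difference between simulated
#' populations is attributable to the mode of regulation alone.
#'
#' @param spec A [life_history_spec()], or a target size `n_hat` if
#'   `lifespan` and `delta` are supplied directly.
#' @param lifespan,delta Convenience scalar arguments, used when `spec` is
#'   numeric.
#' @param strict If `TRUE` (default) an infeasible combination (derived
#'   `b >= 1`) is an error; if `FALSE` a `derived_params` object with
#'   `feasible = FALSE` and a `reason` field is returned, for grid builders
#'   that must report rather than fail.
#' @return An object of class `derived_params`: list with elements `s`, `b`,
#'   `delta`, `gamma`, `n_hat`, `lifespan`, `feasible` (and `reason` when
#'   infeasible).
#' @export
#' @examples
#' derive_matched_parameters(n_hat = 500, lifespan = 5, delta = 1e-3)
derive_matched_parameters <- function(spec = NULL, lifespan = NULL,
                                      delta = NULL, strict = TRUE,
                                      n_hat = NULL) {
  if (is.null(spec)) spec <- n_hat
  if (inherits(spec, "life_history_spec")) {
    lh <- spec
  } else {
    lh <- life_history_spec(spec, lifespan, delta)
  }
  s <- survival_from_lifespan(lh$lifespan)
  b <- tryCatch(derive_fertility_rate(s, lh$delta, lh$n_hat),
                error = function(e) e)
  if (inherits(b, "error")) {
    if (strict) stop(b)
    return(structure(list(s = s, b = NA_real_, delta = lh$delta,
                          gamma = NA_real_, n_hat = lh$n_hat,
                          lifespan = lh$lifespan, feasible = FALSE,
                          reason = conditionMessage(b)),
                     class = "derived_params"))
  }
  gamma <- derive_gamma(s, b, lh$n_hat)  # always feasible once b > (1-s)/s
  structure(list(s = s, b = b, delta = lh$delta, gamma = gamma,
                 n_hat = lh$n_hat, lifespan = lh$lifespan, feasible = TRUE),
            class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat("Matched demographic parameters\n")
  cat(sprintf("  target equilibrium size N^ : %g\n", x$n_hat))
  cat(sprintf("  expected lifespan L^       : %g steps\n", x$lifespan))
  if (!x$feasible) {
    cat("  INFEASIBLE:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  baseline survival s        : %.6f\n", x$s))
  cat(sprintf("  baseline fertility b       : %.6f\n", x$b))
  cat(sprintf("  fertility regulation delta : %.6g\n", x$delta))
  cat(sprintf("  mortality regulation gamma : %.6g\n", x$gamma))
  invisible(x)
}

#' Iterate the two-age-class demographic recursion
#'
#' Deterministic forward iteration of the juvenile/adult recursion under one
#' of the two pure regulation modes. Writing \eqn{N_t = N_{0,t} + N_{1,t}}
#' for the total:
#' \describe{
#'   \item{fertility}{\eqn{N_{0,t+1} = N_{1,t}\, b\, e^{-\delta N_t}},
#'     \eqn{N_{1,t+1} = (N_{0,t} + N_{1,t})\, s}}
#'   \item{mortality}{\eqn{N_{0,t+1} = N_{1,t}\, b},
#'     \eqn{N_{1,t+1} = (N_{0,t} + N_{1,t})\, s\, e^{-\gamma N_t}}}
#' }
#' After a transient, the total converges to the closed-form equilibrium
#' returned by [fertility_equilibrium()] / [mortality_equilibrium()] whenever
#' a positive one exists, with equilibrium age ratios
#' \eqn{N_0/N_1 = (1-s)/s} (fertility mode) and \eqn{N_0/N_1 = b}
#' (mortality mode).
#'
#' @param params A `derived_params` object (see
#'   [derive_matched_parameters()]).
#' @param mode `"fertility"` or `"mortality"`.
#' @param n0_init,n1_init Initial juvenile and adult counts (non-negative).
#' @param steps Number of steps to iterate, >= 1.
#' @return A data frame of class `age_trajectory` with columns `time`
#'   (0..steps), `n0`, `n1` and `total`.
#' @export
#' @examples
#' d <- derive_matched_parameters(n_hat = 500, lifespan = 5, delta = 1e-3)
#' tr <- iterate_recursion(d, "fertility", n0_init = 10, n1_init = 10,
#'                         steps = 500)
#' tail(tr$total, 1)  # ~500
iterate_recursion <- function(params, mode = c("fertility", "mortality"),
                              n0_init, n1_init, steps) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "derived_params"), isTRUE(params$feasible),
            n0_init >= 0, n1_init >= 0, steps >= 1)
  s <- params$s; b <- params$b
  n0 <- numeric(steps + 1L); n1 <- numeric(steps + 1L)
  n0[1L] <- n0_init; n1[1L] <- n1_init
  if (mode == "fertility") {
    delta <- params$delta
    for (t in seq_len(steps)) {
      tot <- n0[t] + n1[t]
      n0[t + 1L] <- n1[t] * b * exp(-delta * tot)
      n1[t + 1L] <- tot * s
    }
  } else {
    gamma <- params$gamma
    for (t in seq_len(steps)) {
      tot <- n0[t] + n1[t]
      n0[t + 1L] <- n1[t] * b
      n1[t + 1L] <- tot * s * exp(-gamma * tot)
    }
  }
  structure(data.frame(time = 0:steps, n0 = n0, n1 = n1, total = n0 + n1),
            class = c("age_trajectory", "data.frame"), mode = mode)
}

#' Analytic equilibrium for a matched parameter set
#'
#' Convenience dispatcher over [fertility_equilibrium()] and
#' [mortality_equilibrium()]; by construction of
#' [derive_matched_parameters()] both modes return the same target size.
#'
#' @inheritParams iterate_recursion
#' @return Equilibrium total population size.
#' @export
equilibrium_size <- function(params, mode = c("fertility", "mortality")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "derived_params"), isTRUE(params$feasible))
  if (mode == "fertility") {
    fertility_equilibrium(params$s, params$b, params$delta)
  } else {
    mortality_equilibrium(params$s, params$b, params$gamma)
  }
}
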