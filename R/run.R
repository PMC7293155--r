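#' Run one individual-based simulation
#'
#' The package's central function: seeds the random number stream, founds
#' the population, iterates the life cycle (birth and mutation, learning,
#' survival and ageing, environmental stochasticity) for `config$steps`
#' steps, and returns the per-step records together with a post-burn-in
#' summary. The run is a pure function of the configuration (including its
#' seed): the same `sim_config` always produces bit-identical records.
#'
#' If the population dies out, the run terminates early with the `extinct`
#' flag set and truncated records; summaries over an unreachable window are
#' `NA` rather than an error, so parameter sweeps can report extinction
#' rates.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sl_run`: list with elements
#'   \describe{
#'     \item{records}{data frame, one row per completed step (see
#'       [record_step()])}
#'     \item{summary}{a `run_summary` (see [summarize_run()])}
#'     \item{config}{the configuration}
#'     \item{extinct}{logical}
#'     \item{age_adapted, age_total}{(if `config$record_age`) integer
#'       matrices, steps x age bins, of adapted and total counts per age
#'       class at each step end}
#'     \item{final_state}{the terminal `population_state`}
#'   }
#' @seealso [sim_config()], [summarize_run()], [plot.sl_run()]
#' @export
#' @examples
#' cfg <- sim_config(n_hat = 200, lifespan = 5, delta = 1e-3,
#'                   mode = "fertility", steps = 300, burn_in = 100,
#'                   seed = 42)
#' fit <- run_sim(cfg)
#' summary(fit)
run_sim <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- initialize_population(config)
  steps <- config$steps
  rec <- matrix(NA_real_, nrow = steps, ncol = length(step_record_fields),
                dimnames = list(NULL, step_record_fields))
  bmax <- config$age_bin_max
  if (config$record_age) {
    age_ad <- matrix(0L, nrow = steps, ncol = bmax + 2L)
    age_tot <- matrix(0L, nrow = steps, ncol = bmax + 2L)
    colnames(age_ad) <- colnames(age_tot) <-
      c(as.character(0:bmax), paste0(bmax + 1L, "+"))
  }
  extinct <- FALSE
  last <- 0L
  for (t in seq_len(steps)) {
    if (density_census(state) == 0L) {
      extinct <- TRUE
      break
    }
    out <- sim_step(state, config)
    state <- out$state
    rec[t, ] <- out$record
    if (config$record_age) {
      cnt <- age_bin_counts(state, bmax)
      age_ad[t, ] <- cnt$adapted
      age_tot[t, ] <- cnt$total
    }
    last <- t
  }
  if (last > 0L && rec[last, "flag_empty"] == 1) extinct <- TRUE
  records <- as.data.frame(rec[seq_len(last), , drop = FALSE])
  res <- list(
    records = records,
    summary = summarize_run(records, config$burn_in, extinct = extinct),
    config = config,
    extinct = extinct,
    final_state = state
  )
  if (config$record_age) {
    res$age_adapted <- age_ad[seq_len(last), , drop = FALSE]
    res$age_total <- age_tot[seq_len(last), , drop = FALSE]
  }
  structure(res, class = "sl_run")
}

#' @export
print.sl_run <- function(x, ...) {
  d <- x$config$derived
  cat(sprintf("<sl_run> %s regulation, N^ = %g, L^ = %g, %d/%d steps%s\n",
              x$config$mode, d$n_hat, d$lifespan, nrow(x$records),
              x$config$steps, if (x$extinct) " (EXTINCT)" else ""))
  s <- x$summary
  if (!is.na(s$mean_xi_post_burnin)) {
    cat(sprintf("  post-burn-in mean xi %.4f, mean census %.1f, prop. adapted %.4f\n",
                s$mean_xi_post_burnin, s$mean_census_post_burnin,
                s$mean_prop_adapted))
  }
  invisible(x)
}

#' @export
summary.sl_run <- function(object, ...) {
  object$summary
}

#' Plot a simulation run
#'
#' Base-graphics four-panel view of a run: population census with the
#' analytic equilibrium of the neutral demographic model, proportion
#' adapted, mean learning propensity xi, and the effective vital rates.
#' Environment switches are drawn as dashed vertical lines.
#'
#' @param x An `sl_run` object.
#' @param from,to Step range to display (defaults to the whole run).
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.sl_run <- function(x, from = 1L, to = nrow(x$records), ...) {
  r <- x$records
  r <- r[r$t >= from & r$t <= to, , drop = FALSE]
  sw <- r$t[r$switched == 1]
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(op))
  mark <- function() if (length(sw)) graphics::abline(v = sw, lty = 2,
                                                      col = "grey60")
  graphics::plot(r$t, r$n_census, type = "l", xlab = "", ylab = "census N")
  graphics::abline(h = x$config$derived$n_hat, col = "red", lty = 3)
  mark()
  graphics::plot(r$t, r$prop_adapted, type = "l", ylim = c(0, 1),
                 xlab = "", ylab = "prop. adapted")
  mark()
  graphics::plot(r$t, r$mean_xi, type = "l", ylim = c(0, 1),
                 xlab = "", ylab = "mean xi")
  mark()
  graphics::plot(r$t, r$eff_survival, type = "l", ylim = c(0, 1),
                 xlab = "time step", ylab = "effective rates", col = "darkgreen")
  graphics::lines(r$t, r$eff_fertility, col = "purple")
  graphics::legend("bottomright", c("survival", "fertility"), lty = 1,
                   col = c("darkgreen", "purple"), bty = "n", cex = 0.8)
  mark()
  invisible(x)
}
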