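# Per-step measurement and post-run summarization. Effective vital rates are
# realized ratios (events / individuals at risk) per step, not expectations;
# averaged over steps and replicates they estimate the actual per-individual
# probabilities of reproducing and surviving at each point in time.

step_record_fields <- c(
  "t", "n_census", "n_adults", "n_births", "n_at_risk", "n_survivors",
  "prop_adapted", "mean_xi", "eff_fertility", "eff_survival",
  "switched", "env_epoch", "flag_no_adults", "flag_empty"
)

#' Build the per-step record
#'
#' Called once per simulator step, after the environment phase, with the
#' counts captured at the phase boundaries: `n_census` and `n_adults` from
#' the pre-birth census, `n_births` from the birth phase, `n_at_risk` and
#' `n_survivors` from the survival phase. End-of-step fields
#' (`prop_adapted`, `mean_xi`) are computed over all individuals alive after
#' ageing and environmental change, so a step in which the environment
#' switched reports `prop_adapted = 0`.
#'
#' Division guards: with no adults, `eff_fertility` is 0 and
#' `flag_no_adults` is set; with an empty end-of-step population,
#' `prop_adapted` and `mean_xi` are 0 and `flag_empty` is set.
#'
#' @param state A `population_state` as left by [environment_phase()].
#' @param n_adults Number of adults at the pre-birth census.
#' @return Named numeric vector with fields `t`, `n_census`, `n_adults`,
#'   `n_births`, `n_at_risk`, `n_survivors`, `prop_adapted`, `mean_xi`,
#'   `eff_fertility` (births per adult), `eff_survival` (survivors per
#'   individual at risk), `switched`, `env_epoch`, `flag_no_adults`,
#'   `flag_empty`.
#' @export
record_step <- function(state, n_adults) {
  n_end <- length(state$age)
  empty <- n_end == 0L
  no_adults <- n_adults == 0L
  c(t = as.numeric(state$t),
    n_census = as.numeric(state$n_census),
    n_adults = as.numeric(n_adults),
    n_births = as.numeric(state$n_births),
    n_at_risk = as.numeric(state$n_at_risk),
    n_survivors = as.numeric(state$n_survivors),
    prop_adapted = if (empty) 0 else mean(state$adapted),
    mean_xi = if (empty) 0 else mean(state$xi),
    eff_fertility = if (no_adults) 0 else state$n_births / n_adults,
    eff_survival = if (state$n_at_risk == 0L) 0 else
      state$n_survivors / state$n_at_risk,
    switched = as.numeric(state$switched),
    env_epoch = as.numeric(state$env_epoch),
    flag_no_adults = as.numeric(no_adults),
    flag_empty = as.numeric(empty))
}

#' Fraction adapted per age class
#'
#' Bins individuals by age (single-year bins up to `bin_max`, then one open
#' bin) and reports the fraction adapted in each non-empty bin. Empty bins
#' are absent from the result, not reported as zero.
#'
#' @param state A `population_state`.
#' @param bin_max Largest single-year age bin (default 10).
#' @return Named numeric vector of fractions for non-empty bins, names
#'   `"0"`, `"1"`, ..., `"<bin_max>"`, `"<bin_max+1>+"`.
#' @export
adaptation_by_age <- function(state, bin_max = 10L) {
  bin_max <- as.integer(bin_max)
  if (length(state$age) == 0L) return(stats::setNames(numeric(0), character(0)))
  bins <- pmin(state$age, bin_max + 1L)
  tot <- tabulate(bins + 1L, nbins = bin_max + 2L)
  ad <- tabulate(bins[state$adapted] + 1L, nbins = bin_max + 2L)
  labs <- c(as.character(0:bin_max), paste0(bin_max + 1L, "+"))
  keep <- tot > 0L
  stats::setNames((ad / tot)[keep], labs[keep])
}

# Internal: age-binned adapted/total counts as a fixed-width integer vector
# pair, used by run_sim to accumulate per-step matrices.
age_bin_counts <- function(state, bin_max) {
  bins <- pmin(state$age, bin_max + 1L)
  list(total = tabulate(bins + 1L, nbins = bin_max + 2L),
       adapted = tabulate(bins[state$adapted] + 1L, nbins = bin_max + 2L))
}

#' Summarize a run over its post-burn-in steps
#'
#' Time-averages the per-step records over steps `t > burn_in`. For the
#' effective vital rates, guarded steps (no adults / empty population) are
#' excluded from the average. A run that went extinct before the end of the
#' burn-in has no valid summary window and reports `NA` averages with the
#' extinct flag set.
#'
#' @param records Data frame of per-step records (see [record_step()]),
#'   possibly truncated by extinction.
#' @param burn_in Number of initial steps to discard; must be smaller than
#'   the number of steps originally requested.
#' @param extinct Logical: did the run end in extinction?
#' @return An object of class `run_summary`: list with
#'   `mean_xi_post_burnin`, `mean_census_post_burnin`, `mean_prop_adapted`,
#'   `mean_eff_fertility`, `mean_eff_survival`, `n_switches` (whole run),
#'   `n_steps_summarized`, `extinct`.
#' @export
summarize_run <- function(records, burn_in, extinct = FALSE) {
  stopifnot(is.data.frame(records), burn_in >= 0)
  post <- records[records$t > burn_in, , drop = FALSE]
  n_post <- nrow(post)
  if (!extinct && n_post == 0L) {
    stop("burn_in (", burn_in, ") leaves no steps to summarize")
  }
  avg <- function(x) if (n_post == 0L) NA_real_ else mean(x)
  rate_avg <- function(x, flag) {
    ok <- flag == 0
    if (n_post == 0L || !any(ok)) NA_real_ else mean(x[ok])
  }
  structure(list(
    mean_xi_post_burnin = avg(post$mean_xi),
    mean_census_post_burnin = avg(post$n_census),
    mean_prop_adapted = avg(post$prop_adapted),
    mean_eff_fertility = if (n_post == 0L) NA_real_ else
      rate_avg(post$eff_fertility, post$flag_no_adults),
    mean_eff_survival = if (n_post == 0L) NA_real_ else
      rate_avg(post$eff_survival, as.numeric(post$n_at_risk == 0)),
    n_switches = as.integer(sum(records$switched)),
    n_steps_summarized = n_post,
    extinct = isTRUE(extinct)
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Run summary (", x$n_steps_summarized, " post-burn-in steps)\n",
      sep = "")
  if (x$extinct) cat("  population went EXTINCT\n")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("  mean xi            :", fmt(x$mean_xi_post_burnin), "\n")
  cat("  mean census        :", fmt(x$mean_census_post_burnin), "\n")
  cat("  mean prop. adapted :", fmt(x$mean_prop_adapted), "\n")
  cat("  mean eff. fertility:", fmt(x$mean_eff_fertility), "\n")
  cat("  mean eff. survival :", fmt(x$mean_eff_survival), "\n")
  cat("  environment switches:", x$n_switches, "\n")
  invisible(x)
}

#' Aggregate replicate summaries by condition
#'
#' Collapses a replicate-level summary table (as produced by
#' [run_replicates()] or [run_sweep()]) to one row per condition: replicate
#' counts, extinction rate, and mean and standard deviation of each summary
#' statistic over non-extinct replicates. Replicate-level rows are the
#' input and remain available; this function only adds the condition-level
#' view. Results are invariant to replicate ordering.
#'
#' @param summaries Data frame with a `condition_id` column, an `extinct`
#'   column and the numeric summary columns.
#' @return Data frame with one row per condition.
#' @export
aggregate_replicates <- function(summaries) {
  stopifnot(is.data.frame(summaries), "condition_id" %in% names(summaries))
  stats_cols <- intersect(
    c("mean_xi_post_burnin", "mean_census_post_burnin", "mean_prop_adapted",
      "mean_eff_fertility", "mean_eff_survival"),
    names(summaries))
  ids <- unique(summaries$condition_id)
  rows <- lapply(ids, function(id) {
    sub <- summaries[summaries$condition_id == id, , drop = FALSE]
    ok <- !sub$extinct
    out <- list(condition_id = id,
                n_replicates = nrow(sub),
                n_extinct = sum(!ok),
                extinction_rate = mean(!ok))
    for (cl in stats_cols) {
      v <- sub[[cl]][ok]
      out[[paste0(cl, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(cl, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Switch-aligned averages of per-step observables
#'
#' Aligns the per-step records on environment switches and averages each
#' observable at each offset across switches, exposing the post-switch
#' dynamics of adaptation, birth numbers and effective vital rates (the
#' birth-timing signature that distinguishes the two regulation modes).
#' Windows that begin inside the burn-in, run past the end of the record,
#' or contain another switch are discarded.
#'
#' @param records Per-step record data frame.
#' @param window Integer vector `c(before, after)` of offsets relative to
#'   the switch step (default `c(-10, 100)`).
#' @param burn_in Steps to exclude at the start (default 0).
#' @param vars Observable columns to average.
#' @return Data frame with column `offset` and one column per observable;
#'   attribute `n_windows` gives the number of switches averaged. `NULL`
#'   if no complete window exists.
#' @export
switch_aligned <- function(records, window = c(-10L, 100L), burn_in = 0L,
                           vars = c("prop_adapted", "n_births",
                                    "eff_fertility", "eff_survival")) {
  stopifnot(length(window) == 2L, window[1] <= 0L, window[2] >= 0L)
  vars <- intersect(vars, names(records))
  switch_t <- records$t[records$switched == 1]
  t_min <- min(records$t); t_max <- max(records$t)
  offs <- seq.int(window[1], window[2])
  keep <- vapply(switch_t, function(st) {
    lo <- st + window[1]; hi <- st + window[2]
    if (lo <= burn_in || lo < t_min || hi > t_max) return(FALSE)
    sum(switch_t >= lo & switch_t <= hi) == 1L  # only the aligning switch
  }, logical(1))
  switch_t <- switch_t[keep]
  if (length(switch_t) == 0L) return(NULL)
  # records$t is 1..n contiguous (possibly truncated); index directly
  idx0 <- match(switch_t, records$t)
  acc <- matrix(0, nrow = length(offs), ncol = length(vars),
                dimnames = list(NULL, vars))
  for (i in idx0) {
    acc <- acc + as.matrix(records[i + offs - 0L, vars, drop = FALSE])
  }
  out <- data.frame(offset = offs, acc / length(switch_t))
  attr(out, "n_windows") <- length(switch_t)
  out
}
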