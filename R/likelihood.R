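#' Integrated branching intensity
#'
#' Computes \eqn{\int_0^{T} N(t)\,\lambda(t)\,dt} for a rate model over a
#' chronogram, where `N(t)` is the reconstructed lineage count and `T` the
#' root age. For the constant, piecewise and covariate families the rate is
#' constant between the union of branching times and epoch boundaries, so the
#' integral is evaluated exactly by piecewise bookkeeping. The logistic
#' sigmoid has the exact antiderivative `softplus(a t + b)/a`, so that family
#' is also integrated analytically, segment by segment between branching
#' events.
#'
#' @param model a rate model, see [rate_constant()].
#' @param tree a [chronogram].
#' @return a single number (expected event count).
#' @export
integrated_intensity <- function(model, tree) UseMethod("integrated_intensity")

#' @export
integrated_intensity.rate_constant <- function(model, tree) {
  stopifnot(inherits(tree, "chronogram"))
  model$lambda * total_branch_length(tree)
}

#' @export
integrated_intensity.rate_piecewise <- function(model, tree) {
  stopifnot(inherits(tree, "chronogram"))
  bnd <- c(tree$root_age, model$breakpoints, 0)   # ages, oldest first
  Xs <- lineage_time_below(tree, bnd)
  L <- Xs[-length(Xs)] - Xs[-1]                   # per-epoch lineage time
  sum(model$rates * L)
}

#' @export
integrated_intensity.rate_covariate <- function(model, tree) {
  stopifnot(inherits(tree, "chronogram"))
  X <- total_branch_length(tree)
  Lh <- high_stand_lineage_time(model$intervals, tree)
  model$lambda_high * Lh + model$lambda_low * (X - Lh)
}

#' @export
integrated_intensity.rate_logistic <- function(model, tree) {
  stopifnot(inherits(tree, "chronogram"))
  ts <- sort(tree$root_age - tree$event_ages_all)  # event times, ascending
  lo <- ts
  hi <- c(ts[-1], tree$root_age)
  nseg <- 1 + seq_along(ts)                        # N(t) on each segment
  sum(nseg * logistic_integral(model$a, model$b, lo, hi))
}

# Exact integral of plogis(a t + b) over [t1, t2], vectorised.
logistic_integral <- function(a, b, t1, t2) {
  if (a == 0) return(stats::plogis(b) * (t2 - t1))
  (softplus(a * t2 + b) - softplus(a * t1 + b)) / a
}

# Lineage time spent inside the high-stand intervals (clamped to the tree).
high_stand_lineage_time <- function(intervals, tree) {
  if (nrow(intervals) == 0) return(0)
  s <- pmin(intervals$start_age, tree$root_age)
  e <- pmax(intervals$end_age, 0)
  keep <- s > e
  if (!any(keep)) return(0)
  sum(lineage_time_below(tree, s[keep]) - lineage_time_below(tree, e[keep]))
}

# Non-root events falling in the high-stand intervals.
high_stand_events <- function(intervals, tree) {
  if (nrow(intervals) == 0) return(0L)
  s <- pmin(intervals$start_age, tree$root_age)
  e <- pmax(intervals$end_age, 0)
  keep <- s > e
  if (!any(keep)) return(0L)
  sum(events_below(tree, s[keep]) - events_below(tree, e[keep]))
}

#' Time-dependent pure-birth (Yule) log-likelihood
#'
#' Log-likelihood of a chronogram under a pure-birth process with
#' time-varying speciation rate \eqn{\lambda(t)}:
#' \deqn{\log L = \sum_i \log \lambda(t_i) - \int_0^{T} N(t) \lambda(t) dt
#'   + \log (n-1)!}
#' where the sum runs over the non-root branching events (the process is
#' conditioned on the root split, which carries no rate factor) and the
#' \eqn{\log (n-1)!} term counts the labelled histories, matching the
#' convention of `ape`'s Yule fitters so absolute values are comparable.
#' Returns `-Inf` if any event falls where the rate is zero.
#'
#' @param model a rate model, see [rate_constant()].
#' @param tree a [chronogram] with at least 3 tips.
#' @return the log-likelihood (a single number, possibly `-Inf`).
#' @examples
#' toy <- read_chronogram("((A:1,B:1):1,C:2);")
#' yule_time_loglik(rate_constant(0.2), toy)  # log(0.2) - 1 + log(2)
#' @export
yule_time_loglik <- function(model, tree) {
  stopifnot(inherits(tree, "chronogram"), inherits(model, "rate_model"))
  if (tree$n < 3)
    stop("the Yule likelihood needs at least 3 tips (one non-root event)")
  ev_t <- tree$root_age - tree$event_ages
  lam <- rate_at(model, ev_t, tree$root_age)
  if (any(lam <= 0)) return(-Inf)
  sum(log(lam)) - integrated_intensity(model, tree) + lfactorial(tree$n - 1)
}

#' Akaike information criterion
#'
#' `AIC = -2 logL + 2k`.
#'
#' @param logL log-likelihood.
#' @param k number of free parameters (non-negative).
#' @return the AIC value.
#' @export
aic <- function(logL, k) {
  if (!is_scalar_number(logL)) stop("'logL' must be a single number")
  if (!is_scalar_number(k) || k < 0) stop("'k' must be a non-negative count")
  -2 * logL + 2 * k
}

#' Likelihood-ratio test for clock-like substitution rates
#'
#' Arithmetic of the clock versus non-clock comparison:
#' `LR = 2 (logL_nonclock - logL_clock)`, referred to a chi-square upper tail
#' with `df` degrees of freedom (1 when a two-rate model is compared with a
#' single-rate clock). The non-clock model nests the clock, so its likelihood
#' should not be lower; a warning is issued if it is (numerical noise from
#' the upstream optimiser) and the statistic is floored at zero for the
#' p-value.
#'
#' @param logL_clock,logL_nonclock fitted log-likelihoods.
#' @param df degrees of freedom (default 1).
#' @return a list with `statistic`, `p_value` and `df`.
#' @examples
#' lrt_clock(-413.34, -413.26)  # LR = 0.16
#' @export
lrt_clock <- function(logL_clock, logL_nonclock, df = 1) {
  if (!is_scalar_number(logL_clock) || !is_scalar_number(logL_nonclock))
    stop("log-likelihoods must be single numbers")
  lr <- 2 * (logL_nonclock - logL_clock)
  if (lr < -1e-8)
    warning("non-clock log-likelihood is below the clock one; ",
            "check the upstream fits")
  list(statistic = lr,
       p_value = stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE),
       df = df)
}
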