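#' Lineage-through-time curve
#'
#' The cumulative count of reconstructed lineages against time since the
#' root: one point per branching event, starting at (0, 2) for a bifurcating
#' root and ending at the tip count. The step function is right-continuous
#' (see [lineage_count()]).
#'
#' @param x a [chronogram] with at least 2 tips.
#' @return a data frame with columns `time` (Myr since the root), `age`
#'   (Myr before present) and `n_lineages`.
#' @export
ltt_curve <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  if (x$n < 2) stop("an LTT curve needs at least 2 tips")
  ages <- branching_times(x)                  # descending
  t <- x$root_age - ages                      # ascending
  data.frame(time = t, age = ages, n_lineages = 1L + seq_along(t))
}

#' LTT simulation envelope
#'
#' Pointwise quantile envelope of the lineage count under a fitted
#' diversification model, obtained by simulating replicate chronograms
#' conditioned on the observed tip count and root age (rejection sampling,
#' see [simulate_conditioned_tree()]) and taking per-time quantiles on a
#' shared grid.
#'
#' @param tree a [chronogram].
#' @param fit a `diversification_fit` (its `model` is simulated from).
#' @param reps number of simulated trees (at least 100; default 200).
#' @param seed RNG seed (optional).
#' @param level envelope coverage (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param grid_points number of grid times (default 101).
#' @return a data frame with columns `time`, `count` (observed), `lower`,
#'   `upper` and `median` (simulated quantiles); the matrix of simulated
#'   counts is attached as attribute `"sims"`.
#' @export
ltt_envelope <- function(tree, fit, reps = 200, seed = NULL, level = 0.95,
                         grid_points = 101) {
  stopifnot(inherits(tree, "chronogram"),
            inherits(fit, "diversification_fit"))
  if (reps < 100) stop("'reps' must be at least 100 for a stable envelope")
  grid <- seq(0, tree$root_age, length.out = grid_points)
  obs <- lineage_count(tree, grid)
  sims <- matrix(NA_integer_, reps, grid_points)
  for (r in seq_len(reps)) {
    sim <- simulate_conditioned_tree(fit$model, n = tree$n,
                                     root_age = tree$root_age,
                                     seed = derive_seed(seed, r))
    sims[r, ] <- lineage_count(sim, grid)
  }
  alpha <- (1 - level) / 2
  qs <- apply(sims, 2, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  out <- data.frame(time = grid, count = obs,
                    lower = qs[1, ], median = qs[2, ], upper = qs[3, ])
  attr(out, "sims") <- sims
  out
}

#' Per-window diversification rate estimates
#'
#' Splits the tree's age span into windows of fixed width, half-open toward
#' the past with the youngest window containing the present, and estimates a
#' speciation rate per window as (non-root branching events in the window) /
#' (lineage-time in the window). Windows with zero lineage-time get `NA`,
#' never 0. With a width at least the root age this collapses to the
#' constant-rate MLE.
#'
#' @param x a [chronogram].
#' @param width window width in Myr (default 10).
#' @return a data frame, oldest window first, with columns `age_old`,
#'   `age_young`, `events`, `lineage_time`, `rate`.
#' @export
window_rates <- function(x, width = 10) {
  stopifnot(inherits(x, "chronogram"))
  if (!is_scalar_number(width) || width <= 0)
    stop("'width' must be a single positive number of Myr")
  bnd <- seq(0, x$root_age, by = width)
  if (bnd[length(bnd)] < x$root_age) bnd <- c(bnd, x$root_age)
  Eb <- events_below(x, bnd)
  Xb <- lineage_time_below(x, bnd)
  ev <- diff(Eb); lt <- diff(Xb)
  out <- data.frame(age_old = bnd[-1], age_young = bnd[-length(bnd)],
                    events = ev, lineage_time = lt,
                    rate = ifelse(lt > 0, ev / lt, NA_real_))
  out[order(out$age_old, decreasing = TRUE), , drop = FALSE]
}
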