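# Maximum-likelihood fitting of diversification models and AIC comparison.

new_diversification_fit <- function(model, logL, k, estimates, se = NULL,
                                    converged = TRUE, evals = NA_integer_,
                                    details = list()) {
  if (is.null(se)) se <- rep(NA_real_, length(estimates))
  names(se) <- names(estimates)
  structure(list(model = model, logL = logL, k = k, AIC = aic(logL, k),
                 estimates = estimates, se = se, converged = converged,
                 evals = evals, details = details),
            class = "diversification_fit")
}

#' @export
print.diversification_fit <- function(x, ...) {
  cat(sprintf("Diversification fit (%s): logL = %.4f, k = %d, AIC = %.4f\n",
              x$model$family, x$logL, x$k, round(x$AIC, 4)))
  est <- sprintf("%s = %.4g%s", names(x$estimates), x$estimates,
                 ifelse(is.na(x$se), "", sprintf(" ± %.3g", x$se)))
  cat(" ", paste(est, collapse = ", "), "\n")
  if (!isTRUE(x$converged)) cat("  (optimiser did not report convergence)\n")
  invisible(x)
}

#' Constant-rate Yule fit
#'
#' Maximum-likelihood fit of the constant-rate pure-birth model. The MLE has
#' the closed form \eqn{\hat\lambda = (n-2)/X} with `X` the total edge length
#' (event count and `X` both follow the conditioned process, so the count is
#' the number of non-root branching events). The standard error is the
#' Poisson-information form \eqn{\hat\lambda/\sqrt{n-2}}.
#'
#' @param tree a [chronogram] with at least 3 tips.
#' @return a `diversification_fit` with `k = 1`.
#' @examples
#' toy <- read_chronogram("((A:1,B:1):1,C:2);")
#' fit_yule_constant(toy)$estimates  # lambda = 0.2
#' @export
fit_yule_constant <- function(tree) {
  stopifnot(inherits(tree, "chronogram"))
  if (tree$n < 3) stop("need at least 3 tips")
  X <- total_branch_length(tree)
  if (X <= 0) stop("degenerate tree: zero total branch length")
  ne <- length(tree$event_ages)
  lambda <- ne / X
  model <- rate_constant(lambda)
  new_diversification_fit(
    model, yule_time_loglik(model, tree), k = 1,
    estimates = c(lambda = lambda),
    se = c(lambda = lambda / sqrt(ne)))
}

#' Constant-rate birth--death fit
#'
#' Maximum-likelihood fit of the reconstructed-process birth--death model
#' with speciation rate `lambda` and extinction rate `mu >= 0`, conditioned
#' on the root split and on survival of both root lineages (the standard
#' reconstructed-tree likelihood in terms of the net rate `r = lambda - mu`
#' and the turnover `a = mu/lambda`). The optimiser works on `(r, a)` with
#' box constraints so the pure-birth boundary `mu = 0` is attainable; on that
#' boundary the log-likelihood coincides with the constant-rate Yule value.
#'
#' @param tree a [chronogram] with at least 3 tips.
#' @return a `diversification_fit` with `k = 2`; estimates `lambda` and `mu`.
#' @export
fit_birth_death_constant <- function(tree) {
  stopifnot(inherits(tree, "chronogram"))
  if (tree$n < 3) stop("need at least 3 tips")
  bt <- tree$event_ages_all              # descending, root age first
  N <- length(bt) + 1L                   # effective tip count
  sum_young <- sum(bt[-1])

  negll <- function(p) {
    r <- p[1]; a <- p[2]
    ll <- suppressWarnings(
      lfactorial(N - 1) + (N - 2) * log(r) + r * sum_young +
        N * log(1 - a) - 2 * sum(log(exp(r * bt) - a)))
    if (!is.finite(ll)) 1e12 else -ll
  }

  # stage 1: unconstrained Nelder-Mead on (log r, logit a) from several
  # starts; stage 2: box-constrained polish in (r, a) so the pure-birth
  # boundary a = 0 stays attainable
  negll_t <- function(q) negll(c(exp(q[1]), stats::plogis(q[2])))
  lam0 <- length(tree$event_ages) / total_branch_length(tree)
  starts <- list(c(log(lam0), -6), c(log(lam0 / 2), 0),
                 c(log(lam0 * 2), -2))
  best <- NULL
  evals <- 0L
  for (s in starts) {
    o1 <- tryCatch(stats::optim(s, negll_t, method = "Nelder-Mead",
                                control = list(maxit = 2000)),
                   error = function(e) NULL)
    if (is.null(o1)) next
    p1 <- c(exp(o1$par[1]), stats::plogis(o1$par[2]))
    o <- tryCatch(
      stats::optim(p1, negll, method = "L-BFGS-B",
                   lower = c(1e-9, 0), upper = c(Inf, 1 - 1e-9)),
      error = function(e) list(par = p1, value = o1$value,
                               convergence = o1$convergence,
                               counts = c(0, 0)))
    evals <- evals + o1$counts[1] + o$counts[1]
    if (is.null(best) || o$value < best$value) best <- o
  }
  # the boundary itself, in case the interior search drifted away from it
  ob <- tryCatch(
    stats::optim(c(lam0, 0), negll, method = "L-BFGS-B",
                 lower = c(1e-9, 0), upper = c(Inf, 1 - 1e-9)),
    error = function(e) NULL)
  if (!is.null(ob) && (is.null(best) || ob$value < best$value)) best <- ob
  if (is.null(best)) stop("birth-death optimisation failed from all starts")
  r <- best$par[1]; a <- best$par[2]
  lambda <- r / (1 - a); mu <- a * lambda
  se <- tryCatch({
    H <- stats::optimHess(best$par, negll)
    v <- diag(solve(H))
    if (any(v <= 0)) stop("non-positive variance")
    # delta method from (r, a) to (lambda, mu)
    J <- matrix(c(1 / (1 - a), r / (1 - a)^2,
                  a / (1 - a), r / (1 - a)^2), 2, 2, byrow = TRUE)
    V <- J %*% solve(H) %*% t(J)
    sqrt(pmax(diag(V), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  new_diversification_fit(
    rate_constant(lambda), -best$value, k = 2,
    estimates = c(lambda = lambda, mu = mu),
    se = c(lambda = se[1], mu = se[2]),
    converged = best$convergence == 0, evals = evals,
    details = list(r = r, a = a))
}

# Default breakpoint candidate grid: midpoints between consecutive distinct
# non-root branching ages, plus a uniform grid, deduplicated.
breakpoint_candidates <- function(tree, grid_resolution = 0.1) {
  ages <- sort(unique(tree$event_ages))
  mids <- if (length(ages) >= 2) (ages[-1] + ages[-length(ages)]) / 2 else numeric(0)
  grd <- seq(grid_resolution, tree$root_age, by = grid_resolution)
  cand <- sort(unique(c(mids, grd)))
  cand[cand > 0 & cand < tree$root_age]
}

#' Piecewise-constant (rate-shift) Yule fit
#'
#' Fits a pure-birth model with `m` rate epochs separated by `m - 1`
#' breakpoint ages. For fixed breakpoints each epoch rate has the analytic
#' MLE `events in epoch / lineage-time in epoch`; the breakpoints are
#' profiled by exhaustive search over a candidate grid, because the profile
#' likelihood is piecewise in the breakpoints with jumps at branching times
#' (continuous optimisation would stall on the flats). Epochs are half-open:
#' an event exactly on a breakpoint age belongs to the younger epoch. Epochs
#' and their rates are reported oldest-first.
#'
#' @param tree a [chronogram] with at least 3 tips.
#' @param m number of epochs (`m = 1` reduces to [fit_yule_constant()]).
#' @param grid_resolution spacing (Myr) of the uniform part of the candidate
#'   grid (default 0.1).
#' @param candidates optional numeric vector of candidate breakpoint ages,
#'   overriding the default grid.
#' @param breakpoints optional fixed breakpoint ages (descending); when
#'   supplied no search is performed.
#' @param min_events minimum number of branching events required in every
#'   epoch during the breakpoint search (default 5, so every epoch rate is
#'   estimated with relative standard error at most `1/sqrt(5)`; the floor
#'   shrinks automatically on trees with fewer events than `m * min_events`).
#'   Unconstrained profiling
#'   rewards degenerate edge epochs — e.g. a zero-event epoch spanning the
#'   gap between the youngest branching event and the present — exactly the
#'   minimum-segment problem of changepoint inference, and the occupancy
#'   floor is the standard remedy. Fixed user-supplied breakpoints are not
#'   constrained.
#' @return a `diversification_fit` with `k = 2m - 1`; estimates
#'   `lambda_1..lambda_m` (oldest first) and `tau_1..tau_{m-1}`.
#' @export
fit_yule_piecewise <- function(tree, m, grid_resolution = 0.1,
                               candidates = NULL, breakpoints = NULL,
                               min_events = 5) {
  stopifnot(inherits(tree, "chronogram"))
  if (!is_scalar_number(m) || m < 1 || m != round(m))
    stop("'m' must be a positive integer epoch count")
  if (tree$n < 3) stop("need at least 3 tips")
  m <- as.integer(m)
  if (m == 1) return(fit_yule_constant(tree))
  ne <- length(tree$event_ages)
  if (m > ne + 1L)
    stop("more epochs (", m, ") than branching events (", ne, ")")
  X <- total_branch_length(tree)

  if (!is.null(breakpoints)) {
    bp <- sort(as.numeric(breakpoints), decreasing = TRUE)
    if (length(bp) != m - 1L) stop("need ", m - 1L, " fixed breakpoints")
    res <- piecewise_profile(tree, matrix(sort(bp), ncol = 1), ne, X)
    return(piecewise_fit_from(tree, res$rates[, 1], bp, res$logL[1], m))
  }

  cand <- if (is.null(candidates)) breakpoint_candidates(tree, grid_resolution)
          else sort(unique(candidates[candidates > 0 & candidates < tree$root_age]))
  if (length(cand) < m - 1L)
    stop("not enough breakpoint candidates for ", m, " epochs")
  if (choose(length(cand), m - 1L) > 3e6)
    stop("exhaustive profile over ", length(cand), " candidates choose ",
         m - 1L, " is too large; coarsen 'grid_resolution'")
  cmb <- utils::combn(length(cand), m - 1L)      # ascending ages per column
  B <- matrix(cand[cmb], nrow = m - 1L)
  res <- piecewise_profile(tree, B, ne, X)
  floor_eff <- min(min_events, ne %/% m)   # small trees: share events out
  res$logL[colSums(res$events < floor_eff) > 0] <- -Inf
  if (all(!is.finite(res$logL)))
    stop("no breakpoint configuration satisfies the per-epoch occupancy ",
         "floor (min_events = ", min_events, ")")
  best <- which.max(res$logL)
  bp <- sort(B[, best], decreasing = TRUE)
  piecewise_fit_from(tree, res$rates[, best], bp, res$logL[best], m)
}

# Profile log-likelihood for columns of breakpoint ages (ascending within a
# column). Returns rates young->old per column and the profiled logL.
piecewise_profile <- function(tree, B, ne, X) {
  K <- ncol(B); nb <- nrow(B)
  Ec <- matrix(events_below(tree, B), nrow = nb)
  Xc <- matrix(lineage_time_below(tree, B), nrow = nb)
  pad0 <- matrix(0, 1, K)
  Eb <- rbind(pad0, Ec, matrix(ne, 1, K))
  Xb <- rbind(pad0, Xc, matrix(X, 1, K))
  Ee <- Eb[-1, , drop = FALSE] - Eb[-(nb + 2), , drop = FALSE]  # young->old
  Le <- Xb[-1, , drop = FALSE] - Xb[-(nb + 2), , drop = FALSE]
  ok <- colSums(Le <= 0) == 0
  Lsafe <- pmax(Le, .Machine$double.xmin)
  term <- ifelse(Ee > 0, Ee * log(Ee / Lsafe), 0)
  logL <- colSums(term) - ne + lfactorial(tree$n - 1)
  logL[!ok] <- -Inf
  list(logL = logL, rates = Ee / Lsafe, events = Ee, ltime = Le)
}

piecewise_fit_from <- function(tree, rates_young_first, bp, logL, m) {
  rates <- rev(rates_young_first)                 # oldest-first
  ev <- rev(attr_events(tree, bp))
  model <- rate_piecewise(rates, bp)
  est <- c(stats::setNames(rates, paste0("lambda_", seq_len(m))),
           stats::setNames(bp, paste0("tau_", seq_len(m - 1))))
  se <- c(ifelse(ev > 0, rates / sqrt(ev), NA_real_),
          rep(NA_real_, m - 1))
  names(se) <- names(est)
  new_diversification_fit(model, logL, k = 2L * m - 1L,
                          estimates = est, se = se,
                          details = list(events = ev))
}

# events per epoch, young->old, for fixed breakpoints (ascending diff logic)
attr_events <- function(tree, bp) {
  b <- sort(bp)
  Eb <- c(0, events_below(tree, b), length(tree$event_ages))
  diff(Eb)
}

#' Logistic time-dependent Yule fit
#'
#' Fits \eqn{\lambda(t) = 1/(1+e^{-(a t + b)})} (t = time since the root) by
#' numerical maximum likelihood with multiple starting points (a flat start
#' at the constant-rate MLE plus seeded perturbations), Nelder--Mead followed
#' by a BFGS polish. Standard errors come from the observed information
#' (numerical Hessian).
#'
#' @param tree a [chronogram] with at least 3 tips.
#' @param starts number of starting points (default 5).
#' @param seed seed for the start perturbations (fixed default for
#'   reproducibility).
#' @return a `diversification_fit` with `k = 2`; estimates `a` and `b`.
#' @export
fit_yule_logistic <- function(tree, starts = 5, seed = 1) {
  stopifnot(inherits(tree, "chronogram"))
  if (tree$n < 3) stop("need at least 3 tips")
  nll <- function(p) {
    ll <- yule_time_loglik(rate_logistic(p[1], p[2]), tree)
    if (!is.finite(ll)) 1e12 else -ll
  }
  lam0 <- min(max(length(tree$event_ages) / total_branch_length(tree), 1e-3),
              1 - 1e-3)
  b0 <- stats::qlogis(lam0)
  pts <- local_seed(seed, {
    c(list(c(0, b0)),
      replicate(max(starts - 1, 0),
                c(stats::rnorm(1, 0, 0.05), stats::rnorm(1, b0, 1)),
                simplify = FALSE))
  })
  best <- NULL; evals <- 0L
  for (p in pts) {
    o1 <- stats::optim(p, nll, method = "Nelder-Mead")
    o2 <- tryCatch(stats::optim(o1$par, nll, method = "BFGS"),
                   error = function(e) o1)
    o <- if (o2$value <= o1$value) o2 else o1
    evals <- evals + o1$counts[1] + o2$counts[1]
    if (is.null(best) || o$value < best$value) best <- o
  }
  a <- best$par[1]; b <- best$par[2]
  se <- tryCatch({
    H <- stats::optimHess(best$par, nll)
    sqrt(diag(solve(H)))
  }, error = function(e) c(NA_real_, NA_real_))
  new_diversification_fit(
    rate_logistic(a, b), -best$value, k = 2,
    estimates = c(a = a, b = b), se = c(a = se[1], b = se[2]),
    converged = best$convergence == 0, evals = evals)
}

#' Sea-level covariate Yule fit
#'
#' Two-rate pure-birth model whose epochs are the high-stand and low-stand
#' age intervals of a [sea_level_intervals] table. Both MLEs are analytic:
#' events and lineage-time are pooled per sea-level state, and each rate is
#' their ratio. Any age not covered by a high-stand interval (including ages
#' older than the table's span) is treated as low-stand.
#'
#' @param tree a [chronogram] with at least 3 tips.
#' @param intervals a [sea_level_intervals] object. An empty table degrades
#'   to the constant-rate fit with a warning.
#' @return a `diversification_fit` with `k = 2`; estimates `lambda_high` and
#'   `lambda_low`.
#' @export
fit_yule_covariate <- function(tree, intervals) {
  stopifnot(inherits(tree, "chronogram"))
  if (!inherits(intervals, "sea_level_intervals"))
    stop("'intervals' must be a sea_level_intervals object")
  if (tree$n < 3) stop("need at least 3 tips")
  if (nrow(intervals) == 0) {
    warning("empty sea-level table: falling back to the constant-rate model")
    return(fit_yule_constant(tree))
  }
  X <- total_branch_length(tree)
  ne <- length(tree$event_ages)
  Lh <- high_stand_lineage_time(intervals, tree)
  eh <- high_stand_events(intervals, tree)
  Ll <- X - Lh; el <- ne - eh
  lam_h <- if (Lh > 0) eh / Lh else 0
  lam_l <- if (Ll > 0) el / Ll else 0
  model <- rate_covariate(lam_h, lam_l, intervals)
  new_diversification_fit(
    model, yule_time_loglik(model, tree), k = 2,
    estimates = c(lambda_high = lam_h, lambda_low = lam_l),
    se = c(lambda_high = if (eh > 0) lam_h / sqrt(eh) else NA_real_,
           lambda_low  = if (el > 0) lam_l / sqrt(el) else NA_real_),
    details = list(events = c(high = eh, low = el),
                   lineage_time = c(high = Lh, low = Ll)))
}

#' Fit and compare the diversification model suite
#'
#' Fits the standard model set — constant Yule, constant birth--death,
#' sea-level covariate (when an interval table is given), logistic, and
#' one- and two-breakpoint piecewise models — and tabulates estimates,
#' log-likelihood, parameter count and AIC. The best model is the minimum
#' AIC, ties broken toward fewer parameters.
#'
#' @param tree a [chronogram].
#' @param intervals optional [sea_level_intervals]; if `NULL` the covariate
#'   model is skipped.
#' @param max_breakpoints largest number of breakpoints to fit (default 2).
#' @param grid_resolution breakpoint search grid spacing (Myr).
#' @return a data frame (one row per model) with attribute `"fits"` holding
#'   the full fit objects.
#' @export
model_comparison <- function(tree, intervals = NULL, max_breakpoints = 2,
                             grid_resolution = 0.1) {
  stopifnot(inherits(tree, "chronogram"))
  fits <- list(yule = fit_yule_constant(tree),
               birth_death = fit_birth_death_constant(tree))
  if (!is.null(intervals))
    fits$sea_level <- fit_yule_covariate(tree, intervals)
  fits$logistic <- fit_yule_logistic(tree)
  for (b in seq_len(max_breakpoints)) {
    nm <- sprintf("breakpoints_%d", b)
    fits[[nm]] <- fit_yule_piecewise(tree, m = b + 1L,
                                     grid_resolution = grid_resolution)
  }
  fmt <- vapply(fits, function(f)
    paste(sprintf("%s = %.4g%s", names(f$estimates), f$estimates,
                  ifelse(is.na(f$se), "", sprintf(" ± %.3g", f$se))),
          collapse = "; "), character(1))
  tab <- data.frame(
    model = names(fits),
    estimates = fmt,
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    row.names = NULL)
  ord <- order(tab$AIC, tab$k)
  tab$best <- FALSE
  tab$best[ord[1]] <- TRUE
  attr(tab, "fits") <- fits
  tab
}
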