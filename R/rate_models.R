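#' Speciation-rate models
#'
#' Parametric families for the per-lineage speciation rate \eqn{\lambda(t)}
#' used by the time-dependent pure-birth likelihood:
#'
#' * `rate_constant(lambda)` — a single rate (events/lineage/Myr).
#' * `rate_piecewise(rates, breakpoints)` — piecewise-constant rates with
#'   breakpoints given as ages (Myr before present). Epochs are indexed
#'   oldest-first: `rates[1]` applies before `breakpoints[1]`, and an event
#'   falling exactly on a breakpoint age belongs to the *younger* epoch.
#' * `rate_logistic(a, b)` — \eqn{\lambda(t) = 1/(1 + e^{-(a t + b)})} with
#'   `t` the time since the root, so a negative slope `a` means a rate that
#'   declines toward the present. The rate is bounded in (0, 1).
#' * `rate_covariate(lambda_high, lambda_low, intervals)` — a two-rate model
#'   keyed to a [sea_level_intervals] table: `lambda_high` applies during
#'   high-stand age intervals, `lambda_low` elsewhere.
#'
#' @param lambda,rates,lambda_high,lambda_low non-negative rates
#'   (events/lineage/Myr).
#' @param breakpoints strictly decreasing ages (Myr); one fewer than `rates`.
#' @param a,b slope and intercept of the logistic rate in `t`.
#' @param intervals a [sea_level_intervals] object.
#' @return an object of class `"rate_model"` (subclassed by family).
#' @seealso [rate_at()], [integrated_intensity()], [yule_time_loglik()]
#' @export
rate_constant <- function(lambda) {
  if (!is_scalar_number(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  structure(list(family = "constant", lambda = lambda),
            class = c("rate_constant", "rate_model"))
}

#' @rdname rate_constant
#' @export
rate_piecewise <- function(rates, breakpoints) {
  if (!is.numeric(rates) || anyNA(rates) || any(rates < 0))
    stop("'rates' must be non-negative numbers")
  if (length(breakpoints) != length(rates) - 1L)
    stop("need exactly one breakpoint fewer than rates")
  if (length(breakpoints) &&
      (anyNA(breakpoints) || any(breakpoints <= 0) ||
       any(diff(breakpoints) >= 0)))
    stop("'breakpoints' must be strictly decreasing positive ages (Myr)")
  structure(list(family = "piecewise", rates = as.numeric(rates),
                 breakpoints = as.numeric(breakpoints)),
            class = c("rate_piecewise", "rate_model"))
}

#' @rdname rate_constant
#' @export
rate_logistic <- function(a, b) {
  if (!is_scalar_number(a) || !is_scalar_number(b))
    stop("'a' and 'b' must be single numbers")
  structure(list(family = "logistic", a = a, b = b),
            class = c("rate_logistic", "rate_model"))
}

#' @rdname rate_constant
#' @export
rate_covariate <- function(lambda_high, lambda_low, intervals) {
  if (!is_scalar_number(lambda_high) || lambda_high < 0 ||
      !is_scalar_number(lambda_low)  || lambda_low  < 0)
    stop("rates must be single non-negative numbers")
  if (!inherits(intervals, "sea_level_intervals"))
    stop("'intervals' must be a sea_level_intervals object")
  structure(list(family = "covariate_step", lambda_high = lambda_high,
                 lambda_low = lambda_low, intervals = intervals),
            class = c("rate_covariate", "rate_model"))
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Speciation-rate model:", x$family, "\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Evaluate a speciation-rate model
#'
#' Evaluates \eqn{\lambda(t)} at times since the root. Age-keyed families
#' (piecewise, covariate) convert `t` to an age via `root_age - t` before
#' locating the epoch; an instant exactly on an epoch boundary takes the
#' *younger* epoch's rate.
#'
#' @param model a [rate_constant()]-family model.
#' @param t time(s) since the root (Myr), in `[0, root_age]`.
#' @param root_age root age in Myr.
#' @return numeric vector of rates (events/lineage/Myr).
#' @export
rate_at <- function(model, t, root_age) UseMethod("rate_at")

check_rate_domain <- function(t, root_age) {
  if (!is.numeric(t) || anyNA(t))
    stop("'t' must be numeric")
  eps <- 1e-9 * max(root_age, 1)
  if (any(t < -eps | t > root_age + eps))
    stop("'t' outside [0, root_age]")
}

#' @export
rate_at.rate_constant <- function(model, t, root_age) {
  check_rate_domain(t, root_age)
  rep_len(model$lambda, length(t))
}

#' @export
rate_at.rate_piecewise <- function(model, t, root_age) {
  check_rate_domain(t, root_age)
  a <- root_age - t
  # epoch index, oldest-first; boundary age belongs to the younger epoch
  idx <- 1L + vapply(a, function(ai) sum(ai <= model$breakpoints), integer(1))
  model$rates[idx]
}

#' @export
rate_at.rate_logistic <- function(model, t, root_age) {
  check_rate_domain(t, root_age)
  stats::plogis(model$a * t + model$b)
}

#' @export
rate_at.rate_covariate <- function(model, t, root_age) {
  check_rate_domain(t, root_age)
  a <- root_age - t
  hi <- in_high_stand(model$intervals, a)
  ifelse(hi, model$lambda_high, model$lambda_low)
}

#' Sea-level high-stand intervals
#'
#' A table of age intervals (Myr before present) during which sea level stood
#' above the reference height (here +50 m); the complement is treated as
#' low-stand. `start_age > end_age` within each interval because ages
#' decrease toward the present. Overlapping or touching intervals are merged.
#' Membership is half-open toward the present: an age exactly on the younger
#' boundary of an interval is *low*-stand, matching the epoch boundary rule
#' of the piecewise models.
#'
#' @param start_age,end_age numeric vectors of interval boundaries (Myr),
#'   with `start_age[i] > end_age[i]`.
#' @return an object of class `"sea_level_intervals"`: a data frame with
#'   columns `start_age`, `end_age`, sorted oldest first.
#' @examples
#' sea_level_intervals(c(12, 5), c(10, 4))
#' @export
sea_level_intervals <- function(start_age, end_age) {
  if (length(start_age) != length(end_age))
    stop("'start_age' and 'end_age' must have equal length")
  if (length(start_age) == 0) {
    out <- data.frame(start_age = numeric(0), end_age = numeric(0))
    class(out) <- c("sea_level_intervals", "data.frame")
    return(out)
  }
  if (anyNA(start_age) || anyNA(end_age) || any(end_age < 0))
    stop("interval ages must be non-negative numbers")
  if (any(start_age <= end_age))
    stop("each interval needs start_age > end_age (ages decrease toward the present)")
  o <- order(start_age, decreasing = TRUE)
  s <- start_age[o]; e <- end_age[o]
  # merge overlapping / touching intervals (scanning old -> young)
  ms <- s[1]; me <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      k <- length(ms)
      if (s[i] >= me[k]) me[k] <- min(me[k], e[i])
      else { ms <- c(ms, s[i]); me <- c(me, e[i]) }
    }
  }
  out <- data.frame(start_age = ms, end_age = me)
  class(out) <- c("sea_level_intervals", "data.frame")
  out
}

in_high_stand <- function(intervals, age) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(age)))
  vapply(age, function(a)
    any(intervals$end_age < a & a <= intervals$start_age), logical(1))
}

#' @rdname sea_level_intervals
#' @param file a two-column comma-separated file `start_age,end_age`, one
#'   high-stand interval per row (header optional).
#' @export
read_sea_levels <- function(file) {
  d <- utils::read.csv(file, header = TRUE)
  if (!all(c("start_age", "end_age") %in% names(d))) {
    d <- utils::read.csv(file, header = FALSE)
    if (ncol(d) < 2) stop("expected two columns: start_age,end_age")
    names(d)[1:2] <- c("start_age", "end_age")
  }
  sea_level_intervals(d$start_age, d$end_age)
}

#' @rdname sea_level_intervals
#' @param x a `sea_level_intervals` object.
#' @export
write_sea_levels <- function(x, file) {
  stopifnot(inherits(x, "sea_level_intervals"))
  utils::write.csv(as.data.frame(unclass(x))[c("start_age", "end_age")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
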