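# Simulators: time-varying pure-birth chronograms, community assembly,
# and a sea-level fixture. These define the study conditions under which the
# estimators and the Pi_ST test are exercised.

#' Simulate a pure-birth chronogram under a time-varying rate
#'
#' Forward simulation from two root lineages. Families with piecewise-
#' constant rates (constant, piecewise, covariate) use exponential waiting
#' times at the current total rate `N * lambda`, restarting at epoch
#' boundaries; the logistic family uses Ogata thinning with the per-segment
#' supremum of the monotone sigmoid as bound. Stopping is either at a fixed
#' `duration` (the root age of the returned tree) or at a tip count
#' `n_tips`; the tip-count stop runs to the time of the next (untaken)
#' speciation event, which makes the constant-rate MLE `(n-2)/X` exactly
#' unbiased. Age-keyed families (piecewise, covariate) need a known root age
#' and therefore require the `duration` stop.
#'
#' @param model a rate model, see [rate_constant()].
#' @param n_tips stop at this tip count (constant/logistic families only).
#' @param duration stop at this root age (Myr).
#' @param seed RNG seed (optional; same seed, same tree).
#' @param max_events safety cap on the event count.
#' @return a [chronogram]; tips are labelled `t1..tn`.
#' @examples
#' simulate_yule_tree(rate_constant(0.1), duration = 30, seed = 1)
#' @export
simulate_yule_tree <- function(model, n_tips = NULL, duration = NULL,
                               seed = NULL, max_events = 1e5) {
  stopifnot(inherits(model, "rate_model"))
  if (is.null(n_tips) == is.null(duration))
    stop("give exactly one of 'n_tips' or 'duration'")
  if (!is.null(n_tips)) {
    if (!is_scalar_number(n_tips) || n_tips < 2 || n_tips != round(n_tips))
      stop("'n_tips' must be an integer >= 2")
    if (inherits(model, "rate_piecewise") || inherits(model, "rate_covariate"))
      stop("age-keyed rate families need a 'duration' stop")
    if (inherits(model, "rate_constant") && model$lambda == 0 && n_tips > 2)
      stop("target tip count unreachable with a zero speciation rate")
  }
  if (!is.null(duration) &&
      (!is_scalar_number(duration) || duration <= 0))
    stop("'duration' must be a single positive number of Myr")

  local_seed(seed, sim_forward(model, n_tips, duration, max_events))
}

# rate and epoch-boundary lookup in forward time; `horizon` is the total
# duration when known (NA for tip-count stops of t-keyed families)
sim_rate_fun <- function(model, horizon) {
  if (inherits(model, "rate_constant")) {
    list(rate = function(t) model$lambda,
         sup  = function(t) model$lambda,
         bounds = numeric(0))
  } else if (inherits(model, "rate_logistic")) {
    list(rate = function(t) stats::plogis(model$a * t + model$b),
         # sigmoid monotone in t: sup over [t, horizon] at an endpoint;
         # bounded by 1 when the horizon is open-ended
         sup = function(t) if (is.na(horizon)) 1 else
           max(stats::plogis(model$a * t + model$b),
               stats::plogis(model$a * horizon + model$b)),
         bounds = numeric(0))
  } else if (inherits(model, "rate_piecewise")) {
    bnd_t <- sort(horizon - model$breakpoints)     # breakpoints in t
    list(rate = function(t) {
      a <- horizon - t
      model$rates[1L + sum(a <= model$breakpoints)]
    }, sup = NULL, bounds = bnd_t[bnd_t > 0 & bnd_t < horizon])
  } else if (inherits(model, "rate_covariate")) {
    edges <- sort(horizon - c(model$intervals$start_age,
                              model$intervals$end_age))
    list(rate = function(t) {
      if (in_high_stand(model$intervals, horizon - t)) model$lambda_high
      else model$lambda_low
    }, sup = NULL, bounds = edges[edges > 0 & edges < horizon])
  } else stop("unknown rate family")
}

sim_forward <- function(model, n_tips, duration, max_events) {
  horizon <- if (is.null(duration)) NA_real_ else duration
  rf <- sim_rate_fun(model, horizon)
  piecewise_const <- is.null(rf$sup)

  # lineage records: birth time, parent internal node, fate node (NA = tip)
  l_birth <- c(0, 0)
  l_parent <- c(1L, 1L)
  l_fate <- c(NA_integer_, NA_integer_)
  active <- c(1L, 2L)
  int_time <- 0                       # internal node 1 = the root split
  int_child <- list(c(1L, 2L))
  t <- 0; n_events <- 0L
  target <- if (is.null(n_tips)) Inf else n_tips

  repeat {
    N <- length(active)
    if (N >= target) {
      # run to the next (untaken) event to close the final interval
      lam <- if (piecewise_const) rf$rate(t) else rf$sup(t)
      if (lam <= 0)
        stop("speciation rate is zero: cannot close the final interval ",
             "of a tip-count-stopped simulation")
      repeat {
        w <- stats::rexp(1, N * lam)
        t2 <- t + w
        if (piecewise_const) {
          nb <- rf$bounds[rf$bounds > t]
          if (length(nb) && t2 > nb[1]) { t <- nb[1]; lam <- rf$rate(t); next }
          t <- t2; break
        } else {
          t <- t2
          if (stats::runif(1) <= rf$rate(t) / lam) break
        }
      }
      duration <- t
      break
    }
    lam_b <- if (piecewise_const) rf$rate(t) else rf$sup(t)
    if (lam_b <= 0) {
      if (piecewise_const) {
        nb <- rf$bounds[rf$bounds > t]
        if (length(nb)) { t <- nb[1]; next }
      }
      if (is.na(horizon))
        stop("speciation rate is zero with no remaining epochs: ",
             "target tip count unreachable")
      t <- horizon
      break
    }
    w <- stats::rexp(1, N * lam_b)
    t2 <- t + w
    if (piecewise_const) {
      nb <- rf$bounds[rf$bounds > t]
      if (length(nb) && t2 > nb[1]) { t <- nb[1]; next }
    }
    if (!is.na(horizon) && t2 >= horizon) { t <- horizon; break }
    t <- t2
    if (!piecewise_const && stats::runif(1) > rf$rate(t) / lam_b) next
    # branching event: split a uniformly chosen active lineage
    n_events <- n_events + 1L
    if (n_events > max_events) stop("event cap exceeded; check the rates")
    k <- active[sample.int(N, 1)]
    node <- length(int_time) + 1L
    int_time <- c(int_time, t)
    id1 <- length(l_birth) + 1L; id2 <- id1 + 1L
    l_birth <- c(l_birth, t, t)
    l_parent <- c(l_parent, node, node)
    l_fate <- c(l_fate, NA_integer_, NA_integer_)
    l_fate[k] <- node
    int_child[[node]] <- c(id1, id2)
    active <- c(active[active != k], id1, id2)
  }

  build_sim_phylo(l_birth, l_fate, int_time, int_child, duration)
}

# Assemble an ape::phylo from the simulation records (iterative DFS,
# cladewise edge order, root = n+1 as ape expects).
build_sim_phylo <- function(l_birth, l_fate, int_time, int_child, duration) {
  n_int <- length(int_time)
  n_tip <- sum(is.na(l_fate))
  n_edge <- n_tip + n_int - 1L       # one edge per non-root node
  edge <- matrix(0L, n_edge, 2)
  elen <- numeric(n_edge)
  int_id <- integer(n_int)
  tip_ct <- 0L; int_ct <- 0L; e <- 0L

  # stack of (lineage, parent ape-node id); seed with the root's children
  int_ct <- 1L; int_id[1] <- n_tip + 1L
  stack_l <- rev(int_child[[1]])
  stack_p <- rep(int_id[1], 2)
  while (length(stack_l)) {
    l <- stack_l[length(stack_l)]; p <- stack_p[length(stack_p)]
    stack_l <- stack_l[-length(stack_l)]
    stack_p <- stack_p[-length(stack_p)]
    fate <- l_fate[l]
    e <- e + 1L
    if (is.na(fate)) {               # tip
      tip_ct <- tip_ct + 1L
      edge[e, ] <- c(p, tip_ct)
      elen[e] <- duration - l_birth[l]
    } else {                         # internal node
      int_ct <- int_ct + 1L
      id <- n_tip + int_ct
      int_id[fate] <- id
      edge[e, ] <- c(p, id)
      elen[e] <- int_time[fate] - l_birth[l]
      ch <- int_child[[fate]]
      stack_l <- c(stack_l, rev(ch))
      stack_p <- c(stack_p, rep(id, length(ch)))
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_len(n_tip)),
                        Nnode = n_int), class = "phylo")
  chronogram(phy, tol = 1e-8)
}

#' Simulate a chronogram conditioned on tip count and root age
#'
#' Rejection sampling: fixed-duration forward simulations
#' ([simulate_yule_tree()]) are repeated until one has exactly `n` tips, so
#' the accepted trees follow the forward process conditioned on the observed
#' size and depth — the distribution needed for LTT envelopes.
#'
#' @param model a rate model.
#' @param n required tip count (>= 2).
#' @param root_age required root age (Myr).
#' @param seed RNG seed (optional).
#' @param max_attempts cap on rejection attempts before giving up.
#' @return a [chronogram] with exactly `n` tips and depth `root_age`.
#' @export
simulate_conditioned_tree <- function(model, n, root_age, seed = NULL,
                                      max_attempts = 10000) {
  stopifnot(inherits(model, "rate_model"))
  if (!is_scalar_number(n) || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2")
  if (!is_scalar_number(root_age) || root_age <= 0)
    stop("'root_age' must be a single positive number of Myr")
  local_seed(seed, {
    for (i in seq_len(max_attempts)) {
      x <- sim_forward(model, n_tips = NULL, duration = root_age,
                       max_events = 1e5)
      if (x$n == n) return(x)
    }
    stop("no simulation matched n = ", n, " in ", max_attempts,
         " attempts; the model is a poor match for this (n, root_age) — ",
         "revise the parameters")
  })
}

#' Simulate community occurrence matrices over a chronogram
#'
#' Assembles `n_sites` presence/absence samples of `richness_per_site`
#' species from the tree's tips under one of four rules:
#'
#' * `neutral` — uniform sampling without replacement (random sorting).
#' * `filtered` — habitat filtering: a Brownian trait is evolved on the tree
#'   (unit rate, root 0), each site draws an optimum uniformly over the
#'   trait range, and species are sampled with weight
#'   `exp(-strength * |trait - optimum|)`, producing phylogenetic
#'   clustering.
#' * `dispersed` — limiting similarity: species are added in random order,
#'   rejecting any candidate diverged by less than `strength` Myr from a
#'   resident, producing phylogenetic dispersion (sites may fall short of
#'   the target richness, with a warning).
#' * `recent_allopatry` — for every cherry younger than `strength` Myr the
#'   two sister species are confined to disjoint site groups (the two
#'   islands), emulating young allopatric sister species with
#'   non-overlapping ranges; remaining richness is filled neutrally.
#'
#' Sites are split evenly between two islands and alternate inner-reef /
#' outer-slope habitats in the metadata.
#'
#' @param tree a [chronogram].
#' @param n_sites number of sites (default 6).
#' @param richness_per_site species per site (default 20).
#' @param mode assembly rule, see above.
#' @param strength mode-specific intensity: filtering decay (1/trait units),
#'   limiting-similarity radius (Myr), or allopatry age threshold (Myr).
#' @param seed RNG seed (optional).
#' @return an [occurrence_matrix] with site metadata.
#' @export
simulate_communities <- function(tree, n_sites = 6, richness_per_site = 20,
                                 mode = c("neutral", "filtered", "dispersed",
                                          "recent_allopatry"),
                                 strength = 1, seed = NULL) {
  stopifnot(inherits(tree, "chronogram"))
  mode <- match.arg(mode)
  sp <- tree$phy$tip.label
  nsp <- length(sp)
  if (richness_per_site > nsp)
    stop("richness_per_site exceeds the species pool")
  if (strength < 0) stop("'strength' must be non-negative")
  sites <- sprintf("s%02d", seq_len(n_sites))
  island <- rep(c("island_A", "island_B"), each = ceiling(n_sites / 2),
                length.out = n_sites)
  habitat <- rep(c("inner_reef", "outer_slope"), length.out = n_sites)
  meta <- data.frame(site = sites, island = island, habitat = habitat)
  pres <- matrix(0L, nsp, n_sites, dimnames = list(sp, sites))

  local_seed(seed, {
    if (mode == "neutral") {
      for (s in seq_len(n_sites))
        pres[sample.int(nsp, richness_per_site), s] <- 1L
    } else if (mode == "filtered") {
      trait <- ape::rTraitCont(tree$phy, model = "BM", sigma = 1,
                               root.value = 0)
      for (s in seq_len(n_sites)) {
        opt <- stats::runif(1, min(trait), max(trait))
        w <- exp(-strength * abs(trait - opt))
        pres[sample.int(nsp, richness_per_site, prob = w), s] <- 1L
      }
    } else if (mode == "dispersed") {
      d <- divergence_matrix(tree)
      short <- FALSE
      for (s in seq_len(n_sites)) {
        ord <- sample.int(nsp)
        chosen <- integer(0)
        for (k in ord) {
          if (length(chosen) == 0 || all(d[k, chosen] >= strength))
            chosen <- c(chosen, k)
          if (length(chosen) == richness_per_site) break
        }
        if (length(chosen) < richness_per_site) short <- TRUE
        pres[chosen, s] <- 1L
      }
      if (short)
        warning("limiting similarity exhausted the pool before reaching ",
                "the target richness on some sites")
    } else {                         # recent_allopatry
      grp <- ifelse(island == "island_A", 1L, 2L)
      allowed <- matrix(TRUE, nsp, 2)
      for (ch in tree_cherries(tree)) {
        if (tree$node_age[ch$node] < strength) {
          o <- sample.int(2)         # random orientation of the split
          allowed[ch$tips[1], o[2]] <- FALSE
          allowed[ch$tips[2], o[1]] <- FALSE
        }
      }
      for (s in seq_len(n_sites)) {
        pool <- which(allowed[, grp[s]])
        take <- min(richness_per_site, length(pool))
        pres[pool[sample.int(length(pool), take)], s] <- 1L
      }
    }
    occurrence_matrix(pres, meta)
  })
}

# cherries: internal nodes whose children are exactly two tips
tree_cherries <- function(tree) {
  phy <- tree$phy
  n <- tree$n
  out <- list()
  for (v in (n + 1L):(n + tree$Nnode)) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    if (length(ch) == 2 && all(ch <= n))
      out[[length(out) + 1L]] <- list(node = v, tips = ch)
  }
  out
}

#' Sea-level interval fixtures
#'
#' Ready-made high-stand tables for tests and examples: `"toy"` is a fixed
#' two-interval table; `"cenozoic_like"` draws random alternating high/low
#' spans over the last 30 Myr (older ages are left low-stand, reflecting the
#' sparse lineage record before 30 Ma).
#'
#' @param style `"toy"` or `"cenozoic_like"`.
#' @param seed RNG seed for the random style.
#' @return a [sea_level_intervals] object.
#' @export
sea_level_fixture <- function(style = c("toy", "cenozoic_like"),
                              seed = NULL) {
  style <- match.arg(style)
  if (style == "toy")
    return(sea_level_intervals(start_age = c(12, 5), end_age = c(10, 4)))
  local_seed(seed, {
    s <- numeric(0); e <- numeric(0)
    a <- 30
    repeat {
      a <- a - stats::runif(1, 2, 6)      # low-stand span
      if (a <= 0) break
      hi <- stats::runif(1, 1, 4)         # high-stand span
      s <- c(s, a); e <- c(e, max(a - hi, 0))
      a <- a - hi
      if (a <= 0) break
    }
    sea_level_intervals(s, e)
  })
}
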