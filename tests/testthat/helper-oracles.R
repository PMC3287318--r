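# Shared fixtures and independent oracles used across the test files.

toy_tree <- function() read_chronogram("((A:1,B:1):1,C:2);")

toy_occ <- function() {
  occurrence_matrix(matrix(c(1, 1, 0, 1, 0, 1), nrow = 3,
                           dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
}

# random ultrametric trees independent of the package's own simulator
rand_tree <- function(n, seed) {
  set.seed(seed)
  chronogram(ape::rcoal(n))
}

# brute-force pairwise MRCA age: intersect the two root paths and take the
# youngest shared ancestor
brute_divergence <- function(x) {
  phy <- x$phy
  n <- x$n
  parent <- rep(NA_integer_, n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  path_up <- function(v) {
    p <- v
    while (!is.na(parent[v])) { v <- parent[v]; p <- c(p, v) }
    p
  }
  paths <- lapply(seq_len(n), path_up)
  d <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(paths[[i]], paths[[j]])
    d[i, j] <- d[j, i] <- min(x$node_age[common])
  }
  d
}

# connected components of the graph linking species with divergence < T
# (label-propagation; independent of the tree traversal in the package)
components_below <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] < threshold && comp[i] != comp[j]) {
        cc <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- cc
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(rownames(d), comp))
}

# exact integral of N(t) dt evaluated from lineage_count at segment midpoints
ltt_integral <- function(x) {
  t_ev <- sort(x$root_age - branching_times(x))
  lo <- t_ev
  hi <- c(t_ev[-1], x$root_age)
  mid <- (lo + hi) / 2
  keep <- hi > lo
  sum(lineage_count(x, mid[keep]) * (hi - lo)[keep])
}

is_cherry_pair <- function(tree, lab1, lab2) {
  i <- match(lab1, tree$phy$tip.label)
  j <- match(lab2, tree$phy$tip.label)
  for (ch in reefdiv:::tree_cherries(tree))
    if (setequal(ch$tips, c(i, j))) return(TRUE)
  FALSE
}

yule_time_loglik_vec <- function(models, tree) {
  vapply(models, function(m) yule_time_loglik(m, tree), numeric(1))
}

# all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# exhaustive Pi_ST null over all tip permutations, computed with plain loops
enum_pi_null <- function(occ, tree, threshold = Inf) {
  d <- divergence_matrix(tree)
  n <- nrow(d)
  tip_of <- match(rownames(occ$presence), rownames(d))
  vapply(all_perms(n), function(perm) {
    dd <- function(a, b) d[perm[tip_of[a]], perm[tip_of[b]]]
    dS <- numeric(0)
    for (s in seq_len(ncol(occ$presence))) {
      pr <- which(occ$presence[, s] > 0)
      if (length(pr) >= 2) {
        cb <- utils::combn(pr, 2)
        for (cc in seq_len(ncol(cb))) {
          v <- dd(cb[1, cc], cb[2, cc])
          if (v < threshold) dS <- c(dS, v)
        }
      }
    }
    pool <- which(rowSums(occ$presence) > 0)
    dT <- numeric(0)
    cb <- utils::combn(pool, 2)
    for (cc in seq_len(ncol(cb))) {
      v <- dd(cb[1, cc], cb[2, cc])
      if (v < threshold) dT <- c(dT, v)
    }
    (mean(dT) - mean(dS)) / mean(dT)
  }, numeric(1))
}
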