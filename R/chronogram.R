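#' Chronogram objects
#'
#' A chronogram is a rooted ultrametric phylogeny whose branch lengths are in
#' absolute time (here millions of years, Myr), so that every tip sits at the
#' present (age 0) and every node has a well-defined age before present.
#' `chronogram()` validates an [ape::phylo] tree and attaches the node-age
#' bookkeeping used by the diversification and community-structure functions;
#' `read_chronogram()` does the same from a Newick file or string.
#'
#' Two time conventions are used consistently throughout the package:
#' an *age* is measured in Myr before present (the palaeontological axis),
#' while *t* is time since the root, `t = root_age - age`. Likelihood
#' integrals run forward in `t`; user-facing thresholds, breakpoints and
#' sea-level intervals are ages.
#'
#' Multifurcating nodes are accepted: a node of out-degree `m` contributes
#' `m - 1` branching events at the same age.
#'
#' @param phy an object of class `"phylo"` with branch lengths.
#' @param tol relative ultrametricity tolerance: the maximum allowed
#'   deviation of any root-to-tip path from the root age, as a fraction of
#'   the root age. Chronograms produced by dating software carry rounding
#'   noise, hence the default `1e-6`.
#' @return an object of class `"chronogram"`: a list with elements `phy`
#'   (the underlying tree), `n` (tip count), `root_age` (Myr), `node_age`
#'   (ages of all nodes, tips first), and internal event/edge tables.
#' @examples
#' x <- read_chronogram("((A:1,B:1):1,C:2);")
#' x$root_age
#' branching_times(x)
#' @export
chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo"))
    stop("'phy' must be an ape \"phylo\" object")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; a chronogram requires edge lengths in Myr")
  if (anyNA(phy$edge.length))
    stop("tree has missing branch lengths")
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed in a chronogram")
  n <- length(phy$tip.label)
  if (any(!nzchar(phy$tip.label)))
    stop("tip labels must be non-empty")
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }

  depth <- ape::node.depth.edgelength(phy)   # distance from the root
  root_age <- max(depth[seq_len(n)])
  if (root_age <= 0)
    stop("tree has zero depth")
  dev <- abs(depth[seq_len(n)] - root_age)
  worst <- which.max(dev)
  if (dev[worst] / root_age > tol)
    stop(sprintf(paste0(
      "tree is not ultrametric: root-to-tip path for '%s' is %.9g ",
      "against a root age of %.9g (relative discrepancy %.3g > tolerance %g)"),
      phy$tip.label[worst], depth[worst], root_age, dev[worst] / root_age, tol))

  node_age <- root_age - depth
  node_age[seq_len(n)] <- 0          # tips are at the present by definition

  Nnode <- phy$Nnode
  outdeg <- tabulate(phy$edge[, 1], nbins = n + Nnode)
  root <- n + 1L
  mult <- pmax(outdeg - 1L, 0L)      # branching events carried by each node
  ev_nodes <- rep.int(seq_len(n + Nnode), mult)
  ev_ages_all <- node_age[ev_nodes]
  # The root split is conditioned on (it carries no rate factor): drop one
  # event belonging to the root node.
  drop1 <- match(root, ev_nodes)
  ev_nonroot <- if (is.na(drop1)) ev_ages_all else ev_ages_all[-drop1]

  structure(list(
    phy = phy,
    n = n,
    Nnode = Nnode,
    root_age = root_age,
    node_age = node_age,
    tol = tol,
    event_ages_all = sort(ev_ages_all, decreasing = TRUE),
    event_ages = sort(ev_nonroot, decreasing = TRUE),
    edge_parent_age = node_age[phy$edge[, 1]],
    edge_child_age = node_age[phy$edge[, 2]]
  ), class = "chronogram")
}

#' @rdname chronogram
#' @param source path to a Newick file, or a Newick string.
#' @export
read_chronogram <- function(source, tol = 1e-6) {
  if (!is.character(source) || length(source) != 1L)
    stop("'source' must be a single file path or Newick string")
  phy <- tryCatch(suppressWarnings(
    if (file.exists(source)) ape::read.tree(file = source)
    else ape::read.tree(text = source)),
    error = function(e) NULL)
  if (is.null(phy))
    stop("failed to parse Newick input: ", source)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("input contains ", length(phy), " trees; expected exactly one")
    phy <- phy[[1L]]
  }
  chronogram(phy, tol = tol)
}

#' @rdname chronogram
#' @param x a `chronogram`.
#' @param file output path.
#' @export
write_chronogram <- function(x, file) {
  stopifnot(inherits(x, "chronogram"))
  ape::write.tree(x$phy, file = file)
  invisible(file)
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("Chronogram: %d tips, root age %.4g Myr, %d branching events\n",
              x$n, x$root_age, length(x$event_ages_all)))
  invisible(x)
}

# Total edge length X = integral of N(t) dt over the tree.
total_branch_length <- function(x) sum(x$phy$edge.length)

# Lineage-time accumulated at ages <= a, i.e. the integral of N over the age
# band [0, a]; exact, via per-edge overlap. Vectorised over `a`.
lineage_time_below <- function(x, a) {
  vapply(a, function(ai)
    sum(pmax(0, pmin(x$edge_parent_age, ai) - x$edge_child_age)),
    numeric(1))
}

# Number of non-root branching events with age <= a (boundary inclusive:
# an event exactly at a counts as "younger"). Vectorised over `a`.
events_below <- function(x, a) {
  v <- sort(x$event_ages)            # ascending
  findInterval(a, v)
}

#' Branching times of a chronogram
#'
#' Ages (Myr before present) of all branching events, sorted from the root
#' toward the present. A multifurcation of out-degree `m` contributes `m - 1`
#' tied ages, so the vector always has `n - 1` entries for a tree with a
#' bifurcating root.
#'
#' @param x a [chronogram].
#' @return numeric vector of ages, descending; the first element is the root
#'   age.
#' @export
branching_times <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  if (x$n < 2)
    stop("branching times require at least 2 tips")
  x$event_ages_all
}

#' Lineage count through time
#'
#' Number of reconstructed-tree lineages alive at time `t` since the root.
#' The step function is right-continuous: an event occurring at time `t`
#' counts from `t` onward, which makes the exact identity
#' `integral of N(t) dt = sum of edge lengths` hold.
#'
#' @param x a [chronogram].
#' @param t time(s) since the root, in `[0, root_age]` (Myr).
#' @return integer vector of lineage counts, one per element of `t`.
#' @export
lineage_count <- function(x, t) {
  stopifnot(inherits(x, "chronogram"))
  if (!is.numeric(t) || anyNA(t))
    stop("'t' must be numeric")
  eps <- x$tol * max(x$root_age, 1)
  if (any(t < -eps | t > x$root_age + eps))
    stop("'t' outside [0, root_age]")
  a <- x$root_age - t                # event at age a counts for ages <= a
  vapply(a, function(ai) 1L + sum(x$event_ages_all >= ai), integer(1))
}

#' Pairwise divergence (MRCA age) matrix
#'
#' The divergence between two species is the age of their most recent common
#' ancestor in Myr (not twice that age). On an ultrametric tree the matrix
#' satisfies the three-point condition: for any triple, the two largest
#' pairwise entries are equal.
#'
#' @param x a [chronogram].
#' @return a symmetric `n x n` numeric matrix with zero diagonal, labelled by
#'   tip names.
#' @export
divergence_matrix <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  lab <- x$phy$tip.label
  if (x$n == 1)
    return(matrix(0, 1, 1, dimnames = list(lab, lab)))
  mr <- ape::mrca(x$phy)
  d <- matrix(x$node_age[mr], x$n, x$n, dimnames = list(lab, lab))
  diag(d) <- 0
  d
}

#' Partition tips into clades younger than a divergence threshold
#'
#' Groups the tips into maximal blocks whose most recent common ancestor is
#' younger than `threshold` Myr. Tips with no relative below the threshold
#' form singleton blocks. Because the tree is ultrametric, the blocks are
#' exactly the connected components of the graph linking species whose
#' pairwise divergence is below the threshold.
#'
#' @param x a [chronogram].
#' @param threshold divergence threshold in Myr (strictly positive; may be
#'   `Inf`, giving a single block).
#' @return a list of character vectors of tip labels; blocks are disjoint and
#'   cover all tips.
#' @export
clades_below_threshold <- function(x, threshold) {
  stopifnot(inherits(x, "chronogram"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0)
    stop("divergence threshold must be a single positive number of Myr")
  idx <- clade_blocks_index(x, threshold)
  lapply(idx, function(i) x$phy$tip.label[i])
}

# Same partition, as integer tip indices (internal workhorse).
clade_blocks_index <- function(x, threshold) {
  n <- x$n
  if (n == 1) return(list(1L))
  phy <- x$phy
  m <- n + x$Nnode
  parent <- rep(NA_integer_, m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  age <- x$node_age
  root <- n + 1L

  # accumulate descendant tips in postorder (children before parents)
  tips_below <- vector("list", m)
  tips_below[seq_len(n)] <- as.list(seq_len(n))
  eo <- ape::postorder(phy)
  for (e in eo) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }

  # block roots: age < threshold and (node is the root or parent age >= threshold)
  cand <- which(age < threshold &
                (seq_len(m) == root | age[parent] >= threshold))
  blocks <- tips_below[cand]
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, min, integer(1)))]
}
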