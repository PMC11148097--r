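#' Euclidean distance matrix between regional profiles
#'
#' Pairwise Euclidean distances between sample rows (tumor regions plus the
#' matched normal) over a common feature set. For binary alteration rows
#' the Euclidean distance equals the square root of the Hamming distance;
#' the normal sample enters as an all-zero alteration row for the mutation
#' and CNV layers and as its measured profile for methylation.
#'
#' @param rows numeric matrix with one row per sample (rownames are sample
#'   ids) and aligned feature columns.
#' @return Symmetric numeric matrix with zero diagonal and the sample ids
#'   as dimnames.
#' @export
euclidean_distances <- function(rows) {
  rows <- as.matrix(rows)
  if (is.null(rownames(rows))) stop("rows must be labelled with sample ids")
  if (any(!is.finite(rows))) stop("profiles must be finite")
  as.matrix(stats::dist(rows, method = "euclidean"))
}

# All unrooted binary topologies on n labelled leaves, built by stepwise
# leaf addition: each k-th leaf subdivides one existing edge. Leaves are
# 1..n, internal nodes n+1..2n-2 (assigned in insertion order). Returns a
# list of edge matrices (2 columns, node ids).
.enumerate_topologies <- function(n) {
  stopifnot(n >= 3L)
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                 ncol = 2L, byrow = TRUE)
  topos <- list(base)
  if (n == 3L) return(topos)
  for (k in 4L:n) {
    new_node <- n + (k - 2L)
    topos <- unlist(lapply(topos, function(ed) {
      lapply(seq_len(nrow(ed)), function(i) {
        a <- ed[i, 1L]; b <- ed[i, 2L]
        rbind(ed[-i, , drop = FALSE],
              c(a, new_node), c(new_node, b), c(new_node, k))
      })
    }), recursive = FALSE)
  }
  topos
}

# Leaf-pair x edge incidence matrix: entry 1 iff the edge lies on the path
# between the pair. Paths found by BFS parent pointers from each leaf.
.path_incidence <- function(edges, n) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  pairs <- utils::combn(n, 2L)
  A <- matrix(0, ncol(pairs), nrow(edges))
  for (p in seq_len(ncol(pairs))) {
    from <- pairs[1L, p]; to <- pairs[2L, p]
    parent_edge <- integer(n_nodes)
    parent <- integer(n_nodes)
    seen <- logical(n_nodes)
    queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == to) break
      nb <- adj[[v]]
      for (j in seq_len(NROW(nb))) {
        w <- nb[j, 1L]
        if (!seen[w]) {
          seen[w] <- TRUE
          parent[w] <- v
          parent_edge[w] <- nb[j, 2L]
          queue <- c(queue, w)
        }
      }
    }
    v <- to
    while (v != from) {
      A[p, parent_edge[v]] <- 1
      v <- parent[v]
    }
  }
  A
}

# Canonical encoding of an unrooted topology: the sorted list of leaf-label
# splits induced by internal edges (smaller side, lexicographic). Used as a
# deterministic tie-break.
.topology_encoding <- function(edges, labels) {
  n <- length(labels)
  enc <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (edges[i, 1L] <= n || edges[i, 2L] <= n) next
    cut <- edges[-i, , drop = FALSE]
    # leaves reachable from one endpoint without crossing edge i
    reach <- edges[i, 1L]
    repeat {
      hit <- cut[, 1L] %in% reach | cut[, 2L] %in% reach
      nxt <- unique(c(cut[hit, 1L], cut[hit, 2L]))
      if (all(nxt %in% reach)) break
      reach <- unique(c(reach, nxt))
    }
    side <- sort(labels[intersect(reach, seq_len(n))])
    other <- sort(setdiff(labels, side))
    pick <- if (length(side) < length(other) ||
                (length(side) == length(other) &&
                 paste(side, collapse = ",") <
                 paste(other, collapse = ","))) side else other
    enc <- c(enc, paste(pick, collapse = ","))
  }
  paste(sort(enc), collapse = "|")
}

# Edge matrix (node ids as in .enumerate_topologies) -> ape "phylo".
.edges_to_phylo <- function(edges, lengths, labels) {
  n <- length(labels)
  root <- n + 1L
  # orient edges away from the root by BFS
  oriented <- matrix(0L, nrow(edges), 2L)
  elen <- numeric(nrow(edges))
  seen <- root
  queue <- root
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      w <- if (a == v && !(b %in% seen)) b else
        if (b == v && !(a %in% seen)) a else next
      k <- k + 1L
      oriented[k, ] <- c(v, w)
      elen[k] <- lengths[i]
      seen <- c(seen, w)
      queue <- c(queue, w)
    }
  }
  phy <- list(edge = oriented, tip.label = labels,
              Nnode = max(edges) - n, edge.length = elen)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' Minimum-evolution tree by exhaustive OLS search
#'
#' Builds the per-patient tree of tumor regions plus the matched normal by
#' the ordinary-least-squares minimum-evolution criterion: every unrooted
#' binary topology on the leaves is enumerated, branch lengths are fitted
#' to the distance matrix by least squares, negative fitted lengths are
#' clamped to zero, and the topology with the smallest total (clamped) tree
#' length wins. With at most 8 leaves the enumeration is exact (3
#' topologies at 4 leaves, 10,395 at 8), so no heuristic search is needed.
#' Ties are broken deterministically by a lexicographic encoding of the
#' topology's leaf splits, making the result invariant to leaf input order.
#'
#' @param dm symmetric distance matrix with zero diagonal and sample ids as
#'   dimnames (3 to 8 leaves), e.g. from \code{\link{euclidean_distances}}.
#'   Non-metric input is accepted; OLS handles it.
#' @param root_label leaf to use as the tree root (the normal sample), or
#'   \code{NULL} to leave the tree unrooted.
#' @param clamp_negative clamp negative OLS branch lengths to 0 (default);
#'   set \code{FALSE} to retain raw OLS lengths in the returned tree (the
#'   selection criterion still uses clamped totals).
#' @return Object of class \code{ith_tree}: list with \code{phy} (an
#'   \code{ape} \code{phylo}), \code{root_label}, \code{total_length}
#'   (sum of clamped branch lengths) and \code{ols_lengths} (raw fitted
#'   lengths of the winning topology).
#' @export
minimum_evolution_tree <- function(dm, root_label = NULL,
                                   clamp_negative = TRUE) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  n <- nrow(dm)
  if (is.null(labels) || is.null(colnames(dm))) {
    stop("distance matrix must have sample ids as dimnames")
  }
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)) ||
      any(abs(diag(dm)) > 1e-12) || any(!is.finite(dm))) {
    stop("distance matrix must be symmetric, finite, with zero diagonal")
  }
  if (n < 3L) stop("minimum evolution needs >= 3 leaves")
  if (n > 8L) {
    stop("exhaustive search supports at most 8 leaves; ",
         "use a heuristic tree builder for larger problems")
  }
  pairs <- utils::combn(n, 2L)
  dvec <- dm[cbind(pairs[1L, ], pairs[2L, ])]
  best <- NULL
  for (edges in .enumerate_topologies(n)) {
    A <- .path_incidence(edges, n)
    b <- qr.coef(qr(A), dvec)
    clamped <- pmax(b, 0)
    total <- sum(clamped)
    enc <- .topology_encoding(edges, labels)
    if (is.null(best) || total < best$total - 1e-12 ||
        (abs(total - best$total) <= 1e-12 && enc < best$enc)) {
      best <- list(edges = edges, b = b, clamped = clamped,
                   total = total, enc = enc)
    }
  }
  lengths <- if (clamp_negative) best$clamped else best$b
  phy <- .edges_to_phylo(best$edges, lengths, labels)
  if (!is.null(root_label)) {
    if (!root_label %in% labels) stop("root_label not among leaves")
    phy <- ape::root(phy, outgroup = root_label, resolve.root = FALSE)
  }
  structure(list(phy = phy, root_label = root_label,
                 total_length = best$total, ols_lengths = best$b),
            class = "ith_tree")
}

#' @export
print.ith_tree <- function(x, ...) {
  cat(sprintf("Minimum-evolution tree: %d leaves, total length %.4f\n",
              length(x$phy$tip.label), x$total_length))
  if (!is.null(x$root_label)) cat("  rooted at:", x$root_label, "\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Topological concordance of two trees
#'
#' Robinson-Foulds distance between the unrooted topologies of two trees on
#' the same leaf set (the number of leaf bipartitions present in one tree
#' but not the other). Two trees are called aligned iff the distance is 0,
#' i.e. their topologies agree exactly; branch lengths are ignored. Used to
#' compare each patient's phyloepigenetic tree with the phylogenetic tree.
#'
#' @param t1,t2 \code{ith_tree} objects (or \code{ape} \code{phylo}) with
#'   identical leaf sets.
#' @return List with \code{rf_distance} (integer) and \code{aligned}
#'   (logical).
#' @export
tree_concordance <- function(t1, t2) {
  p1 <- if (inherits(t1, "ith_tree")) t1$phy else t1
  p2 <- if (inherits(t2, "ith_tree")) t2$phy else t2
  if (!setequal(p1$tip.label, p2$tip.label)) {
    stop("trees have different leaf sets")
  }
  rf <- as.numeric(ape::dist.topo(ape::unroot(p1), ape::unroot(p2),
                                  method = "PH85"))
  list(rf_distance = rf, aligned = rf == 0)
}
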