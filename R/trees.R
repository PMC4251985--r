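#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering. At each step the pair of clusters
#' at minimal distance is merged at node height equal to half the merging
#' distance, so the result is ultrametric; after a merge, distances to the new
#' cluster are size-weighted averages. Ties are broken by merging the pair
#' whose (lexicographically sorted) representative labels are smallest, making
#' the topology deterministic.
#'
#' @param d Symmetric distance matrix with labels as dimnames (e.g. from
#'   \code{\link{distance_matrix}}); all entries must be finite.
#' @return An \code{ape} \code{phylo} tree (rooted, ultrametric).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(d))  # ((A:1,B:1):1,C:2);
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values (infinite distances are refused)")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  ## active clusters: newick fragment, size, height, representative label
  nwk <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_lab <- labels
  active <- rep(TRUE, n)
  dd <- d
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        i <- idx[a]; j <- idx[b]
        v <- dd[i, j]
        if (v < best_d - 1e-12) {
          best_d <- v
          best <- c(i, j)
        } else if (abs(v - best_d) <= 1e-12) {
          cand <- sort(c(rep_lab[i], rep_lab[j]))
          cur <- sort(c(rep_lab[best[1]], rep_lab[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    if (rep_lab[j] < rep_lab[i]) { tmp <- i; i <- j; j <- tmp }
    h <- best_d / 2
    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], h - height[i],
                       nwk[j], h - height[j])
    ## size-weighted average linkage update, written into slot i
    others <- setdiff(idx, c(i, j))
    for (k in others) {
      dd[i, k] <- (size[i] * dd[i, k] + size[j] * dd[j, k]) / (size[i] + size[j])
      dd[k, i] <- dd[i, k]
    }
    nwk[i] <- new_nwk
    height[i] <- h
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active[j] <- FALSE
  }
  tree <- ape::read.tree(text = paste0(nwk[which(active)], ";"))
  tree
}

#' Attach bootstrap support to a tree
#'
#' Annotates each internal node of \code{main} with the percentage of
#' replicate trees containing the same tip clade (rooted bipartition).
#' Supports are stored as internal node labels, the conventional Newick slot.
#'
#' @param main A rooted \code{phylo} tree.
#' @param reps List of replicate \code{phylo} trees on the same tip set.
#' @return \code{main} with \code{node.label} set to percentages in [0, 100].
#' @export
bootstrap_support <- function(main, reps) {
  stopifnot(inherits(main, "phylo"))
  tipset <- sort(main$tip.label)
  clade_keys <- function(tr) {
    n <- length(tr$tip.label)
    keys <- character(tr$Nnode)
    for (k in seq_len(tr$Nnode)) {
      node <- n + k
      tips <- tr$tip.label[tip_descendants(tr, node)]
      keys[k] <- paste(sort(tips), collapse = "\r")
    }
    keys
  }
  rep_keys <- lapply(reps, function(tr) {
    if (!identical(sort(tr$tip.label), tipset)) {
      stop("replicate tree has a different tip set")
    }
    clade_keys(tr)
  })
  main_keys <- clade_keys(main)
  counts <- vapply(main_keys, function(key) {
    sum(vapply(rep_keys, function(ks) key %in% ks, logical(1)))
  }, numeric(1))
  main$node.label <- as.character(round(100 * counts / length(reps), 1))
  main
}

## tip indices below a node (node may itself be a tip)
tip_descendants <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_descendants, tr = tr))
}

#' Prune a tree to a tip subset
#'
#' Induced subtree on \code{keep}: removed tips are dropped, unary nodes are
#' suppressed with their branch lengths summed, so root-to-tip heights of the
#' kept tips (and hence ultrametricity) are preserved. Any regime painting is
#' dropped; repaint after pruning.
#'
#' @param tree A \code{phylo} tree.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned \code{phylo} tree.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (!is.null(attr(tree, "regimes"))) {
    message("regime painting dropped by pruning; repaint with paint_regimes()")
  }
  out <- ape::keep.tip(tree, keep)
  attr(out, "regimes") <- NULL
  attr(out, "root_regime") <- NULL
  class(out) <- "phylo"
  out
}

#' Paint selective regimes onto a tree
#'
#' Assigns a regime label to every branch given tip regimes. Under the
#' \code{"stem"} rule, a branch gets regime \code{r} iff all tips descending
#' from it carry \code{r} (the regime runs from the clade's stem down); all
#' remaining branches, and the root itself, take \code{root_regime}. Under
#' \code{"parsimony"}, interior states are assigned by Fitch parsimony with
#' ties resolved towards the parent state (and the root tie towards
#' \code{root_regime} when given, otherwise the first state in the tie).
#'
#' @param tree A rooted \code{phylo} tree.
#' @param tip_regimes Named character vector mapping every tip label to a
#'   regime.
#' @param interior_rule \code{"stem"} or \code{"parsimony"}.
#' @param root_regime Regime for the root (and, under \code{"stem"}, for
#'   mixed branches). Defaults to the most frequent tip regime.
#' @return The tree with class \code{c("regime_tree", "phylo")} and attributes
#'   \code{regimes} (character, one per edge, in \code{tree$edge} order) and
#'   \code{root_regime}.
#' @export
paint_regimes <- function(tree, tip_regimes,
                          interior_rule = c("parsimony", "stem"),
                          root_regime = NULL) {
  interior_rule <- match.arg(interior_rule)
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(tree$tip.label, names(tip_regimes))
  if (length(missing_tips)) {
    stop("tip(s) without regime: ", paste(missing_tips, collapse = ", "))
  }
  tip_regimes <- tip_regimes[tree$tip.label]
  if (is.null(root_regime)) {
    tab <- sort(table(tip_regimes), decreasing = TRUE)
    root_regime <- names(tab)[1]
  }
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- n + 1L
  states <- unique(c(tip_regimes, root_regime))
  node_state <- character(n + nnode)
  node_state[seq_len(n)] <- tip_regimes
  if (interior_rule == "stem") {
    for (nd in seq.int(n + 1L, n + nnode)) {
      tips <- tip_descendants(tree, nd)
      r <- unique(tip_regimes[tips])
      node_state[nd] <- if (length(r) == 1L) r else root_regime
    }
    node_state[root] <- root_regime
  } else {
    ## Fitch: postorder state sets, then preorder resolution toward parent
    sets <- vector("list", n + nnode)
    for (i in seq_len(n)) sets[[i]] <- tip_regimes[i]
    post <- postorder_nodes(tree)
    for (nd in post) {
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      s <- Reduce(intersect, lapply(kids, function(k) sets[[k]]))
      if (!length(s)) s <- Reduce(union, lapply(kids, function(k) sets[[k]]))
      sets[[nd]] <- s
    }
    root_set <- sets[[root]]
    node_state[root] <- if (root_regime %in% root_set) root_regime else root_set[1]
    pre <- rev(post)
    for (nd in pre) {
      if (nd == root) next
      parent <- tree$edge[tree$edge[, 2] == nd, 1]
      node_state[nd] <- if (node_state[parent] %in% sets[[nd]]) {
        node_state[parent]
      } else {
        sets[[nd]][1]
      }
    }
  }
  ## a branch carries the regime of its child node
  regimes <- node_state[tree$edge[, 2]]
  attr(tree, "regimes") <- regimes
  attr(tree, "root_regime") <- node_state[root]
  class(tree) <- c("regime_tree", "phylo")
  tree
}

## internal nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  n <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  unique(ord$edge[, 1])
}

#' @export
print.regime_tree <- function(x, ...) {
  reg <- attr(x, "regimes")
  cat(sprintf("Regime-painted ultrametric tree: %d tips, regimes: %s (root: %s)\n",
              length(x$tip.label),
              paste(sprintf("%s (%d branches)", names(table(reg)), table(reg)),
                    collapse = ", "),
              attr(x, "root_regime")))
  invisible(x)
}

#' Regime labels of a painted tree
#'
#' @param tree A tree painted by \code{\link{paint_regimes}}.
#' @return Character vector of per-edge regimes (in \code{tree$edge} order).
#' @export
regimes <- function(tree) {
  r <- attr(tree, "regimes")
  if (is.null(r)) stop("tree has no regime painting; use paint_regimes()")
  r
}

#' Rescale total tree height
#'
#' Multiplies all branch lengths so that the root-to-tip height equals
#' \code{height}. Fitting on height-1 trees puts Brownian rates and OU
#' selection strengths in tree-height units, making fits comparable across
#' distance metrics. Zero-length terminal branches are floored at
#' \code{1e-8 * height} to keep trait covariance matrices positive definite.
#'
#' @param tree An ultrametric \code{phylo} tree.
#' @param height Target height (default 1).
#' @return Rescaled tree (regime attributes preserved).
#' @export
rescale_tree_height <- function(tree, height = 1) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_along(tree$tip.label)])
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length * height / h
  tips <- tree$edge[, 2] <= length(tree$tip.label)
  floorlen <- 1e-8 * height
  tree$edge.length[tips] <- pmax(tree$edge.length[tips], floorlen)
  tree
}

#' Write a regime painting to a sidecar CSV
#'
#' Serializes per-branch regimes as (parent node, child node, regime) rows
#' plus a root-regime row, the companion of Newick output for painted trees.
#'
#' @param tree A regime-painted tree.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_regimes <- function(tree, path) {
  reg <- regimes(tree)
  df <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                   regime = reg, stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(parent = NA, child = length(tree$tip.label) + 1L,
                             regime = attr(tree, "root_regime")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
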