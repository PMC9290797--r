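# Topology weighting on per-window neighbour-joining trees.
#
# For each window: pairwise Hamming distances between phased haplotypes, an
# NJ tree, then quartet sampling with one haplotype per group (outgroup O,
# west W, east E, focal introduced I). The quartet topology inside the tree
# is read off the tip path distances: for leaves {a,b,c,d} the bipartition
# {a,b}|{c,d} holds iff d(a,b)+d(c,d) is the strictly smallest of the three
# pair sums (exact on a tree metric); a three-way tie means a zero-length
# internal edge, i.e. unresolved.
#   topology 1  (O,E)|(W,I)  focal shares west ancestry
#   topology 2  (O,W)|(E,I)  focal shares east ancestry
#   topology 3  (O,I)|(W,E)  focal diverged before the west/east split

#' Group assignment for topology weighting
#'
#' @param outgroup,west,east,focal character vectors of haplotype ids (tree
#'   tip labels), pairwise disjoint and non-empty.
#' @return A \code{topo_groups} list.
#' @export
topo_groups <- function(outgroup, west, east, focal) {
  g <- list(outgroup = as.character(outgroup), west = as.character(west),
            east = as.character(east), focal = as.character(focal))
  if (any(lengths(g) == 0)) stop("every topology group must be non-empty")
  all <- unlist(g, use.names = FALSE)
  if (anyDuplicated(all)) stop("topology groups must be disjoint")
  structure(g, class = "topo_groups")
}

#' Pairwise Hamming distance matrix for a window
#'
#' Entry (i, j) is the proportion of sites in the window, non-missing in both
#' haplotypes, at which i and j differ; missing sites are excluded from that
#' pair's denominator only.
#'
#' @param hm a \code{\link{hapmat}}.
#' @param window one window-table row (must contain at least one SNP).
#' @param haplotypes haplotype ids to include (default: all).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
window_distance_matrix <- function(hm, window, haplotypes = NULL) {
  idx <- window_site_idx(window)
  if (!length(idx)) stop("window has no SNPs")
  if (is.null(haplotypes)) haplotypes <- haplotype_ids(hm)
  rows <- match(haplotypes, rownames(hm$alleles))
  if (anyNA(rows))
    stop("unknown haplotype(s): ",
         paste(haplotypes[is.na(rows)], collapse = ", "))
  if (length(rows) < 4L) stop("need at least 4 haplotypes")
  if (!is.null(hm$unphased) && any(hm$unphased[rows, idx]))
    stop("window contains unphased heterozygous calls; re-read the VCF with ",
         "random_phase_seed to use haplotype-based statistics")
  a <- hm$alleles[rows, idx, drop = FALSE]
  m1 <- (a == 1L) + 0; m1[is.na(m1)] <- 0
  m0 <- (a == 0L) + 0; m0[is.na(m0)] <- 0
  diffs <- m1 %*% t(m0) + m0 %*% t(m1)
  comp <- tcrossprod(m0 + m1)
  if (any(comp == 0 & upper.tri(comp))) {
    bad <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)[1L, ]
    stop("haplotype pair with zero comparable sites: ",
         haplotypes[bad[1L]], " / ", haplotypes[bad[2L]])
  }
  d <- diffs / comp
  diag(d) <- 0
  dimnames(d) <- list(haplotypes, haplotypes)
  d
}

#' Neighbour-joining tree
#'
#' Standard NJ agglomeration. Ties in the Q criterion are broken by the
#' lowest (row, column) index pair, making the output deterministic on
#' degenerate inputs; negative branch lengths are floored at 0.
#'
#' @param d symmetric non-negative distance matrix, at least 4 taxa, with
#'   dimnames as tip labels.
#' @return An unrooted binary \code{ape::phylo} tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  N <- nrow(d)
  if (N < 4L) stop("need at least 4 taxa (quartets require 4)")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(N))
  active <- seq_len(N)          # node ids of active clusters (tips 1..N)
  D <- unname(d)
  next_internal <- N + 1L
  edge_p <- edge_c <- integer(0); edge_l <- numeric(0)
  while (length(active) > 3L) {
    n <- length(active)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]  # lowest (row, col)
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    u <- next_internal; next_internal <- next_internal + 1L
    edge_p <- c(edge_p, u, u)
    edge_c <- c(edge_c, active[i], active[j])
    edge_l <- c(edge_l, max(li, 0), max(lj, 0))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    active <- c(active[keep], u)
  }
  # final star join of the remaining three clusters
  u <- next_internal
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edge_p <- c(edge_p, u, u, u)
  edge_c <- c(edge_c, active)
  edge_l <- c(edge_l, pmax(c(l1, l2, l3), 0))
  # renumber internal nodes: root (created last) -> N+1, ancestors < descendants
  n_int <- u - N
  remap <- function(x) ifelse(x > N, N + n_int - (x - N) + 1L, x)
  tr <- structure(list(edge = cbind(remap(edge_p), remap(edge_c)),
                       edge.length = edge_l,
                       tip.label = labels,
                       Nnode = n_int),
                  class = "phylo", order = NULL)
  ape::reorder.phylo(tr, "cladewise")
}

#' Quartet topology of four leaves within a tree
#'
#' Prunes (implicitly, via tip path distances) to leaves \code{o, w, e, i}
#' and reports which rooted topology the internal-edge bipartition supports:
#' 1 = \{O,E\}|\{W,I\} (focal sister to west), 2 = \{O,W\}|\{E,I\},
#' 3 = \{O,I\}|\{W,E\}; a zero-length internal edge is \code{"unresolved"}.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param o,w,e,i tip labels (outgroup, west, east, focal).
#' @return 1, 2, 3 or the string \code{"unresolved"}.
#' @export
quartet_topology <- function(tree, o, w, e, i) {
  tips <- c(o, w, e, i)
  ix <- match(tips, tree$tip.label)
  if (anyNA(ix)) stop("leaf absent from tree: ",
                      paste(tips[is.na(ix)], collapse = ", "))
  H <- ape::dist.nodes(tree)
  s <- c(H[ix[1], ix[3]] + H[ix[2], ix[4]],   # {O,E}|{W,I}
         H[ix[1], ix[2]] + H[ix[3], ix[4]],   # {O,W}|{E,I}
         H[ix[1], ix[4]] + H[ix[2], ix[3]])   # {O,I}|{W,E}
  quartet_from_sums(s[1], s[2], s[3])
}

quartet_from_sums <- function(s1, s2, s3, tol = NULL) {
  s <- cbind(s1, s2, s3)
  m <- pmin(s[, 1], s[, 2], s[, 3])
  if (is.null(tol)) tol <- 1e-10 * (1 + m)
  near <- s <= m + tol
  out <- rep("unresolved", nrow(s))
  res <- rowSums(near) == 1L
  out[res] <- as.character(max.col(near[res, , drop = FALSE] * 1))
  if (length(out) == 1L && out != "unresolved") return(as.integer(out))
  out
}

#' Topology weights by quartet sampling
#'
#' Samples \code{n_subtrees} quartets, one haplotype per group, and reports
#' the proportion of resolved quartets supporting each topology (the "fixed"
#' subtree-sampling scheme). When the number of one-per-group combinations is
#' at most \code{n_subtrees} the quartets are enumerated exhaustively (the
#' result is then seed-independent); otherwise they are sampled uniformly
#' with replacement under \code{seed}. Unresolved quartets are excluded from
#' the weight denominator and reported as a separate fraction.
#'
#' @param tree an \code{ape::phylo} tree whose tips include all group members.
#' @param groups a \code{\link{topo_groups}}.
#' @param n_subtrees number of quartets to sample (default 600).
#' @param seed integer seed for the sampling branch.
#' @return A \code{topo_weights}: list with \code{weights} (named topo1/2/3,
#'   summing to 1 over resolved quartets), \code{unresolved} fraction,
#'   \code{n_subtrees}, \code{exhaustive}, \code{classification} (the
#'   strict >0.5 rule) and \code{score} (w1 - w2).
#' @export
topology_weights <- function(tree, groups, n_subtrees = 600L, seed = NULL) {
  stopifnot(inherits(groups, "topo_groups"), n_subtrees >= 1)
  ix <- lapply(groups, function(g) {
    m <- match(g, tree$tip.label)
    if (anyNA(m)) stop("group haplotype(s) absent from tree: ",
                       paste(g[is.na(m)], collapse = ", "))
    m
  })
  ntip <- length(tree$tip.label)
  H <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip)]
  ncomb <- prod(lengths(ix))
  exhaustive <- ncomb <= n_subtrees
  if (exhaustive) {
    gr <- expand.grid(o = ix$outgroup, w = ix$west, e = ix$east, i = ix$focal)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    gr <- data.frame(
      o = ix$outgroup[sample.int(length(ix$outgroup), n_subtrees, replace = TRUE)],
      w = ix$west[sample.int(length(ix$west), n_subtrees, replace = TRUE)],
      e = ix$east[sample.int(length(ix$east), n_subtrees, replace = TRUE)],
      i = ix$focal[sample.int(length(ix$focal), n_subtrees, replace = TRUE)])
  }
  topo <- quartet_from_sums(H[cbind(gr$o, gr$e)] + H[cbind(gr$w, gr$i)],
                            H[cbind(gr$o, gr$w)] + H[cbind(gr$e, gr$i)],
                            H[cbind(gr$o, gr$i)] + H[cbind(gr$w, gr$e)])
  n <- length(topo)
  counts <- c(sum(topo == "1"), sum(topo == "2"), sum(topo == "3"))
  nres <- sum(counts)
  w <- if (nres > 0) counts / nres else rep(NA_real_, 3L)
  names(w) <- c("topo1", "topo2", "topo3")
  out <- structure(list(weights = w, unresolved = 1 - nres / n,
                        n_subtrees = n, exhaustive = exhaustive),
                   class = "topo_weights")
  out$classification <- classify_window(out)
  out$score <- ancestry_score(out)
  out
}

#' @export
print.topo_weights <- function(x, ...) {
  cat(sprintf(
    "topo_weights: w = (%.3f, %.3f, %.3f), unresolved %.3f, n = %d%s -> %s (score %.3f)\n",
    x$weights[1], x$weights[2], x$weights[3], x$unresolved, x$n_subtrees,
    if (x$exhaustive) " (exhaustive)" else "", x$classification, x$score))
  invisible(x)
}

tw_weights <- function(weights) {
  if (inherits(weights, "topo_weights")) weights$weights else as.numeric(weights)
}

#' Classify a window from its topology weights
#'
#' \code{"topo<k>"} iff weight k strictly exceeds \code{threshold}
#' (the >50\% rule); otherwise \code{"ambiguous"}.
#'
#' @param weights a \code{topo_weights} or numeric vector of three weights.
#' @param threshold classification threshold (default 0.5, strict).
#' @return One of \code{"topo1"}, \code{"topo2"}, \code{"topo3"},
#'   \code{"ambiguous"}.
#' @export
classify_window <- function(weights, threshold = 0.5) {
  w <- tw_weights(weights)
  if (anyNA(w)) return("ambiguous")
  k <- which(w > threshold)
  if (length(k) == 1L) paste0("topo", k) else "ambiguous"
}

#' Ancestry score of a window
#'
#' Weight for the focal-sister-to-west topology minus the weight for the
#' focal-sister-to-east topology; +1 is pure west ancestry, -1 pure east.
#'
#' @param weights a \code{topo_weights} or numeric vector of three weights.
#' @return Score in [-1, 1] (NA when no quartet resolved).
#' @export
ancestry_score <- function(weights) {
  w <- tw_weights(weights)
  unname(w[1] - w[2])
}

#' Rank correlation of ancestry scores between two populations
#'
#' @param scoresA,scoresB per-window ancestry scores, paired by window.
#' @param method correlation method (default \code{"spearman"}).
#' @return List with \code{rho}, \code{p_value}, \code{n} (paired windows
#'   with both scores defined).
#' @export
ancestry_correlation <- function(scoresA, scoresB, method = "spearman") {
  stopifnot(length(scoresA) == length(scoresB))
  ok <- !is.na(scoresA) & !is.na(scoresB)
  if (sum(ok) < 3L) stop("need at least 3 paired windows with defined scores")
  ct <- suppressWarnings(
    stats::cor.test(scoresA[ok], scoresB[ok], method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Topology-weight scan over a window table
#'
#' Runs distance matrix + NJ + quartet sampling for every window with at
#' least one SNP. Per-window sampling seeds are \code{seed + window index},
#' so results do not depend on which windows are evaluated.
#'
#' @param hm a \code{\link{hapmat}} (phased).
#' @param windows window table (typically snp_count mode).
#' @param groups a \code{\link{topo_groups}} of haplotype ids.
#' @param n_subtrees quartets per window (default 600).
#' @param seed base seed.
#' @param trees if \code{TRUE}, also return newick strings per window.
#' @return data.frame: scaffold, start, end, n_snps, n_subtrees, topo1,
#'   topo2, topo3, unresolved, class, score (and \code{newick} if requested).
#' @export
topoweights_scan <- function(hm, windows, groups, n_subtrees = 600L,
                             seed = 1L, trees = FALSE) {
  haps <- unlist(groups, use.names = FALSE)
  nw <- nrow(windows)
  res <- data.frame(scaffold = windows$scaffold, start = windows$start,
                    end = windows$end, n_snps = windows$n_snps,
                    n_subtrees = NA_integer_, topo1 = NA_real_,
                    topo2 = NA_real_, topo3 = NA_real_,
                    unresolved = NA_real_, class = "ambiguous",
                    score = NA_real_, stringsAsFactors = FALSE)
  if (trees) res$newick <- NA_character_
  for (k in seq_len(nw)) {
    if (is.na(windows$snp_first[k]) || windows$n_snps[k] < 1L) next
    d <- window_distance_matrix(hm, windows[k, ], haps)
    tr <- nj_tree(d)
    tw <- topology_weights(tr, groups, n_subtrees = n_subtrees,
                           seed = seed + k)
    res$n_subtrees[k] <- tw$n_subtrees
    res[k, c("topo1", "topo2", "topo3")] <- as.list(tw$weights)
    res$unresolved[k] <- tw$unresolved
    res$class[k] <- tw$classification
    res$score[k] <- tw$score
    if (trees) res$newick[k] <- ape::write.tree(tr)
  }
  res
}
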