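#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Standard agglomeration: start from singletons and repeatedly merge the
#' pair of clusters with the smallest between-cluster dissimilarity
#' \eqn{D(A, B)} under the chosen linkage —
#' single: \eqn{\min d(x, y)}, complete: \eqn{\max d(x, y)}, average:
#' \eqn{(1/(n_A n_B)) \sum d(x, y)} over cross pairs \eqn{x \in A, y \in B}.
#' Between-cluster dissimilarities are maintained by the Lance-Williams
#' update (exactly equivalent to the definitions above). Ties on the
#' minimal \eqn{D(A, B)} are broken by the lowest smaller slot index, then
#' the lowest larger one, so dendrograms are bit-reproducible.
#'
#' @param d a square symmetric dissimilarity matrix (e.g. from
#'   \code{\link{dissimilarity}}).
#' @param linkage \code{"single"}, \code{"complete"} or \code{"average"}.
#' @return object of class \code{trait_dendrogram}: list with
#'   \code{merge} (hclust-style (n-1) x 2 matrix, negative entries =
#'   leaves), \code{height} (merge heights, non-decreasing), \code{labels},
#'   \code{linkage} and \code{measure} (if carried on \code{d}).
#' @export
hierarchical_cluster <- function(d, linkage = c("single", "complete", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2, ncol(d) == n)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dm <- d
  diag(dm) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  id <- -seq_len(n)              # hclust coding: negative leaf, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    sub <- dm
    sub[!active, ] <- Inf
    sub[, !active] <- Inf
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- h
    ## Lance-Williams update of D(new, C) for every other active cluster C
    upd <- switch(linkage,
      single   = pmin(dm[i, ], dm[j, ]),
      complete = pmax(dm[i, ], dm[j, ]),
      average  = (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) /
                 (sizes[i] + sizes[j]))
    dm[i, ] <- upd
    dm[, i] <- upd
    dm[i, i] <- Inf
    active[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    id[i] <- s
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage,
                 measure = attr(d, "measure")),
            class = "trait_dendrogram")
}

#' @export
print.trait_dendrogram <- function(x, ...) {
  cat(sprintf("trait_dendrogram: %d leaves, %s linkage%s\n",
              length(x$labels), x$linkage,
              if (!is.null(x$measure)) paste0(", ", x$measure, " measure") else ""))
  invisible(x)
}

#' Convert a trait dendrogram to a stats::hclust object
#' @param x a \code{trait_dendrogram}
#' @param ... unused
#' @return an object of class \code{hclust}
#' @export
as.hclust.trait_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { walk(x$merge[node, 1L]); walk(x$merge[node, 2L]) }
  }
  walk(n - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = x$linkage,
                 call = match.call(), dist.method = x$measure),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges; the resulting connected components are the
#' clusters. Cuts from one dendrogram are nested across k.
#'
#' @param dg a \code{\link{hierarchical_cluster}} result.
#' @param k number of clusters, 1..n.
#' @return named integer vector of cluster labels (1..k) per species.
#' @export
cut_tree <- function(dg, k) {
  stopifnot(inherits(dg, "trait_dendrogram"))
  n <- length(dg$labels)
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves")
  stats::cutree(as.hclust.trait_dendrogram(dg), k = k)
}

row_mins <- function(m) do.call(pmin, as.data.frame(m))

#' Partitioning around medoids (k-medoids)
#'
#' BUILD initialization (greedy: first the object minimizing total
#' dissimilarity, then the object with the largest reduction in cost)
#' followed by SWAP: repeatedly apply the single medoid/non-medoid exchange
#' that most reduces the total dissimilarity of objects to their nearest
#' medoid, until no exchange improves. Both phases are deterministic given
#' \code{d}; ties break on the lowest object index.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param k number of medoids, 2 <= k < n.
#' @param seed unused by the deterministic BUILD+SWAP path; kept so callers
#'   can treat all partitioners uniformly.
#' @return list with \code{clustering} (named integer vector, labels 1..k),
#'   \code{medoids} (object indices) and \code{cost} (total dissimilarity
#'   to assigned medoids).
#' @export
pam <- function(d, k, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")
  ## BUILD
  med <- which.min(colSums(d))
  nearest <- d[, med]
  while (length(med) < k) {
    gains <- vapply(seq_len(n), function(cand) {
      if (cand %in% med) return(-Inf)
      sum(pmax(nearest - d[, cand], 0))
    }, 0)
    med <- c(med, which.max(gains))
    nearest <- pmin(nearest, d[, med[length(med)]])
  }
  cost_of <- function(set) sum(row_mins(d[, set, drop = FALSE]))
  cost <- cost_of(med)
  ## SWAP (best improvement)
  repeat {
    best <- list(delta = 0)
    others <- setdiff(seq_len(n), med)
    for (mi in seq_along(med)) {
      rest <- d[, med[-mi], drop = FALSE]
      rest_min <- if (ncol(rest)) row_mins(rest) else rep(Inf, n)
      for (h in others) {
        newcost <- sum(pmin(rest_min, d[, h]))
        if (newcost < cost + best$delta - 1e-12) {
          best <- list(delta = newcost - cost, mi = mi, h = h)
        }
      }
    }
    if (best$delta >= 0) break
    med[best$mi] <- best$h
    cost <- cost + best$delta
  }
  med <- sort(med)
  assign <- apply(d[, med, drop = FALSE], 1L, which.min)
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  list(clustering = stats::setNames(as.integer(assign), labs),
       medoids = med, cost = cost_of(med))
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences between a merge's height and its
#' children's heights (leaves sit at height 0), giving an ultrametric tree
#' readable by standard phylogenetics tools.
#'
#' @param dg a \code{trait_dendrogram}.
#' @param file optional path; when given the string is written there.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when \code{file} is given.
#' @export
to_newick <- function(dg, file = NULL, digits = 10) {
  stopifnot(inherits(dg, "trait_dendrogram"))
  n <- length(dg$labels)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      lab <- gsub("[,;:() ]", "_", dg$labels[-node])
      sprintf("%s:%s", lab, format(parent_h, digits = digits))
    } else {
      h <- dg$height[node]
      sprintf("(%s,%s):%s",
              node_str(dg$merge[node, 1L], h),
              node_str(dg$merge[node, 2L], h),
              format(parent_h - h, digits = digits))
    }
  }
  root <- n - 1L
  h <- dg$height[root]
  nwk <- sprintf("(%s,%s);",
                 node_str(dg$merge[root, 1L], h),
                 node_str(dg$merge[root, 2L], h))
  if (!is.null(file)) { writeLines(nwk, file); return(invisible(nwk)) }
  nwk
}
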