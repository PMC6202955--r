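## Shannon entropy (nats) of a count vector, with 0 ln 0 = 0.
count_entropy <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

## Gini impurity 1 - sum p^2 of a count vector.
count_gini <- function(cnt) {
  p <- cnt / sum(cnt)
  1 - sum(p^2)
}

cluster_counts <- function(tm, part) {
  ids <- rownames(tm$values)
  if (!is.null(names(part))) {
    if (!setequal(names(part), ids)) stop("partition ids do not match the matrix")
    part <- part[ids]
  } else if (length(part) != nrow(tm$values)) {
    stop("partition length does not match the matrix")
  }
  split(seq_along(part), part)
}

## Size-weighted mean per-cluster per-trait impurity; the shared core of
## the entropy (WCE) and Gini within-cluster variability indices.
within_cluster_variability <- function(tm, part, impurity) {
  if (anyNA(tm$values)) stop("validity indices require a complete matrix")
  groups <- cluster_counts(tm, part)
  n <- nrow(tm$values); m <- ncol(tm$values)
  tot <- 0
  for (rows in groups) {
    ng <- length(rows)
    s <- 0
    for (j in seq_len(m)) {
      cnt <- tabulate(factor(tm$values[rows, j], levels = tm$codebook[[j]]),
                      nbins = length(tm$codebook[[j]]))
      s <- s + impurity(cnt)
    }
    tot <- tot + ng / (n * m) * s
  }
  tot
}

#' Within-cluster entropy coefficient (WCE)
#'
#' A compactness index for nominal partitions:
#' \deqn{WCE(k) = \sum_g \frac{n_g}{n m} \sum_c \left(-\sum_u
#'   \frac{n_{gcu}}{n_g} \ln \frac{n_{gcu}}{n_g}\right)}
#' where \eqn{n_{gcu}} counts objects in cluster g showing category u of
#' trait c, with \eqn{0 \ln 0 = 0}. Zero iff every cluster is single-valued
#' on every trait; lower means more within-cluster homogeneity, and for
#' nested cuts of one dendrogram it never increases as k grows.
#'
#' @param tm a complete \code{\link{trait_matrix}}.
#' @param part integer cluster labels (named by species id, or in matrix
#'   row order).
#' @return a single number >= 0.
#' @export
wce <- function(tm, part) within_cluster_variability(tm, part, count_entropy)

#' Gini within-cluster variability
#'
#' The Gini twin of \code{\link{wce}}: identical structure with the inner
#' Shannon entropy replaced by the Gini impurity
#' \eqn{1 - \sum_u (n_{gcu}/n_g)^2}.
#'
#' @inheritParams wce
#' @return a single number in [0, 1).
#' @export
gini_within <- function(tm, part) within_cluster_variability(tm, part, count_gini)

## Pseudo-F on a within-variability index v:
## (n - k) [n v(1) - n v(k)] / ((k - 1) n v(k)); the n factors cancel.
## v(k) = 0 with structure present is a perfect clustering: +Inf, which
## select_k ranks above every finite score.
pseudo_f <- function(v1, vk, n, k) {
  if (k < 2) return(NA_real_)
  if (vk == 0) return(if (v1 > 0) Inf else NA_real_)
  (n - k) * (v1 - vk) / ((k - 1) * vk)
}

#' Entropy pseudo-F (PSFE) across dendrogram cuts
#'
#' A separation index used to choose the number of clusters:
#' \deqn{PSFE(k) = \frac{(n-k)[nWCE(1) - nWCE(k)]}{(k-1)\, nWCE(k)}}
#' with \eqn{nWCE(k) = n \cdot WCE(k)} (the n factor cancels, so the index
#' is insensitive to that reading). Higher is better. A cut with
#' \eqn{WCE(k) = 0} is a perfect clustering and is reported as \code{Inf};
#' \eqn{WCE(1) = 0} (a structureless, constant matrix) gives \code{NA}.
#'
#' @param tm a complete \code{\link{trait_matrix}}.
#' @param cuts named list of partitions indexed by k (as from repeated
#'   \code{\link{cut_tree}} calls); k = 1 is computed internally if absent.
#' @return named numeric vector of PSFE values for each k >= 2 in
#'   \code{cuts}.
#' @export
psfe <- function(tm, cuts) {
  n <- nrow(tm$values)
  ks <- as.integer(names(cuts))
  if (anyNA(ks)) stop("`cuts` must be named by their k")
  w1 <- if (1L %in% ks) wce(tm, cuts[[which(ks == 1L)]])
        else wce(tm, rep(1L, n))
  out <- vapply(seq_along(cuts), function(i) {
    if (ks[i] < 2L) return(NA_real_)
    pseudo_f(w1, wce(tm, cuts[[i]]), n, ks[i])
  }, 0)
  names(out) <- ks
  out[ks >= 2L]
}

#' Successive WCE improvement (delta-WCE)
#'
#' \eqn{\Delta(k) = WCE(k-1) - WCE(k)} for consecutive k on nested cuts;
#' a larger value marks a larger drop in within-cluster variability when
#' moving to k clusters. Non-negative on nested cuts.
#'
#' @param k integer vector of consecutive cluster counts.
#' @param wce_values WCE values aligned with \code{k}.
#' @return named numeric vector of differences for each k from the second
#'   element on.
#' @export
delta_wce <- function(k, wce_values) {
  k <- as.integer(k)
  if (length(k) != length(wce_values)) stop("k and wce_values lengths differ")
  o <- order(k)
  k <- k[o]; wce_values <- wce_values[o]
  if (length(k) < 2L) stop("need at least two consecutive k")
  if (any(diff(k) != 1L)) stop("k values must be consecutive")
  stats::setNames(-diff(wce_values), k[-1L])
}

#' Choose the number of clusters by maximal PSFE
#'
#' Argmax of PSFE over the candidate k; ties go to the smallest k, and an
#' infinite PSFE (perfect clustering) outranks every finite score.
#'
#' @param psfe_values named numeric vector of PSFE per k (names = k).
#' @param k_range candidate k values (default: all names).
#' @return the selected k (integer).
#' @export
select_k <- function(psfe_values, k_range = NULL) {
  ks <- as.integer(names(psfe_values))
  if (!is.null(k_range)) {
    keep <- ks %in% k_range
    psfe_values <- psfe_values[keep]; ks <- ks[keep]
  }
  ok <- !is.na(psfe_values)
  if (!any(ok)) stop("PSFE undefined for every candidate k")
  psfe_values <- psfe_values[ok]; ks <- ks[ok]
  o <- order(-psfe_values, ks)
  ks[o[1L]]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie): 1 for
#' identical partitions, about 0 for independent random ones (may be
#' negative). Symmetric and invariant to label permutation.
#'
#' @param p1,p2 integer cluster labels over the same objects; when both are
#'   named the objects are aligned by name.
#' @return a single number <= 1.
#' @export
adjusted_rand <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) stop("partitions cover different objects")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions cover different numbers of objects")
  }
  tab <- table(p1, p2)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)   # both partitions trivial (all-one-cluster)
  (sij - expected) / (maxi - expected)
}

#' Evaluate a grid of measure x linkage x k clusterings
#'
#' Runs hierarchical clustering for every requested dissimilarity measure
#' and linkage, cuts each dendrogram over the k grid, and tabulates the
#' internal validity indices: WCE and its Gini twin, the entropy and Gini
#' pseudo-F, and the successive WCE improvement. One row per
#' (measure, linkage, k); \code{optimal} flags the PSFE-maximal k within
#' each (measure, linkage).
#'
#' @param tm a complete \code{\link{trait_matrix}}.
#' @param measures subset of the five measure names.
#' @param linkages subset of \code{c("single", "complete", "average")}.
#' @param k_range integer vector of cluster counts to evaluate (>= 2).
#' @return object of class \code{evaluation_table} (a data.frame) with
#'   columns measure, linkage, k, wce, psfe, gini_w, gini_psf, delta_wce,
#'   optimal. The fitted dendrograms are attached as attribute
#'   \code{dendrograms} (named \code{measure.linkage}), the cut partitions
#'   as attribute \code{partitions} (named \code{measure.linkage.k}).
#' @export
evaluate_grid <- function(tm,
                          measures = c("sm", "eskin", "iof", "goodall", "lin"),
                          linkages = c("single", "complete", "average"),
                          k_range = 2:10) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("k_range must be >= 2")
  n <- nrow(tm$values)
  w1 <- wce(tm, rep(1L, n))
  g1 <- gini_within(tm, rep(1L, n))
  rows <- list(); dgs <- list(); parts <- list()
  ft <- build_frequency_table(tm)
  for (ms in measures) {
    d <- dissimilarity(tm, ms, ft = ft)
    for (lk in linkages) {
      dg <- hierarchical_cluster(d, lk)
      dgs[[paste(ms, lk, sep = ".")]] <- dg
      kk <- c(min(k_range) - 1L, k_range)   # one extra cut for delta
      wv <- numeric(length(kk)); gv <- numeric(length(kk))
      for (i in seq_along(kk)) {
        part <- if (kk[i] <= 1L) rep(1L, n) else cut_tree(dg, kk[i])
        if (kk[i] >= 2L)
          parts[[paste(ms, lk, kk[i], sep = ".")]] <- part
        wv[i] <- wce(tm, part)
        gv[i] <- gini_within(tm, part)
      }
      keep <- kk %in% k_range
      dl <- ifelse(diff(kk) == 1L, -diff(wv), NA_real_)  # only consecutive k
      df <- data.frame(
        measure = ms, linkage = lk, k = kk[keep],
        wce = wv[keep],
        psfe = vapply(which(keep), function(i) pseudo_f(w1, wv[i], n, kk[i]), 0),
        gini_w = gv[keep],
        gini_psf = vapply(which(keep), function(i) pseudo_f(g1, gv[i], n, kk[i]), 0),
        delta_wce = dl[keep[-1L]],
        stringsAsFactors = FALSE)
      best <- tryCatch(select_k(stats::setNames(df$psfe, df$k)),
                       error = function(e) NA_integer_)
      df$optimal <- !is.na(best) & df$k == best
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dendrograms") <- dgs
  attr(out, "partitions") <- parts
  class(out) <- c("evaluation_table", "data.frame")
  out
}
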