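#' Jaccard coefficient of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both sets are empty.
#'
#' @param a,b vectors treated as sets (duplicates ignored).
#' @return a number in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap cluster-wise stability of a k-medoids partition
#'
#' The reference partition is k-medoids (\code{\link{pam}}) on the full
#' data. Each replicate draws n species with replacement, rebuilds the
#' category frequencies and the dissimilarity matrix on the resample (so
#' frequency-based measures reflect the resample's composition), reruns
#' k-medoids, and records for every reference cluster the maximum Jaccard
#' coefficient against any replicate cluster. Set comparison uses the
#' unique species identities present in the resample: a species drawn
#' twice counts once, on both sides. A resample with fewer than k distinct
#' species is redrawn (and counted in \code{redraws}).
#'
#' A cluster whose mean Jaccard stays near 1 across replicates keeps its
#' membership under resampling — it is stable; low means and large spreads
#' mark clusters that dissolve.
#'
#' @param tm a complete \code{\link{trait_matrix}}.
#' @param measure dissimilarity measure name (see
#'   \code{\link{dissimilarity}}).
#' @param k number of clusters, 2 <= k < n.
#' @param B bootstrap replicates (default 100).
#' @param seed integer seed; identical seeds give identical reports.
#' @return object of class \code{stability_report}: list with
#'   \code{per_cluster} (data.frame: cluster, size, mean_jaccard,
#'   sd_jaccard, n_replicates), \code{jaccard} (B x k matrix of per-
#'   replicate maxima), \code{reference} (the reference partition),
#'   \code{config} and \code{redraws}.
#' @export
bootstrap_stability <- function(tm, measure = "goodall", k = 3, B = 100,
                                seed = 1L) {
  stopifnot(inherits(tm, "trait_matrix"), B >= 1)
  if (anyNA(tm$values)) stop("stability analysis needs a complete matrix")
  n <- nrow(tm$values)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")
  d_full <- dissimilarity(tm, measure)
  ref <- pam(d_full, k)$clustering
  ref_sets <- split(rownames(tm$values), ref)
  set.seed(seed)
  jac <- matrix(NA_real_, B, k)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= k) break
      redraws <- redraws + 1L
    }
    vals <- tm$values[idx, , drop = FALSE]
    rownames(vals) <- sprintf("bs%04d", seq_len(n))   # resample ids
    btm <- trait_matrix(vals, codebook = tm$codebook,
                        trait_function = tm$trait_function)
    bd <- dissimilarity(btm, measure)
    bpart <- pam(bd, k)$clustering
    orig_id <- rownames(tm$values)[idx]
    boot_sets <- lapply(split(seq_len(n), bpart),
                        function(rows) unique(orig_id[rows]))
    in_resample <- unique(orig_id)
    for (g in seq_len(k)) {
      ref_g <- intersect(ref_sets[[g]], in_resample)
      jac[b, g] <- max(vapply(boot_sets, jaccard, 0, a = ref_g))
    }
  }
  per_cluster <- data.frame(
    cluster = seq_len(k),
    size = as.integer(lengths(ref_sets)),
    mean_jaccard = colMeans(jac),
    sd_jaccard = apply(jac, 2L, stats::sd),
    n_replicates = B)
  structure(list(per_cluster = per_cluster, jaccard = jac, reference = ref,
                 config = list(measure = measure, k = k, B = B, seed = seed),
                 redraws = redraws),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("bootstrap stability: measure=%s, k=%d, B=%d\n",
              x$config$measure, x$config$k, x$config$B))
  print(x$per_cluster, digits = 3)
  invisible(x)
}
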