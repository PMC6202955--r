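#' Category frequency table of a complete trait matrix
#'
#' Per trait c and category u: the absolute count \eqn{f_c(u)} among the n
#' objects, the relative frequency \eqn{p_c(u) = f_c(u)/n}, and the
#' pair estimate \eqn{p2_c(u) = f_c(u)(f_c(u)-1)/(n(n-1))} — the
#' probability that two objects drawn without replacement both show
#' category u. Frequency-based measures (IOF, Goodall, Lin) are always
#' computed against the frequencies of the very matrix being compared,
#' so bootstrap resamples get their own tables.
#'
#' @param tm a complete \code{\link{trait_matrix}} (no missing cells).
#' @return object of class \code{frequency_table}: a named list per trait
#'   with components \code{f}, \code{p}, \code{p2} (named numeric vectors
#'   over the trait's category set) and attribute \code{n}.
#' @export
build_frequency_table <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (anyNA(tm$values))
    stop("frequency table requires a complete matrix (impute first)")
  n <- nrow(tm$values)
  ft <- lapply(seq_len(ncol(tm$values)), function(j) {
    cats <- tm$codebook[[j]]
    f <- table(factor(tm$values[, j], levels = cats))
    f <- stats::setNames(as.numeric(f), cats)
    list(f = f, p = f / n, p2 = f * (f - 1) / (n * (n - 1)))
  })
  names(ft) <- colnames(tm$values)
  attr(ft, "n") <- n
  class(ft) <- "frequency_table"
  ft
}

#' Pairwise dissimilarity of species under a nominal measure
#'
#' Computes the symmetric n-by-n dissimilarity matrix under one of the five
#' categorical measures. Writing \eqn{s_c(x, y)} for the per-trait
#' similarity between objects x and y on trait c (with \eqn{K_c}
#' categories, counts \eqn{f_c}, relative frequencies \eqn{p_c}):
#' \itemize{
#'   \item \code{sm} (simple matching, the nominal part of Gower's
#'     coefficient): 1 on a match, 0 on a mismatch.
#'   \item \code{eskin}: 1 on a match, \eqn{K_c^2 / (K_c^2 + 2)} on a
#'     mismatch — mismatches cost less on traits with many categories.
#'   \item \code{iof} (inverse occurrence frequency): 1 on a match,
#'     \eqn{1 / (1 + \ln f_c(x) \ln f_c(y))} on a mismatch — mismatches
#'     between frequent categories cost more.
#'   \item \code{goodall}: \eqn{1 - p2_c(x)} on a match, 0 on a mismatch —
#'     a match on a rare category counts for more (a globally unique
#'     category matches with similarity exactly 1).
#'   \item \code{lin}: \eqn{2 \ln p_c(x)} on a match,
#'     \eqn{2 \ln(p_c(x) + p_c(y))} on a mismatch, with the object-pair
#'     similarity \eqn{\sum_c s_c / \sum_c (\ln p_c(x_c) + \ln p_c(y_c))}.
#' }
#' For \code{sm}, \code{eskin}, \code{iof} and \code{goodall} the
#' object-pair similarity is the unweighted mean of \eqn{s_c} over the m
#' traits. Dissimilarity is \code{1 - similarity} by default (see
#' \code{transform}). All measures use the natural logarithm.
#'
#' @param tm a complete \code{\link{trait_matrix}}.
#' @param measure one of \code{"sm"}, \code{"eskin"}, \code{"iof"},
#'   \code{"goodall"}, \code{"lin"}.
#' @param ft optional \code{\link{build_frequency_table}} result; must have
#'   been built from \code{tm}. Recomputed when omitted.
#' @param transform similarity-to-dissimilarity transform: \code{"one_minus"}
#'   (default, \code{1 - S}, keeping the range [0, 1]) or \code{"inverse"}
#'   (\code{1/S - 1}, unbounded).
#' @return object of class \code{dissimilarity_matrix}: the numeric n-by-n
#'   matrix with species ids as dimnames and attributes \code{measure} and
#'   \code{transform}.
#' @examples
#' g <- generate_traits(synthetic_spec(n_species = 10, n_traits = 4,
#'                                     categories = 3, theta = 1), seed = 1)
#' d <- dissimilarity(g$tm, "goodall")
#' range(d)
#' @export
dissimilarity <- function(tm, measure = c("sm", "eskin", "iof", "goodall", "lin"),
                          ft = NULL,
                          transform = c("one_minus", "inverse")) {
  measure <- match.arg(measure)
  transform <- match.arg(transform)
  stopifnot(inherits(tm, "trait_matrix"))
  if (anyNA(tm$values)) stop("dissimilarity requires a complete matrix")
  if (is.null(ft)) ft <- build_frequency_table(tm)
  n <- nrow(tm$values); m <- ncol(tm$values)
  S <- matrix(0, n, n)
  if (measure == "lin") D_den <- matrix(0, n, n)
  for (j in seq_len(m)) {
    v <- tm$values[, j]
    K <- length(tm$codebook[[j]])
    match_jj <- outer(v, v, "==")
    sc <- switch(measure,
      sm = ifelse(match_jj, 1, 0),
      eskin = ifelse(match_jj, 1, K^2 / (K^2 + 2)),
      iof = {
        lf <- log(ft[[j]]$f[v])
        ifelse(match_jj, 1, 1 / (1 + outer(lf, lf)))
      },
      goodall = {
        p2 <- ft[[j]]$p2[v]
        ifelse(match_jj, 1 - p2, 0)
      },
      lin = {
        lp <- log(ft[[j]]$p[v])
        pv <- ft[[j]]$p[v]
        D_den <- D_den + outer(lp, lp, "+")
        ifelse(match_jj, 2 * lp[row(match_jj)],
               log(outer(pv, pv, "+")) * 2)
      })
    S <- S + sc
  }
  if (measure == "lin") {
    sim <- S / D_den
    deg <- D_den == 0
    if (any(deg)) {
      warning("degenerate Lin pair(s) with zero denominator; dissimilarity set to 0")
      sim[deg] <- 1
    }
  } else {
    sim <- S / m
  }
  d <- switch(transform, one_minus = 1 - sim, inverse = 1 / sim - 1)
  ## clamp tiny negative residue from floating point
  d[d < 0 & d > -1e-12] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(tm$values), rownames(tm$values))
  structure(d, measure = measure, transform = transform,
            class = c("dissimilarity_matrix", "matrix", "array"))
}
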