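#' Specify a synthetic nominal trait matrix with planted groups
#'
#' Describes a mixture of group-wise categorical distributions. Each group
#' has one preferred category per trait, carrying probability mass
#' \code{theta}; the remaining \code{1 - theta} is spread uniformly over the
#' other categories of that trait. \code{theta = 1} gives deterministic
#' group profiles; \code{theta = 1/K_c} gives no group signal on a trait
#' with \code{K_c} categories. Preferred categories are assigned cyclically
#' across traits so that no single trait separates all groups on its own,
#' mimicking the redundancy of real trait functions.
#'
#' The default mirrors the reference fish study conditions: 116 species,
#' 22 traits with the published per-trait category counts (the published
#' table lists 21 traits; a 22nd four-category trait is appended to match
#' the stated matrix size), and 3 planted groups.
#'
#' @param n_species number of species (rows).
#' @param n_traits number of traits (columns).
#' @param categories integer vector of category counts per trait (recycled
#'   to \code{n_traits}); every entry must be >= 2.
#' @param n_groups number of planted groups.
#' @param theta separability in [0, 1]: probability of a species drawing
#'   its group's preferred category on each trait.
#' @param missing_fraction MCAR missing-cell fraction in [0, 0.45] applied
#'   after generation.
#' @return an object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(n_species = 116, n_traits = 22,
                           categories = tbgb_category_counts(n_traits),
                           n_groups = 3, theta = 0.9,
                           missing_fraction = 0) {
  categories <- rep_len(as.integer(categories), n_traits)
  if (any(categories < 2L)) stop("every trait needs at least 2 categories")
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (missing_fraction < 0 || missing_fraction > 0.45)
    stop("missing_fraction must be in [0, 0.45]")
  if (n_groups < 1L || n_groups > n_species)
    stop("n_groups must be in [1, n_species]")
  structure(list(n_species = as.integer(n_species),
                 n_traits = as.integer(n_traits),
                 categories = categories,
                 n_groups = as.integer(n_groups),
                 theta = theta,
                 missing_fraction = missing_fraction),
            class = "synthetic_spec")
}

#' Per-trait category counts of the reference trait table
#'
#' Category counts taken from the packaged TBGB trait table, padded with
#' 4-category traits if more than its 21 rows are requested.
#'
#' @param n_traits how many counts to return.
#' @return integer vector of length \code{n_traits}.
#' @export
tbgb_category_counts <- function(n_traits = 22) {
  k <- vapply(tbgb_trait_table()$categories, length, 1L)
  c(k, rep(4L, max(0L, n_traits - length(k))))[seq_len(n_traits)]
}

#' Generate a synthetic trait matrix with known group structure
#'
#' Species are assigned to groups in balanced blocks (sizes differing by at
#' most one). Each cell is drawn independently from its group's categorical
#' distribution for that trait (see \code{\link{synthetic_spec}}). Fully
#' reproducible from \code{seed}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param seed integer seed controlling all randomness in the call.
#' @return list with elements \code{tm} (a complete
#'   \code{\link{trait_matrix}}, or with MCAR missing cells if the spec
#'   requests them) and \code{truth} (integer vector of planted group
#'   labels, 1..n_groups).
#' @examples
#' g <- generate_traits(synthetic_spec(n_species = 12, n_traits = 4,
#'                                     categories = 3, n_groups = 3,
#'                                     theta = 1), seed = 1)
#' table(g$truth)
#' @export
generate_traits <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_species; m <- spec$n_traits; K <- spec$categories
  g <- spec$n_groups
  set.seed(seed)
  truth <- sort(rep_len(seq_len(g), n))
  vals <- matrix(NA_character_, n, m,
                 dimnames = list(sprintf("sp%03d", seq_len(n)),
                                 sprintf("T%02d", seq_len(m))))
  codebook <- lapply(seq_len(m), function(j) sprintf("c%d_%d", j, seq_len(K[j])))
  names(codebook) <- colnames(vals)
  for (j in seq_len(m)) {
    cats <- codebook[[j]]
    ## cyclic preferred category so groups are not separable on one trait
    pref <- ((seq_len(g) - 1L + (j - 1L)) %% K[j]) + 1L
    for (gg in seq_len(g)) {
      rows <- which(truth == gg)
      p <- rep((1 - spec$theta) / (K[j] - 1L), K[j])
      p[pref[gg]] <- spec$theta
      vals[rows, j] <- sample(cats, length(rows), replace = TRUE, prob = p)
    }
  }
  tm <- trait_matrix(vals, codebook = codebook)
  if (spec$missing_fraction > 0) {
    tm <- ampute_mcar(tm, spec$missing_fraction,
                      seed = seed + 1000003L)$tm
  }
  list(tm = tm, truth = truth)
}

#' Delete cells completely at random (amputation)
#'
#' Masks exactly \code{round(proportion * n * m)} cells, chosen uniformly
#' without replacement and independently of cell values (MCAR), recording
#' the true values so that imputation accuracy can be scored.
#'
#' @param tm a complete \code{\link{trait_matrix}} (no missing cells in the
#'   targeted columns).
#' @param proportion fraction of cells to mask, in (0, 0.45].
#' @param seed integer seed; the same seed always yields the same mask.
#' @param allow_empty error (default) if a mask would leave a column with
#'   no observed values, or if the rounded cell count is zero; set
#'   \code{TRUE} to permit a zero-cell no-op mask.
#' @return list with \code{tm} (masked matrix) and \code{mask} (data.frame
#'   of \code{row}, \code{col}, \code{true} values of the masked cells).
#' @export
ampute_mcar <- function(tm, proportion, seed = 1L, allow_empty = FALSE) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (!(proportion > 0 && proportion <= 0.45))
    stop("proportion must be in (0, 0.45]")
  if (anyNA(tm$values)) stop("matrix already has missing cells")
  n <- nrow(tm$values); m <- ncol(tm$values)
  n_mask <- round(proportion * n * m)
  if (n_mask == 0L && !allow_empty)
    stop("proportion masks zero cells; set allow_empty = TRUE for a no-op")
  set.seed(seed)
  cells <- sample.int(n * m, n_mask)
  row <- ((cells - 1L) %% n) + 1L
  col <- ((cells - 1L) %/% n) + 1L
  if (any(tabulate(col, m) == n))
    stop("mask would empty an entire column; lower the proportion")
  vals <- tm$values
  true <- vals[cbind(row, col)]
  vals[cbind(row, col)] <- NA_character_
  list(tm = trait_matrix(vals, codebook = tm$codebook,
                         trait_function = tm$trait_function),
       mask = data.frame(row = row, col = col, true = true,
                         stringsAsFactors = FALSE))
}
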