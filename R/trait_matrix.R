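#' Construct a species-by-trait matrix of nominal values
#'
#' The central data container of the package: \code{n} species (rows) by
#' \code{m} nominal traits (columns), with an explicit per-trait category
#' set (the codebook) and \code{NA} marking missing cells. All downstream
#' stages (imputation, dissimilarity, clustering, validity indices) consume
#' this class.
#'
#' @param values character matrix; rownames are species ids, colnames trait
#'   names; \code{NA} marks a missing cell.
#' @param codebook named list mapping each trait name to its ordered
#'   character vector of allowed category labels. Defaults to the sorted
#'   observed labels per trait.
#' @param trait_function optional named character vector tagging each trait
#'   with its function class (\code{"diet"}, \code{"habitat"},
#'   \code{"morphology"} or \code{"life_history"}).
#' @return an object of class \code{trait_matrix}: a list with elements
#'   \code{values}, \code{codebook} and \code{trait_function}.
#' @examples
#' v <- matrix(c("A", "A", "B", "C", "X", "Y", "X", "X"), ncol = 2,
#'             dimnames = list(paste0("sp", 1:4), c("t1", "t2")))
#' tm <- trait_matrix(v)
#' n_species(tm); n_traits(tm)
#' @export
trait_matrix <- function(values, codebook = NULL, trait_function = NULL) {
  if (!is.matrix(values) || !is.character(values))
    stop("`values` must be a character matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("obj", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("trait", seq_len(ncol(values)))
  if (nrow(values) < 2L) stop("a trait matrix needs at least 2 species")
  if (ncol(values) < 1L) stop("a trait matrix needs at least 1 trait")
  if (anyDuplicated(rownames(values)))
    stop("duplicate species id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate trait name: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (is.null(codebook)) {
    codebook <- lapply(seq_len(ncol(values)), function(j)
      sort(unique(values[!is.na(values[, j]), j])))
    names(codebook) <- colnames(values)
  }
  missing_cb <- setdiff(colnames(values), names(codebook))
  if (length(missing_cb))
    stop("trait absent from codebook: ", paste(missing_cb, collapse = ", "))
  codebook <- codebook[colnames(values)]
  for (j in seq_len(ncol(values))) {
    obs <- values[, j]
    bad <- !is.na(obs) & !(obs %in% codebook[[j]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "label %s in row %s, column %s is outside the category set {%s}",
        dQuote(obs[i]), dQuote(rownames(values)[i]),
        dQuote(colnames(values)[j]),
        paste(codebook[[j]], collapse = ", ")))
    }
  }
  if (!is.null(trait_function)) trait_function <- trait_function[colnames(values)]
  structure(list(values = values, codebook = codebook,
                 trait_function = trait_function),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("trait_matrix: %d species x %d traits (%d missing cells)\n",
              nrow(x$values), ncol(x$values), nm))
  cat("categories per trait:",
      paste(vapply(x$codebook, length, 1L), collapse = " "), "\n")
  invisible(x)
}

#' Number of species (rows) in a trait matrix
#' @param tm a \code{trait_matrix}
#' @return integer count
#' @export
n_species <- function(tm) nrow(tm$values)

#' Number of traits (columns) in a trait matrix
#' @param tm a \code{trait_matrix}
#' @return integer count
#' @export
n_traits <- function(tm) ncol(tm$values)

## Rounds half away from zero, the display convention used for percent
## columns in trait tables (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a trait matrix and its codebook from CSV
#'
#' The data CSV has one species per row (first column = species id, header
#' row = trait names). The codebook CSV has columns \code{trait},
#' \code{function}, \code{type}, \code{categories} (\code{|}-separated) and
#' optionally \code{source}.
#'
#' @param path path to the data CSV.
#' @param codebook_path optional path to the codebook CSV. Without one the
#'   category sets are the observed labels (open sets).
#' @param missing_tokens character vector of cell values treated as missing.
#' @param open_sets if \code{TRUE}, labels observed in the data but absent
#'   from the codebook extend the category set; if \code{FALSE} (default)
#'   they are an error.
#' @return a \code{\link{trait_matrix}}
#' @export
read_trait_matrix <- function(path, codebook_path = NULL,
                              missing_tokens = c("", "NA"),
                              open_sets = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  if (ncol(df) < 2L) stop("data CSV must have a species-id column and >= 1 trait")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals %in% missing_tokens] <- NA_character_
  rownames(vals) <- ids
  cb <- NULL; fn <- NULL
  if (!is.null(codebook_path)) {
    cbdf <- read_codebook(codebook_path)
    cb <- cbdf$categories
    names(cb) <- cbdf$trait
    fn <- stats::setNames(cbdf$fun, cbdf$trait)
    absent <- setdiff(colnames(vals), names(cb))
    if (length(absent))
      stop("trait absent from codebook: ", paste(absent, collapse = ", "))
    if (open_sets) {
      for (j in colnames(vals)) {
        seen <- unique(vals[!is.na(vals[, j]), j])
        cb[[j]] <- c(cb[[j]], sort(setdiff(seen, cb[[j]])))
      }
    }
  }
  trait_matrix(vals, codebook = cb, trait_function = fn)
}

#' Read a codebook CSV
#'
#' @param path CSV with columns \code{trait}, \code{function}, \code{type},
#'   \code{categories} (\code{|}-separated), and optionally
#'   \code{missing_percent} and \code{source}.
#' @return data.frame with columns \code{trait}, \code{fun}, \code{type},
#'   \code{categories} (list column), plus any extra columns present.
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("trait", "function", "categories")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("codebook lacks columns: ", paste(miss, collapse = ", "))
  out <- data.frame(trait = df$trait, fun = df[["function"]],
                    type = if ("type" %in% names(df)) df$type else NA_character_,
                    stringsAsFactors = FALSE)
  out$categories <- strsplit(df$categories, "|", fixed = TRUE)
  if ("missing_percent" %in% names(df))
    out$missing_percent <- as.numeric(df$missing_percent)
  if ("source" %in% names(df)) out$source <- df$source
  out
}

#' Write a trait matrix (and optionally its codebook) to CSV
#'
#' Missing cells are written as the first element of \code{missing_token}.
#' A write followed by \code{\link{read_trait_matrix}} round-trips values,
#' category sets and missingness exactly.
#'
#' @param tm a \code{trait_matrix}
#' @param path output CSV path for the data.
#' @param codebook_path optional output CSV path for the codebook.
#' @param missing_token token written for missing cells.
#' @return invisibly, \code{path}.
#' @export
write_trait_matrix <- function(tm, path, codebook_path = NULL,
                               missing_token = "NA") {
  vals <- tm$values
  vals[is.na(vals)] <- missing_token
  df <- data.frame(species = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(codebook_path)) {
    fn <- tm$trait_function
    if (is.null(fn)) fn <- stats::setNames(rep("unspecified", n_traits(tm)),
                                           colnames(tm$values))
    cbdf <- data.frame(trait = colnames(tm$values),
                       "function" = unname(fn[colnames(tm$values)]),
                       type = "nominal",
                       categories = vapply(tm$codebook, paste, "",
                                           collapse = "|"),
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(cbdf, codebook_path, row.names = FALSE)
  }
  invisible(path)
}

#' Summarize per-trait missingness
#'
#' @param tm a \code{trait_matrix}
#' @return a \code{missingness_summary}: data.frame with columns
#'   \code{trait}, \code{n_missing}, \code{fraction} and \code{percent}
#'   (fraction x 100, rounded half away from zero to 1 decimal, the usual
#'   display convention), with attribute \code{n_complete_traits} = number
#'   of traits with no missing cells.
#' @export
summarize_missingness <- function(tm) {
  frac <- colMeans(is.na(tm$values))
  out <- data.frame(trait = colnames(tm$values),
                    n_missing = colSums(is.na(tm$values)),
                    fraction = unname(frac),
                    percent = unname(round_half_up(frac * 100, 1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_complete_traits") <- sum(frac == 0)
  class(out) <- c("missingness_summary", "data.frame")
  out
}

#' Drop traits with too much missing data
#'
#' Retains exactly the traits whose missing fraction is strictly below the
#' cutoff (default 0.25, the usual threshold beyond which categorical
#' imputation accuracy degrades badly for small data sets), preserving
#' column order.
#'
#' @param tm a \code{trait_matrix}
#' @param cutoff missing-fraction cutoff in (0, 1].
#' @return the filtered \code{trait_matrix}
#' @export
drop_high_missing_traits <- function(tm, cutoff = 0.25) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  frac <- colMeans(is.na(tm$values))
  keep <- which(frac < cutoff)
  if (!length(keep)) stop("no trait has missing fraction below the cutoff")
  trait_matrix(tm$values[, keep, drop = FALSE],
               codebook = tm$codebook[keep],
               trait_function = tm$trait_function[keep])
}

#' Define a binning rule for discretizing a continuous trait
#'
#' Intervals are closed on the right and open on the left, except that the
#' first interval is also closed below and the last is unbounded above:
#' with breakpoints \code{b1 < b2 < ... < bB} the bins are
#' \code{[min, b1]}, \code{(b1, b2]}, ..., \code{(bB, Inf)}. This
#' reproduces the familiar "0-20.1; 20.2-54.6; ...; 148.5+" display of
#' published category edges once values are reported to 1 decimal.
#'
#' @param trait name of the trait being binned.
#' @param breaks strictly increasing numeric breakpoints.
#' @param labels category labels, one more than there are breakpoints.
#' @return an object of class \code{binning_rule}
#' @export
binning_rule <- function(trait, breaks, labels) {
  breaks <- as.numeric(breaks)
  if (any(!is.finite(breaks))) stop("breakpoints must be finite")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  if (length(labels) != length(breaks) + 1L)
    stop("need exactly one more label than breakpoints")
  if (anyDuplicated(labels)) stop("labels must be unique")
  structure(list(trait = trait, breaks = breaks, labels = as.character(labels)),
            class = "binning_rule")
}

#' Discretize numeric values under a binning rule
#'
#' Total and deterministic on finite input: every value maps to exactly one
#' label; a value exactly on a breakpoint belongs to the lower bin (right-
#' closed convention).
#'
#' @param values numeric vector (finite).
#' @param rule a \code{\link{binning_rule}}.
#' @return character vector of category labels, same length as \code{values}.
#' @export
discretize <- function(values, rule) {
  if (!inherits(rule, "binning_rule")) stop("`rule` must be a binning_rule")
  if (any(!is.finite(values))) stop("values must be finite")
  idx <- findInterval(values, rule$breaks, left.open = FALSE) + 1L
  ## findInterval counts breaks <= x, so a value equal to a break lands one
  ## bin high; pull exact hits back down into the right-closed bin.
  exact <- match(values, rule$breaks)
  idx[!is.na(exact)] <- exact[!is.na(exact)]
  rule$labels[idx]
}

#' Suggest a log-scale equal-width binning rule
#'
#' Places breakpoints at equal widths on the natural-log scale spanning the
#' data, the strategy appropriate for right-skewed size-like traits (body
#' length, depth). Breakpoints are reported rounded to 1 decimal.
#'
#' @param values positive numeric vector.
#' @param n_bins number of bins, 4 or 5.
#' @param labels optional category labels (default \code{bin1..binK}).
#' @param trait trait name recorded in the rule.
#' @return a \code{\link{binning_rule}} with \code{n_bins - 1} breakpoints.
#' @export
suggest_bins <- function(values, n_bins, labels = NULL, trait = "trait") {
  if (!n_bins %in% c(4L, 5L)) stop("n_bins must be 4 or 5")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be finite and positive for log-width binning")
  if (length(unique(values)) < n_bins)
    stop("fewer distinct values than bins")
  lo <- log(min(values)); hi <- log(max(values))
  breaks <- exp(seq(lo, hi, length.out = n_bins + 1L))[2:n_bins]
  breaks <- round_half_up(breaks, 1)
  if (is.null(labels)) labels <- paste0("bin", seq_len(n_bins))
  binning_rule(trait, breaks, labels)
}

#' The published TBGB trait table, as packaged transcription
#'
#' Returns the packaged transcription of the Tasman Bay / Golden Bay fish
#' trait table: 21 retained traits with their function class, category
#' sets and percent missing. Used as the reference shape for synthetic
#' data and for missingness summaries.
#'
#' @return data.frame as from \code{\link{read_codebook}} with a
#'   \code{missing_percent} column.
#' @export
tbgb_trait_table <- function() {
  read_codebook(system.file("extdata", "tbgb_table1_traits.csv",
                            package = "nomtrait", mustWork = TRUE))
}

#' Canonical binning rules for the TBGB continuous traits
#'
#' The published log-width rules for maximum length and the two depth
#' traits share breakpoints \{20.1, 54.6, 148.4\} (= e^3, e^4, e^5 to one
#' decimal); maximum depth adds a fourth break at 403.4 (= e^6).
#'
#' @return named list of \code{\link{binning_rule}} objects.
#' @export
tbgb_binning_rules <- function() {
  list(
    `Maximum length (cm)` = binning_rule(
      "Maximum length (cm)", c(20.1, 54.6, 148.4),
      c("Small", "Medium", "Large", "Very large")),
    `Common maximum depth (m)` = binning_rule(
      "Common maximum depth (m)", c(20.1, 54.6, 148.4),
      c("Reef", "Shallow", "Ocean", "Deep")),
    `Maximum depth (m)` = binning_rule(
      "Maximum depth (m)", c(20.1, 54.6, 148.4, 403.4),
      c("Reef", "Shallow", "Ocean", "Deep", "Bathy"))
  )
}
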