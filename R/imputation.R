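#' Mode imputation
#'
#' Replaces every missing cell of a trait by that trait's most frequent
#' observed category. Ties go to the category listed first in the
#' codebook, so the result is deterministic. Observed cells are never
#' touched.
#'
#' @param tm a \code{\link{trait_matrix}}.
#' @return the completed \code{trait_matrix}.
#' @export
impute_mode <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  vals <- tm$values
  for (j in seq_len(ncol(vals))) {
    nas <- is.na(vals[, j])
    if (!any(nas)) next
    if (all(nas)) stop("trait ", colnames(vals)[j], " has no observed values")
    cnt <- table(factor(vals[!nas, j], levels = tm$codebook[[j]]))
    vals[nas, j] <- names(cnt)[which.max(cnt)]
  }
  trait_matrix(vals, codebook = tm$codebook, trait_function = tm$trait_function)
}

## Fit-and-predict for one trait given all others, multinomial logistic
## with a small ridge penalty (weight decay) to survive separation.
## Returns an n_missing x K probability matrix, or NULL on failure.
fit_polytomous_trait <- function(df, j, obs_rows, mis_rows, ridge) {
  resp <- df[[j]][obs_rows]
  if (length(unique(resp)) < 2L) return(NULL)
  fml <- stats::as.formula(paste0("`", names(df)[j], "` ~ ."))
  train <- df[obs_rows, , drop = FALSE]
  train[[j]] <- droplevels(train[[j]])    # unobserved categories can't be fit
  fit <- tryCatch(
    nnet::multinom(fml, data = train,
                   decay = ridge, trace = FALSE, maxit = 200,
                   MaxNWts = 10000),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  pr <- stats::predict(fit, newdata = df[mis_rows, , drop = FALSE],
                       type = "probs")
  lv <- levels(df[[j]])
  used <- fit$lev
  if (is.null(dim(pr))) {
    ## two response classes (vector of P(class 2)) or a single new row
    pr <- if (length(used) == 2L && length(mis_rows) >= 1L &&
              length(pr) == length(mis_rows))
      cbind(1 - pr, pr) else matrix(pr, nrow = 1L)
  }
  colnames(pr) <- used
  out <- matrix(0, nrow = length(mis_rows), ncol = length(lv),
                dimnames = list(NULL, lv))
  out[, used] <- pr
  out
}

#' Polytomous chained-equations imputation
#'
#' Fills nominal missing cells by iterated multinomial logistic regression:
#' missing cells are initialized by mode, then each trait with missing
#' values is regressed in turn on all other traits (as factors, with a
#' small ridge penalty on the coefficients), and its missing cells are
#' redrawn from the fitted category probabilities. The sweep is repeated
#' \code{iterations} times. Traits whose regression cannot be fitted (for
#' example a single observed category) keep their mode fill, with a
#' warning.
#'
#' @param tm a \code{\link{trait_matrix}}.
#' @param iterations chained-equation sweeps (default 5).
#' @param seed integer seed; results are fully reproducible from it.
#' @param draw if \code{TRUE} (default) missing cells are sampled from the
#'   fitted probabilities (proper imputation, preserves variability); if
#'   \code{FALSE} the most probable category is taken.
#' @param ridge ridge (weight-decay) penalty on the one-hot coefficients.
#' @return the completed \code{trait_matrix}.
#' @export
impute_polytomous <- function(tm, iterations = 5, seed = 1L, draw = TRUE,
                              ridge = 1e-3) {
  stopifnot(inherits(tm, "trait_matrix"), iterations >= 1)
  if (!anyNA(tm$values)) return(tm)
  na_mask <- is.na(tm$values)
  filled <- impute_mode(tm)
  vals <- filled$values
  set.seed(seed)
  target <- which(colSums(na_mask) > 0L)
  failed <- character(0)
  for (it in seq_len(iterations)) {
    df <- as.data.frame(lapply(seq_len(ncol(vals)), function(jj)
      factor(vals[, jj], levels = tm$codebook[[jj]])),
      col.names = colnames(vals), check.names = FALSE)
    for (j in target) {
      obs_rows <- which(!na_mask[, j])
      mis_rows <- which(na_mask[, j])
      pr <- fit_polytomous_trait(df, j, obs_rows, mis_rows, ridge)
      if (is.null(pr)) {
        failed <- union(failed, colnames(vals)[j])
        next
      }
      lv <- tm$codebook[[j]]
      new_vals <- if (draw) {
        apply(pr, 1L, function(p) sample(lv, 1L, prob = pmax(p, 0)))
      } else {
        lv[max.col(pr, ties.method = "first")]
      }
      vals[mis_rows, j] <- new_vals
      df[[j]] <- factor(vals[, j], levels = lv)
    }
  }
  if (length(failed))
    warning("polytomous fit unavailable for trait(s) ",
            paste(failed, collapse = ", "), "; mode fill kept")
  trait_matrix(vals, codebook = tm$codebook, trait_function = tm$trait_function)
}

## --- imputer registry -------------------------------------------------

imputer_registry <- new.env(parent = emptyenv())

#' Register an imputation method
#'
#' Plug-in point for external imputers (for example random-forest or
#' correspondence-analysis methods): any function taking \code{(tm, seed,
#' mask)} and returning a completed \code{\link{trait_matrix}} can join the
#' benchmark. \code{mask} is supplied by \code{\link{benchmark_imputers}}
#' (ordinary methods must ignore it; it exists so that reference "oracle"
#' methods can be benchmarked as an upper bound).
#'
#' @param name method name used in \code{methods =} arguments.
#' @param fn function \code{(tm, seed, mask)} returning a
#'   \code{trait_matrix}.
#' @return invisibly, \code{name}.
#' @export
register_imputer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = imputer_registry)
  invisible(name)
}

#' Look up a registered imputer
#' @param name method name.
#' @return the registered function.
#' @export
get_imputer <- function(name) {
  if (!exists(name, envir = imputer_registry, inherits = FALSE))
    stop("no imputer registered under ", dQuote(name))
  get(name, envir = imputer_registry, inherits = FALSE)
}

#' Benchmark imputation accuracy under MCAR deletion
#'
#' The accuracy simulation: starting from a fully observed matrix, cells
#' are deleted completely at random at each requested proportion, imputed
#' by each method, and scored as the proportion of masked cells restored
#' to their true category. Repeating this over many masks gives a mean
#' accuracy and a normal-approximation 95\% interval per
#' (method, proportion).
#'
#' @param tm_complete a \code{\link{trait_matrix}} with no missing cells.
#' @param methods character vector of registered imputer names
#'   (built-ins: \code{"mode"}, \code{"polytomous"}).
#' @param proportions missing-cell proportions (default 0.05 to 0.45 in
#'   steps of 0.05).
#' @param repetitions masks per proportion (default 100).
#' @param seed master seed; every mask and every stochastic imputer draw
#'   derives from it.
#' @param ... passed on to \code{\link{ampute_mcar}}.
#' @return object of class \code{imputation_benchmark}: list with
#'   \code{long} (method, proportion, rep, accuracy) and \code{summary}
#'   (method, proportion, mean_accuracy, se, ci_halfwidth, n_reps).
#' @export
benchmark_imputers <- function(tm_complete,
                               methods = c("mode", "polytomous"),
                               proportions = seq(0.05, 0.45, by = 0.05),
                               repetitions = 100, seed = 1L, ...) {
  stopifnot(inherits(tm_complete, "trait_matrix"))
  if (anyNA(tm_complete$values))
    stop("the benchmark needs a fully observed matrix")
  fns <- lapply(methods, get_imputer)
  names(fns) <- methods
  rows <- vector("list", length(proportions) * repetitions * length(methods))
  ri <- 0L
  for (pi in seq_along(proportions)) {
    for (r in seq_len(repetitions)) {
      sub_seed <- (as.integer(seed) * 7919L + pi * 1009L + r * 31L) %%
        2147483647L
      amp <- ampute_mcar(tm_complete, proportions[pi], seed = sub_seed, ...)
      idx <- cbind(amp$mask$row, amp$mask$col)
      for (ms in methods) {
        imp <- fns[[ms]](amp$tm, seed = sub_seed + 1L, mask = amp$mask)
        acc <- mean(imp$values[idx] == amp$mask$true)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(method = ms, proportion = proportions[pi],
                                 rep = r, accuracy = acc,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(long, long[c("method", "proportion")]),
    function(df) {
      se <- stats::sd(df$accuracy) / sqrt(nrow(df))
      data.frame(method = df$method[1L], proportion = df$proportion[1L],
                 mean_accuracy = mean(df$accuracy), se = se,
                 ci_halfwidth = 1.96 * se, n_reps = nrow(df),
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  structure(list(long = long, summary = agg), class = "imputation_benchmark")
}

#' @export
print.imputation_benchmark <- function(x, ...) {
  cat("imputation benchmark:", length(unique(x$summary$method)), "method(s),",
      length(unique(x$summary$proportion)), "proportion(s),",
      x$summary$n_reps[1L], "replicates\n")
  print(x$summary, digits = 3)
  invisible(x)
}

## built-in methods
register_imputer("mode", function(tm, seed, mask) impute_mode(tm))
register_imputer("polytomous", function(tm, seed, mask)
  impute_polytomous(tm, seed = seed))
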