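#' Two-dimensional stochastic-neighbour embedding of a dissimilarity matrix
#'
#' Visualization aid: converts pairwise dissimilarities into perplexity-
#' calibrated Gaussian neighbour probabilities and lays the objects out in
#' the plane by minimizing the Kullback-Leibler divergence to a Student-t
#' neighbour distribution (gradient descent with momentum and early
#' exaggeration). Used only for plotting — no downstream statistic
#' consumes the coordinates. Tiny inputs (n < 4) fall back to classical
#' principal-coordinates so the contract (finite coordinates, determinism)
#' still holds.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param seed integer seed; identical seeds give identical layouts.
#' @param perplexity effective neighbour count; capped at (n - 1) / 3.
#' @param n_iter gradient iterations.
#' @return an n x 2 numeric matrix of coordinates, rownames = object ids.
#' @export
embed_2d <- function(d, seed = 1L, perplexity = 30, n_iter = 500) {
  d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  if (all(d == 0)) {
    warning("degenerate input: all dissimilarities are zero; returning origin")
    return(matrix(0, n, 2, dimnames = list(ids, c("dim1", "dim2"))))
  }
  if (n < 4L) {
    y <- stats::cmdscale(d, k = min(2L, n - 1L))
    if (ncol(y) < 2L) y <- cbind(y, 0)
    dimnames(y) <- list(ids, c("dim1", "dim2"))
    return(y)
  }
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- d^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { p <- rep(1 / length(di), length(di)); break }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  vel <- matrix(0, n, 2)
  exag <- 4
  for (it in seq_len(n_iter)) {
    Pit <- if (it <= 100) P * exag else P
    sq <- rowSums(y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    mom <- if (it <= 250) 0.5 else 0.8
    vel <- mom * vel - 200 * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
  }
  dimnames(y) <- list(ids, c("dim1", "dim2"))
  y
}

#' Pairwise adjusted-Rand agreement across clustering configurations
#'
#' Compares the partitions produced by different (measure, linkage)
#' combinations at one shared k: a symmetric matrix of adjusted Rand
#' indices with unit diagonal.
#'
#' @param partitions named list of partitions over the same objects, all
#'   with the same number of clusters.
#' @return symmetric numeric matrix, dimnames = configuration names.
#' @export
pairwise_ari_table <- function(partitions) {
  stopifnot(is.list(partitions), length(partitions) >= 1)
  ks <- vapply(partitions, function(p) length(unique(p)), 1L)
  if (length(unique(ks)) != 1L)
    stop("partitions have different numbers of clusters: ",
         paste(unique(ks), collapse = ", "))
  p <- length(partitions)
  out <- diag(1, p)
  if (p > 1) for (i in 1:(p - 1)) for (j in (i + 1):p) {
    out[i, j] <- out[j, i] <- adjusted_rand(partitions[[i]], partitions[[j]])
  }
  dimnames(out) <- list(names(partitions), names(partitions))
  out
}

#' Assemble a pipeline configuration
#'
#' Defaults mirror the reference study design: 25\% missingness cutoff,
#' polytomous imputation, all five measures, all three linkages,
#' k = 2..10 for the validity grid, and bootstrap stability plus pairwise
#' agreement at k in \{3, 5, 7, 9\}.
#'
#' @param missing_cutoff missing-fraction cutoff for dropping traits.
#' @param imputation \code{"polytomous"}, \code{"mode"}, or any registered
#'   imputer name.
#' @param measures dissimilarity measures to run.
#' @param linkages linkage methods to run.
#' @param k_range k grid for the validity indices.
#' @param stability_k k values for bootstrap stability and the
#'   agreement tables.
#' @param stability_B bootstrap replicates.
#' @param stability_measures measures for the stability stage (defaults to
#'   \code{measures}).
#' @param embed_measure measure whose dissimilarities are embedded for the
#'   scatter output (default: first of \code{measures}).
#' @param perplexity embedding perplexity.
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(missing_cutoff = 0.25,
                            imputation = "polytomous",
                            measures = c("sm", "eskin", "iof", "goodall", "lin"),
                            linkages = c("single", "complete", "average"),
                            k_range = 2:10,
                            stability_k = c(3, 5, 7, 9),
                            stability_B = 100,
                            stability_measures = measures,
                            embed_measure = measures[1L],
                            perplexity = 30,
                            seed = 1L) {
  measures <- match.arg(measures, c("sm", "eskin", "iof", "goodall", "lin"),
                        several.ok = TRUE)
  linkages <- match.arg(linkages, c("single", "complete", "average"),
                        several.ok = TRUE)
  structure(list(missing_cutoff = missing_cutoff, imputation = imputation,
                 measures = measures, linkages = linkages,
                 k_range = sort(unique(as.integer(k_range))),
                 stability_k = as.integer(stability_k),
                 stability_B = as.integer(stability_B),
                 stability_measures = stability_measures,
                 embed_measure = embed_measure,
                 perplexity = perplexity, seed = as.integer(seed)),
            class = "pipeline_config")
}

sub_seed <- function(seed, stage) {
  (as.integer(seed) * 2654435L + match(stage,
    c("impute", "stability", "embed")) * 97L) %% 2147483647L
}

#' Run the full functional-group analysis
#'
#' Orchestrates every stage on one trait matrix: missingness screening and
#' trait dropping, imputation, the five-measure x three-linkage x k-grid
#' validity evaluation, bootstrap stability at the requested k values,
#' pairwise adjusted-Rand agreement between configurations, and a 2-D
#' embedding for plotting. All CSV and Newick outputs plus a JSON manifest
#' (configuration, seeds, package version, per-file MD5 checksums) are
#' written under \code{out_dir}; a rerun with the same inputs and seed is
#' byte-identical.
#'
#' @param tm a \code{\link{trait_matrix}} (may contain missing cells), or a
#'   path to a data CSV readable by \code{\link{read_trait_matrix}}.
#' @param out_dir output directory (created if needed).
#' @param config a \code{\link{pipeline_config}}.
#' @param codebook_path codebook CSV when \code{tm} is a path.
#' @return invisibly, a list with the imputed matrix, the
#'   \code{\link{evaluate_grid}} table, the per-(measure, linkage)
#'   selected k, stability reports, ARI tables, embedding coordinates and
#'   the manifest.
#' @export
run_pipeline <- function(tm, out_dir, config = pipeline_config(),
                         codebook_path = NULL) {
  if (is.character(tm))
    tm <- read_trait_matrix(tm, codebook_path = codebook_path)
  stopifnot(inherits(tm, "trait_matrix"), inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  file.create(log_path)
  logf("pipeline start: %d species x %d traits, seed %d",
       n_species(tm), n_traits(tm), config$seed)

  ## 1. screening + imputation
  tm2 <- stage("screen", drop_high_missing_traits(tm, config$missing_cutoff))
  logf("screen: retained %d/%d traits below cutoff %.2f",
       n_traits(tm2), n_traits(tm), config$missing_cutoff)
  imp <- stage("impute", {
    if (anyNA(tm2$values))
      get_imputer(config$imputation)(tm2, seed = sub_seed(config$seed, "impute"),
                                     mask = NULL)
    else tm2
  })
  write_trait_matrix(imp, file.path(out_dir, "imputed_matrix.csv"),
                     codebook_path = file.path(out_dir, "codebook.csv"))
  logf("impute: method %s, %d cells filled", config$imputation,
       sum(is.na(tm2$values)))

  ## 2. dissimilarities + evaluation grid
  ev <- stage("evaluate",
              evaluate_grid(imp, config$measures, config$linkages,
                            config$k_range))
  ft <- build_frequency_table(imp)
  for (ms in config$measures) {
    d <- dissimilarity(imp, ms, ft = ft)
    utils::write.csv(as.data.frame(unclass(d)),
                     file.path(out_dir, sprintf("dissimilarity_%s.csv", ms)))
  }
  dgs <- attr(ev, "dendrograms")
  for (nm in names(dgs)) {
    to_newick(dgs[[nm]], file.path(out_dir, sprintf("dendrogram_%s.nwk", nm)))
    utils::write.csv(
      data.frame(left = dgs[[nm]]$merge[, 1], right = dgs[[nm]]$merge[, 2],
                 height = dgs[[nm]]$height),
      file.path(out_dir, sprintf("merges_%s.csv", nm)), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(ev), file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  sel <- do.call(rbind, lapply(split(as.data.frame(ev),
                                     ev[c("measure", "linkage")], drop = TRUE),
    function(df) data.frame(measure = df$measure[1], linkage = df$linkage[1],
                            selected_k = if (any(df$optimal)) df$k[df$optimal][1]
                                         else NA_integer_)))
  rownames(sel) <- NULL
  utils::write.csv(sel, file.path(out_dir, "selected_k.csv"), row.names = FALSE)
  logf("evaluate: %d grid rows; selected k per combination written", nrow(ev))

  ## 3. partitions at the stability k values + agreement tables
  parts <- attr(ev, "partitions")
  ari_tabs <- list()
  for (k in intersect(config$stability_k, config$k_range)) {
    sel_parts <- parts[grep(sprintf("\\.%d$", k), names(parts))]
    if (length(sel_parts) >= 1L) {
      ari_tabs[[as.character(k)]] <- pairwise_ari_table(sel_parts)
      utils::write.csv(as.data.frame(ari_tabs[[as.character(k)]]),
                       file.path(out_dir, sprintf("ari_k%d.csv", k)))
    }
  }

  ## 4. bootstrap stability
  stab <- list()
  for (ms in config$stability_measures) for (k in config$stability_k) {
    rep_name <- sprintf("%s.k%d", ms, k)
    stab[[rep_name]] <- stage(paste0("stability:", rep_name),
      bootstrap_stability(imp, measure = ms, k = k, B = config$stability_B,
                          seed = sub_seed(config$seed, "stability")))
  }
  stab_df <- do.call(rbind, lapply(names(stab), function(nm) {
    df <- stab[[nm]]$per_cluster
    df$measure <- stab[[nm]]$config$measure
    df$k <- stab[[nm]]$config$k
    df
  }))
  if (!is.null(stab_df))
    utils::write.csv(stab_df, file.path(out_dir, "stability.csv"),
                     row.names = FALSE)
  logf("stability: %d (measure, k) combinations, B = %d",
       length(stab), config$stability_B)

  ## 5. embedding
  emb <- stage("embed", embed_2d(dissimilarity(imp, config$embed_measure,
                                               ft = ft),
                                 seed = sub_seed(config$seed, "embed"),
                                 perplexity = config$perplexity))
  utils::write.csv(data.frame(species = rownames(emb), emb),
                   file.path(out_dir, "embedding.csv"), row.names = FALSE)

  ## 6. manifest
  outputs <- sort(setdiff(list.files(out_dir), c("manifest.json", "run.log")))
  manifest <- list(
    package = "nomtrait",
    version = as.character(utils::packageVersion("nomtrait")),
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("pipeline done: %d output files", length(outputs))
  invisible(list(imputed = imp, evaluation = ev, selected_k = sel,
                 stability = stab, ari = ari_tabs, embedding = emb,
                 manifest = manifest, dir = out_dir))
}
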