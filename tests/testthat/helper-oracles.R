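## Independent oracles and fixture builders. These deliberately recompute
## everything from first principles (no Lance-Williams updates, no
## contingency-table shortcuts) so they can vouch for the package's
## optimized paths.

## random complete trait matrix with uniform categories
rand_tm <- function(n, m, K = 3, seed = 1) {
  set.seed(seed)
  vals <- matrix(sample(LETTERS[seq_len(K)], n * m, replace = TRUE), n, m,
                 dimnames = list(paste0("s", seq_len(n)),
                                 paste0("t", seq_len(m))))
  trait_matrix(vals, codebook = stats::setNames(
    rep(list(LETTERS[seq_len(K)]), m), colnames(vals)))
}

## naive agglomeration: recompute D(A,B) from the original matrix at every
## step by enumerating cross pairs; same slot-index tie rule as the package
naive_linkage <- function(d, linkage) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  Dab <- function(A, B) {
    cross <- d[A, B, drop = FALSE]
    switch(linkage, single = min(cross), complete = max(cross),
           average = mean(cross))
  }
  for (s in seq_len(n - 1)) {
    best <- list(h = Inf, i = NA, j = NA)
    act <- which(active)
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      h <- Dab(clusters[[act[ii]]], clusters[[act[jj]]])
      if (h < best$h) best <- list(h = h, i = act[ii], j = act[jj])
    }
    heights[s] <- best$h
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    active[best$j] <- FALSE
    members[[s]] <- sort(clusters[[best$i]])
  }
  list(heights = heights, members = members)
}

## cut the naive agglomeration at k: partition after n - k merges
naive_cut <- function(nl, n, k) {
  lab <- seq_len(n)
  for (s in seq_len(n - k)) lab[nl$members[[s]]] <- n + s
  as.integer(factor(lab))
}

## exhaustive k-medoids: global optimum over all medoid sets (tiny n only)
brute_pam <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  sets <- utils::combn(n, k)
  costs <- apply(sets, 2, function(set)
    sum(apply(d[, set, drop = FALSE], 1, min)))
  best <- which.min(costs)
  list(medoids = sets[, best], cost = costs[best])
}

## pair-counting adjusted Rand index over all object pairs
pair_ari <- function(p1, p2) {
  n <- length(p1)
  a <- b <- cd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
    if (s1 && s2) a <- a + 1
    else if (!s1 && !s2) b <- b + 1
    else cd <- cd + 1
  }
  total <- a + b + cd
  ## expected agreement under hypergeometric model
  n1 <- sum(choose(table(p1), 2)); n2 <- sum(choose(table(p2), 2))
  exp_a <- n1 * n2 / total
  max_a <- (n1 + n2) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

## per-cluster entropy WCE computed the slow way (explicit proportions)
naive_wce <- function(tm, part) {
  n <- nrow(tm$values); m <- ncol(tm$values)
  total <- 0
  for (g in unique(part)) {
    rows <- which(part == g)
    for (j in seq_len(m)) {
      p <- prop.table(table(tm$values[rows, j]))
      total <- total + length(rows) / (n * m) * (-sum(p * log(p)))
    }
  }
  total
}

## Hamming distance / m between rows
hamming_frac <- function(tm) {
  n <- nrow(tm$values)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- mean(tm$values[i, ] != tm$values[j, ])
  out
}

## consistent category relabeling of a trait matrix (order-preserving)
relabel_tm <- function(tm, prefix = "z_") {
  vals <- tm$values
  cb <- tm$codebook
  for (j in seq_len(ncol(vals))) {
    map <- stats::setNames(paste0(prefix, j, "_", cb[[j]]), cb[[j]])
    vals[, j] <- unname(map[vals[, j]])
    cb[[j]] <- unname(map)
  }
  trait_matrix(vals, codebook = cb)
}

named_truth <- function(g) stats::setNames(g$truth, rownames(g$tm$values))
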