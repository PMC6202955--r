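mk_tm <- function(cols, codebook = NULL) {
  vals <- do.call(cbind, cols)
  rownames(vals) <- paste0("s", seq_len(nrow(vals)))
  trait_matrix(vals, codebook = codebook)
}

test_that("mode imputation fills with the modal category, deterministically", {
  tm <- mk_tm(list(t1 = c("A", "A", "B", NA)))
  expect_equal(unname(impute_mode(tm)$values[4, 1]), "A")
  ## tie: first category in codebook order wins
  tie <- mk_tm(list(t1 = c("B", "A", NA, NA)),
               codebook = list(t1 = c("A", "B")))
  expect_equal(unname(impute_mode(tie)$values[3:4, 1]), c("A", "A"))
  tie2 <- mk_tm(list(t1 = c("B", "A", NA, NA)),
                codebook = list(t1 = c("B", "A")))
  expect_equal(unname(impute_mode(tie2)$values[3:4, 1]), c("B", "B"))
  ## complete input is returned unchanged
  full <- rand_tm(10, 3, seed = 2)
  expect_identical(impute_mode(full)$values, full$values)
  expect_identical(impute_polytomous(full, seed = 1)$values, full$values)
  ## fully missing trait is an error
  allna <- mk_tm(list(t1 = c("A", "B"), t2 = c(NA, NA)),
                 codebook = list(t1 = c("A", "B"), t2 = c("X", "Y")))
  expect_error(impute_mode(allna), "no observed values")
})

test_that("polytomous imputation exploits a deterministic trait dependency", {
  ## Y is a relabeled copy of X; the chained-equations model should restore
  ## masked Y cells almost perfectly where mode imputation cannot
  set.seed(42)
  n <- 500
  x <- sample(c("A", "B", "C"), n, replace = TRUE)
  y <- c(A = "U", B = "V", C = "W")[x]
  miss <- sample(n, 60)
  y_obs <- y; y_obs[miss] <- NA
  tm <- mk_tm(list(X = x, Y = y_obs),
              codebook = list(X = c("A", "B", "C"), Y = c("U", "V", "W")))
  imp <- impute_polytomous(tm, iterations = 3, seed = 7)
  acc <- mean(imp$values[miss, "Y"] == y[miss])
  expect_gte(acc, 0.95)
  ## reproducible from the seed
  imp2 <- impute_polytomous(tm, iterations = 3, seed = 7)
  expect_identical(imp$values, imp2$values)
})

test_that("with independent traits, polytomous gains nothing over mode", {
  g <- generate_traits(synthetic_spec(n_species = 120, n_traits = 3,
                                      categories = 3, n_groups = 3,
                                      theta = 1 / 3), seed = 13)
  ## argmax variant: like-for-like against the deterministic mode fill
  register_imputer("poly_fast", function(tm, seed, mask)
    impute_polytomous(tm, iterations = 2, seed = seed, draw = FALSE))
  bench <- benchmark_imputers(g$tm, methods = c("mode", "poly_fast"),
                              proportions = 0.2, repetitions = 40, seed = 5)
  s <- bench$summary
  diff <- abs(s$mean_accuracy[s$method == "poly_fast"] -
              s$mean_accuracy[s$method == "mode"])
  pooled_se <- sqrt(sum(s$se^2))
  expect_lte(diff, 3 * pooled_se)
})

test_that("the benchmark scores a mask-reading oracle at accuracy 1", {
  register_imputer("oracle", function(tm, seed, mask) {
    vals <- tm$values
    vals[cbind(mask$row, mask$col)] <- mask$true
    trait_matrix(vals, codebook = tm$codebook)
  })
  g <- generate_traits(synthetic_spec(30, 5, 3), seed = 9)
  bench <- benchmark_imputers(g$tm, methods = "oracle",
                              proportions = c(0.1, 0.3), repetitions = 5,
                              seed = 2)
  expect_true(all(bench$summary$mean_accuracy == 1))
  expect_true(all(bench$summary$n_reps == 5))
  expect_error(benchmark_imputers(g$tm, methods = "no_such_method",
                                  proportions = 0.1, repetitions = 2),
               "no imputer registered")
})

test_that("mode accuracy matches the modal-frequency expectation", {
  ## single trait whose modal category has relative frequency 0.7: under
  ## MCAR deletion the expected restoration rate is exactly 0.7
  vals <- matrix(rep(c("A", "B", "C"), times = c(700, 150, 150)), ncol = 1,
                 dimnames = list(paste0("s", 1:1000), "t1"))
  tm <- trait_matrix(vals)
  bench <- benchmark_imputers(tm, methods = "mode", proportions = 0.2,
                              repetitions = 100, seed = 3)
  s <- bench$summary
  expect_lte(abs(s$mean_accuracy - 0.7), 3 * s$se)
})

test_that("benchmark accuracy is invariant to consistent category relabeling", {
  g <- generate_traits(synthetic_spec(40, 4, 3, theta = 0.8), seed = 17)
  b1 <- benchmark_imputers(g$tm, methods = "mode", proportions = 0.15,
                           repetitions = 10, seed = 11)
  b2 <- benchmark_imputers(relabel_tm(g$tm), methods = "mode",
                           proportions = 0.15, repetitions = 10, seed = 11)
  expect_equal(b1$long$accuracy, b2$long$accuracy)
})

test_that("replicate variability shrinks as the masked fraction grows", {
  g <- generate_traits(synthetic_spec(), seed = 6)
  bench <- benchmark_imputers(g$tm, methods = "mode",
                              proportions = c(0.05, 0.45),
                              repetitions = 100, seed = 8)
  s <- bench$summary
  expect_lt(s$se[s$proportion == 0.45], s$se[s$proportion == 0.05])
})
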