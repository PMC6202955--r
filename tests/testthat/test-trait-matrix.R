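test_that("CSV parsing honours codebooks, missing tokens and validation", {
  dir <- withr::local_tempdir()
  data_csv <- file.path(dir, "m.csv")
  cb_csv <- file.path(dir, "cb.csv")
  writeLines(c("species,t1,t2",
               "sp1,A,B", "sp2,B,A", "sp3,A,A", "sp4,NA,B"), data_csv)
  writeLines(c("trait,function,type,categories",
               "t1,diet,nominal,A|B", "t2,habitat,nominal,A|B"), cb_csv)
  tm <- read_trait_matrix(data_csv, cb_csv)
  expect_equal(n_species(tm), 4)
  expect_equal(n_traits(tm), 2)
  expect_equal(vapply(tm$codebook, length, 1L), c(t1 = 2L, t2 = 2L))
  expect_true(is.na(tm$values["sp4", "t1"]))   # "NA" token, not a category
  expect_equal(unname(tm$trait_function), c("diet", "habitat"))

  ## label outside a closed set is an error naming row, column, label
  writeLines(c("species,t1,t2", "sp1,A,B", "sp2,Z,A"), data_csv)
  expect_error(read_trait_matrix(data_csv, cb_csv), "Z.*sp2.*t1|sp2.*t1.*Z")

  ## duplicate species id
  writeLines(c("species,t1,t2", "sp1,A,B", "sp1,B,A"), data_csv)
  expect_error(read_trait_matrix(data_csv, cb_csv), "duplicate species")

  ## trait in data absent from codebook
  writeLines(c("species,t1,t9", "sp1,A,B", "sp2,B,A"), data_csv)
  expect_error(read_trait_matrix(data_csv, cb_csv), "absent from codebook")
})

test_that("write then read round-trips values, categories and missingness", {
  g <- generate_traits(synthetic_spec(n_species = 15, n_traits = 5,
                                      categories = c(2, 3, 4, 5, 7),
                                      missing_fraction = 0.2), seed = 11)
  dir <- withr::local_tempdir()
  write_trait_matrix(g$tm, file.path(dir, "m.csv"), file.path(dir, "cb.csv"))
  back <- read_trait_matrix(file.path(dir, "m.csv"), file.path(dir, "cb.csv"))
  expect_identical(back$values, g$tm$values)
  expect_identical(back$codebook, g$tm$codebook)
})

test_that("missingness summary reproduces the packaged trait-table numbers", {
  tt <- tbgb_trait_table()
  expect_equal(sum(tt$missing_percent == 0), 13)
  expect_equal(max(tt$missing_percent), 23.3)

  ## same numbers through summarize_missingness on a matrix realizing the
  ## table's per-trait missingness over 116 species
  n <- 116
  vals <- matrix("x", n, nrow(tt), dimnames = list(
    sprintf("sp%03d", 1:n), tt$trait))
  for (j in seq_len(nrow(tt))) {
    vals[, j] <- tt$categories[[j]][1]
    k <- round(tt$missing_percent[j] / 100 * n)
    if (k > 0) vals[seq_len(k), j] <- NA
  }
  tm <- trait_matrix(vals, codebook = stats::setNames(tt$categories, tt$trait))
  ms <- summarize_missingness(tm)
  expect_equal(attr(ms, "n_complete_traits"), 13)
  expect_equal(ms$percent, tt$missing_percent)

  ## no missing cells at all
  g <- generate_traits(synthetic_spec(10, 4, 3), seed = 1)
  ms2 <- summarize_missingness(g$tm)
  expect_true(all(ms2$fraction == 0))
  expect_equal(attr(ms2, "n_complete_traits"), 4)
})

test_that("high-missingness traits are dropped strictly below the cutoff", {
  vals <- matrix("A", 30, 3, dimnames = list(paste0("s", 1:30),
                                             c("t0", "t23", "t30")))
  vals[16:30, ] <- "B"
  vals[1:7, "t23"] <- NA    # 23.3%
  vals[1:9, "t30"] <- NA    # 30%
  tm <- trait_matrix(vals)
  kept <- drop_high_missing_traits(tm, 0.25)
  expect_equal(colnames(kept$values), c("t0", "t23"))
  expect_equal(n_traits(drop_high_missing_traits(tm, 1.0)), 3)
  all_missing <- trait_matrix(vals[, c("t23", "t30")],
                              codebook = list(t23 = c("A", "B"),
                                              t30 = c("A", "B")))
  expect_error(drop_high_missing_traits(all_missing, 0.2), "no trait")
  expect_error(drop_high_missing_traits(tm, 1.5), "cutoff")
})

test_that("discretization follows the published bin edges and closure", {
  rules <- tbgb_binning_rules()
  len <- rules[["Maximum length (cm)"]]
  expect_equal(discretize(30, len), "Medium")
  expect_equal(discretize(c(5, 100, 1000), len),
               c("Small", "Large", "Very large"))
  ## a value exactly on a breakpoint belongs to the lower bin
  expect_equal(discretize(20.1, len), "Small")
  expect_equal(discretize(20.1000001, len), "Medium")
  dep <- rules[["Maximum depth (m)"]]
  expect_equal(discretize(c(10, 100, 500), dep), c("Reef", "Ocean", "Bathy"))
  expect_error(discretize(c(1, NA), len), "finite")
  expect_error(discretize(Inf, len), "finite")
  ## total and deterministic: every value maps to exactly one label
  set.seed(5)
  x <- exp(runif(500, -2, 8))
  lab <- discretize(x, dep)
  expect_equal(length(lab), 500)
  expect_false(anyNA(lab))
  expect_identical(lab, discretize(x, dep))
})

test_that("log-width bin suggestion reproduces the e^3..e^5 breakpoints", {
  x <- exp(c(2, 2.5, 3.3, 4.1, 5.2, 6))   # spans e^2..e^6
  rule <- suggest_bins(x, 4)
  expect_equal(rule$breaks, c(20.1, 54.6, 148.4))
  expect_equal(length(rule$labels), 4)
  ## bins covering observed data are nonempty
  cnt <- table(factor(discretize(x, rule), levels = rule$labels))
  expect_true(all(cnt[c(1, 4)] > 0))
  expect_error(suggest_bins(rep(2, 10), 4), "distinct")
  expect_error(suggest_bins(c(-1, 2, 3, 4, 5), 4), "positive")
})
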