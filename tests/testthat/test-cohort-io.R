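test_that("read_cohort assembles blocks, sorts rows, and round-trips", {
  cohort <- tiny_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)
  back <- read_cohort(paths, attr(paths, "diagnosis"))
  expect_equal(back, cohort)

  # shuffling the file rows must not change the result: rows are id-sorted
  for (p in c(paths, attr(paths, "diagnosis"))) {
    df <- read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df[rev(seq_len(nrow(df))), ], p, row.names = FALSE, quote = FALSE)
  }
  shuffled <- read_cohort(paths, attr(paths, "diagnosis"))
  expect_equal(shuffled, cohort)
})

test_that("read_cohort reports the offending subject and cell", {
  cohort <- tiny_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)

  df <- read.csv(paths[["A"]], check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df[-3, ], paths[["A"]], row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(paths, attr(paths, "diagnosis")),
               "subject 'T03' is missing from modality file 'A'")

  paths2 <- write_cohort(cohort, dir)
  df <- read.csv(paths2[["B"]], check.names = FALSE, stringsAsFactors = FALSE)
  df[2, 2] <- "oops"
  write.csv(df, paths2[["B"]], row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(paths2, attr(paths2, "diagnosis")),
               "non-numeric value 'oops' in modality 'B', row 2")
})

test_that("cohort construction rejects incomplete or non-finite data", {
  cohort <- tiny_cohort()
  vals <- cohort$blocks$A$values
  vals[2, 1] <- NA
  expect_error(feature_block(vals, "A"), "non-finite")
  clean <- cohort$blocks$A$values
  expect_error(
    cohort_table(cohort$diagnosis,
                 list(A = feature_block(clean[-1, ], "A"))),
    "rows"
  )
})

test_that("horizon labels follow the conversion rule in every case", {
  # independent oracle: spell the rule out per subject
  oracle <- function(months, reverted, horizon, strict) {
    if (!is.na(months) && months <= horizon) return("pMCI")
    if (strict && !is.na(months) && months > horizon) return("excluded")
    if (strict && reverted) return("excluded")
    "sMCI"
  }
  cases <- expand.grid(months = c(NA, 12, 36, 36.5, 48, 60),
                       reverted = c(FALSE, TRUE))
  n <- nrow(cases)
  ids <- sprintf("M%02d", seq_len(n))
  diagnosis <- data.frame(
    subject_id = c(ids, "ZAD", "ZNC"),
    baseline_group = c(rep("MCI", n), "AD", "NC"),
    months_to_AD = c(cases$months, NA, NA),
    months_last_followup = 60,
    reverted_to_NC = c(cases$reverted, FALSE, FALSE)
  )
  blk <- feature_block(matrix(seq_len(n + 2), ncol = 1), "X", "x1")
  cohort <- cohort_table(diagnosis, list(X = blk))
  for (strict in c(FALSE, TRUE)) {
    lab <- assign_horizon_labels(cohort, 36, strict = strict)
    expected <- vapply(seq_len(n), function(i) {
      oracle(cases$months[i], cases$reverted[i], 36, strict)
    }, character(1))
    expect_equal(as.character(lab)[match(ids, names(lab))], expected,
                 info = paste("strict =", strict))
  }
  # spot values from the definition
  expect_equal(as.character(lab <- assign_horizon_labels(cohort, 36))[
    match("M02", names(lab))], "pMCI")  # months 12 <= 36
  expect_error(assign_horizon_labels(cohort, -1), "positive")
})

test_that("raising the horizon never demotes a progressor", {
  set.seed(7)
  n <- 60
  months <- ifelse(runif(n) < 0.5, sample(1:70, n, replace = TRUE), NA)
  diagnosis <- data.frame(
    subject_id = sprintf("M%02d", 1:n), baseline_group = "MCI",
    months_to_AD = months, months_last_followup = 72,
    reverted_to_NC = FALSE
  )
  cohort <- cohort_table(diagnosis,
                         list(X = feature_block(matrix(rnorm(n)), "X", "x")))
  prev <- character(0)
  for (h in seq(6, 72, by = 6)) {
    lab <- assign_horizon_labels(cohort, h)
    pmci <- names(lab)[lab == "pMCI"]
    expect_true(all(prev %in% pmci))
    # brute-force count per subject
    expect_length(pmci, sum(!is.na(months) & months <= h))
    prev <- pmci
  }
})

test_that("normaliser uses reference-only population moments", {
  blk <- feature_block(matrix(c(1, 3, 10, 0, 2, 4), ncol = 1), "X", "x")
  p <- fit_normalizer(blk, 1:2)
  expect_equal(unname(p$mean), 2)
  expect_equal(unname(p$sd), 1)  # population SD of {1, 3}
  # value 5 with mean 2, sd 1 -> 3
  out <- apply_normalizer(p, feature_block(matrix(5), "X", "x"))
  expect_equal(unname(out$values[1, 1]), 3)

  set.seed(1)
  blk <- feature_block(matrix(rnorm(15, 5, 3), 5, 3), "R")
  p <- fit_normalizer(blk, 1:5)
  # brute-force column loop oracle
  for (j in 1:3) {
    v <- blk$values[, j]
    expect_equal(unname(p$mean[j]), mean(v))
    expect_equal(unname(p$sd[j]), sqrt(mean((v - mean(v))^2)))
  }
  z <- apply_normalizer(p, blk)$values
  expect_equal(unname(colMeans(z)), rep(0, 3))
  expect_equal(unname(colMeans(z^2)), rep(1, 3))
})

test_that("held-out rows keep their offset on the reference scale", {
  set.seed(2)
  ref <- matrix(rnorm(200), 100, 2)
  offset <- c(1.5, -2)
  mci <- sweep(matrix(rnorm(100), 50, 2), 2, offset, "+")
  blk <- feature_block(rbind(ref, mci), "X")
  p <- fit_normalizer(blk, 1:100)
  z <- apply_normalizer(p, blk)$values
  expect_equal(unname(colMeans(z[101:150, ])),
               unname((colMeans(mci) - p$mean) / p$sd),
               tolerance = 1e-12)
  # reference means are ~0, so the held-out means sit near offset / sd
  expect_gt(abs(mean(z[101:150, 1])), 0.5)
  # and the inverse transform recovers the input exactly
  back <- apply_normalizer(p, apply_normalizer(p, blk), invert = TRUE)
  expect_equal(back$values, blk$values, tolerance = 1e-12)
})

test_that("normaliser rejects constant features and dimension mismatches", {
  blk <- feature_block(cbind(c(1, 1, 1), c(1, 2, 3)), "X", c("flat", "ok"))
  expect_error(fit_normalizer(blk, 1:3), "flat")
  blk2 <- feature_block(matrix(rnorm(9), 3, 3), "Y")
  p <- fit_normalizer(feature_block(matrix(rnorm(4), 2, 2), "Z"), 1:2)
  expect_error(apply_normalizer(p, blk2), "features")
  expect_error(fit_normalizer(blk2, 1), "at least 2")
})
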