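# Small deterministic cohort with two generic modalities, used across tests.
tiny_cohort <- function(seed = 42, n_ad = 4, n_nc = 4, n_mci = 6) {
  set.seed(seed)
  groups <- rep(c("AD", "NC", "MCI"), c(n_ad, n_nc, n_mci))
  n <- length(groups)
  ids <- sprintf("T%02d", seq_len(n))
  a <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, paste0("a", 1:3)))
  b <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, paste0("b", 1:2)))
  mci <- groups == "MCI"
  diagnosis <- data.frame(
    subject_id = ids,
    baseline_group = groups,
    months_to_AD = ifelse(mci & seq_len(n) %% 2 == 0, 24, NA_real_),
    months_last_followup = 60,
    reverted_to_NC = FALSE,
    stringsAsFactors = FALSE
  )
  cohort_table(diagnosis,
               list(A = feature_block(a, "A"), B = feature_block(b, "B")))
}

# Random two-class sample with both classes guaranteed present.
random_labelled <- function(n, m, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  y <- rep_len(c("pos", "neg"), n)[sample.int(n)]
  list(x = x, y = y)
}
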