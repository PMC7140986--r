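#' Specify a synthetic multimodal cohort
#'
#' Defines the generative model for an ADNI-like cohort: group-conditional
#' equicorrelated Gaussian feature blocks of unequal dimensionality, a
#' Bernoulli risk-allele block, and conversion times for the progressive
#' MCI group. Each continuous block has `dim` features of which
#' `informative` carry a standardised mean difference `effect` between AD
#' and NC (AD at `+effect/2`, NC at `-effect/2` on the unit-variance scale);
#' the remaining features have zero mean everywhere. All features within a
#' block share an equicorrelation `rho` (a common per-subject factor), so
#' nuisance features are correlated with each other, stressing feature
#' selection realistically. MCI groups sit between the poles: pMCI
#' informative means are `mci_mixing * (AD mean)` and sMCI means
#' `mci_mixing * (NC mean)`.
#'
#' @param n_ad,n_nc,n_pmci,n_smci Group sizes.
#' @param modalities Named list of per-block settings, each a list with
#'   `dim`, `informative`, `effect`, `rho`.
#' @param apoe_freq Named numeric vector of APOE e4 carrier probabilities
#'   for `AD`, `NC`, `pMCI`, `sMCI`.
#' @param mci_mixing Attenuation `a` in `[0, 1]` placing the MCI groups
#'   between the AD and NC poles on informative features.
#' @param conversion List with `mean_months` (exponential mean of the
#'   conversion time, truncated at `max_months`), `max_months` (latest
#'   conversion counted as progressive at the reference 3-year horizon),
#'   `late_rate` (probability that a stable-group subject converts after
#'   `max_months`, within 5 years) and `revert_rate` (probability that a
#'   stable subject's diagnosis reverts to normal) — together these supply
#'   the subjects the strict stable-MCI definition excludes.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ad = 102, n_nc = 200, n_pmci = 110,
                           n_smci = 205,
                           modalities = list(
                             "MRI" = list(dim = 313, informative = 30,
                                          effect = 0.5, rho = 0.2),
                             "FDG-PET" = list(dim = 20, informative = 8,
                                              effect = 0.75, rho = 0.2),
                             "CSF" = list(dim = 3, informative = 3,
                                          effect = 1.1, rho = 0.2)),
                           apoe_freq = c(AD = 0.65, NC = 0.25,
                                         pMCI = 0.60, sMCI = 0.35),
                           mci_mixing = 0.6,
                           conversion = list(mean_months = 20,
                                             max_months = 36,
                                             late_rate = 0.08,
                                             revert_rate = 0.22),
                           seed = 1) {
  for (n in c(n_ad, n_nc, n_pmci, n_smci)) {
    if (!is.numeric(n) || n < 0) stop("group sizes must be nonnegative")
  }
  for (nm in names(modalities)) {
    m <- modalities[[nm]]
    if (m$informative > m$dim) {
      stop("modality '", nm, "': informative count exceeds dimension")
    }
    if (!is.finite(m$effect)) stop("effect sizes must be finite")
    if (m$rho < 0 || m$rho >= 1) stop("rho must be in [0, 1)")
  }
  if (mci_mixing < 0 || mci_mixing > 1) stop("mci_mixing must be in [0, 1]")
  if (any(apoe_freq < 0 | apoe_freq > 1)) {
    stop("apoe_freq entries must be probabilities")
  }
  if (!setequal(names(apoe_freq), c("AD", "NC", "pMCI", "sMCI"))) {
    stop("apoe_freq must be named AD, NC, pMCI, sMCI")
  }
  structure(list(n_ad = n_ad, n_nc = n_nc, n_pmci = n_pmci, n_smci = n_smci,
                 modalities = modalities, apoe_freq = apoe_freq,
                 mci_mixing = mci_mixing, conversion = conversion,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @details `preset_adnilike()` returns the default specification: group
#'   sizes 200 NC / 102 AD / 110 progressive MCI / 205 stable MCI and block
#'   dimensions 313 (MRI) / 20 (FDG-PET) / 3 (CSF) / 1 (APOE), with moderate
#'   effect sizes and a truncated-exponential conversion-time model whose
#'   cumulative pMCI counts grow with the horizon over 1-5 years.
#' @export
preset_adnilike <- function(seed = 1) synthetic_spec(seed = seed)

#' Generate a synthetic multimodal cohort
#'
#' Draws a [cohort_table()] from a [synthetic_spec()]: for each continuous
#' block, `X = sqrt(rho) * f + sqrt(1 - rho) * E + mu(group)` with a common
#' per-subject factor `f`, giving unit-variance equicorrelated features;
#' the APOE block is Bernoulli 0/1 per group. Progressive-group conversion
#' times are truncated-exponential within `max_months`; a small fraction of
#' the stable group converts later than `max_months` or reverts to normal,
#' so the strict labelling mode has subjects to exclude. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [cohort_table()] with blocks `MRI`, `FDG-PET`, `CSF`, `APOE`
#'   (names following `spec$modalities` plus `APOE`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  groups <- rep(c("AD", "NC", "pMCI", "sMCI"),
                c(spec$n_ad, spec$n_nc, spec$n_pmci, spec$n_smci))
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  # informative-feature mean per group, on the unit-variance scale
  pole <- c(AD = 0.5, NC = -0.5,
            pMCI = 0.5 * spec$mci_mixing, sMCI = -0.5 * spec$mci_mixing)
  blocks <- list()
  for (nm in names(spec$modalities)) {
    m <- spec$modalities[[nm]]
    informative <- sort(sample.int(m$dim, m$informative))
    f <- rnorm(n)
    X <- sqrt(m$rho) * f + sqrt(1 - m$rho) *
      matrix(rnorm(n * m$dim), n, m$dim)
    mu <- matrix(0, n, m$dim)
    mu[, informative] <- m$effect * pole[groups]
    X <- X + mu
    colnames(X) <- sprintf("%s_f%03d", nm, seq_len(m$dim))
    rownames(X) <- ids
    blocks[[nm]] <- feature_block(X, nm)
  }
  apoe <- rbinom(n, 1L, spec$apoe_freq[groups])
  blocks[["APOE"]] <- feature_block(matrix(as.numeric(apoe), n, 1,
                                           dimnames = list(ids, "APOE_e4")),
                                    "APOE")

  cv <- spec$conversion
  months_to_AD <- rep(NA_real_, n)
  reverted <- rep(FALSE, n)
  followup <- rep(60, n)
  pm <- groups == "pMCI"
  if (any(pm)) {
    # inverse-CDF draw from Exp(mean_months) truncated to (0, max_months]
    u <- runif(sum(pm)) * (1 - exp(-cv$max_months / cv$mean_months))
    months_to_AD[pm] <- pmax(1, round(-cv$mean_months * log(1 - u)))
  }
  sm <- which(groups == "sMCI")
  if (length(sm) > 0) {
    late <- sm[runif(length(sm)) < cv$late_rate]
    months_to_AD[late] <- round(runif(length(late), cv$max_months + 1, 60))
    rest <- setdiff(sm, late)
    reverted[rest[runif(length(rest)) < cv$revert_rate]] <- TRUE
    followup[sm] <- round(runif(length(sm), 24, 84))
    followup[late] <- pmax(followup[late], months_to_AD[late])
  }
  diagnosis <- data.frame(
    subject_id = ids,
    baseline_group = ifelse(groups %in% c("pMCI", "sMCI"), "MCI", groups),
    months_to_AD = months_to_AD,
    months_last_followup = followup,
    reverted_to_NC = reverted,
    stringsAsFactors = FALSE
  )
  cohort_table(diagnosis, blocks)
}
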