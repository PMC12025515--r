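# Seeded synthetic-data generators. Each generator is a pure function of
# (parameters, seed) and emits exactly the containers/file dialects the
# analysis stages consume, so the whole pipeline is testable end to end
# without external repositories or registry extracts.

#' Simulate multi-study case/control expression data with a shared sparse
#' disease signature
#'
#' Draws a sparse per-gene signature (random subset of genes, random +/-1
#' direction), then for each study generates Gaussian log-scale expression
#' in which case samples are shifted by `study multiplier x delta x
#' signature`. Study multipliers are drawn uniformly in [0.75, 1.25] so
#' studies share the signature but differ in effect strength, mimicking
#' independent case/control series.
#'
#' @param n_studies number of independent studies.
#' @param G number of genes.
#' @param n_case,n_ctrl samples per group in each study (>= 2).
#' @param sparsity fraction of genes carrying the signature (in (0, 1]).
#' @param delta effect size on the log-expression scale for a unit
#'   signature entry.
#' @param sigma within-group Gaussian noise sd (> 0).
#' @param seed integer seed.
#' @return list with `studies` (list of [expression_study()]) and `truth`
#'   (class `signature_truth`: `signature` named vector, `affected` gene
#'   set, `multipliers`, `sigma`).
#' @export
simulate_expression_studies <- function(n_studies, G, n_case, n_ctrl,
                                        sparsity, delta, sigma, seed) {
  stopifnot(n_studies >= 1, G >= 2, n_case >= 2, n_ctrl >= 2,
            sparsity > 0, sparsity <= 1, sigma > 0)
  n_affected <- round(sparsity * G)
  if (n_affected < 1)
    stop("sparsity * G < 1: no gene would carry the signature")
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(G))
  affected <- sort(sample(G, n_affected))
  signature <- stats::setNames(numeric(G), genes)
  signature[affected] <- sample(c(-1, 1), n_affected, replace = TRUE)
  multipliers <- stats::runif(n_studies, 0.75, 1.25)
  baseline <- stats::rnorm(G, mean = 7, sd = 1)

  studies <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    n <- n_case + n_ctrl
    m <- matrix(stats::rnorm(G * n, sd = sigma), G, n) + baseline
    shift <- multipliers[s] * delta * signature
    m[, seq_len(n_case)] <- m[, seq_len(n_case)] + shift
    ids <- sprintf("S%02d_%s%02d", s,
                   rep(c("case", "ctrl"), c(n_case, n_ctrl)),
                   c(seq_len(n_case), seq_len(n_ctrl)))
    rownames(m) <- genes
    colnames(m) <- ids
    ann <- data.frame(sample_id = ids,
                      group = rep(c("case", "control"), c(n_case, n_ctrl)),
                      stringsAsFactors = FALSE)
    studies[[s]] <- expression_study(m, ann)
  }
  names(studies) <- sprintf("study%02d", seq_len(n_studies))
  truth <- structure(list(signature = signature, affected = genes[affected],
                          multipliers = multipliers, sigma = sigma),
                     class = "signature_truth")
  list(studies = studies, truth = truth)
}

#' Simulate a compound-profile library with planted correlated profiles
#'
#' A random subset of `planted` compounds is generated as
#' `z = rho * s + sqrt(1 - rho^2) * eps` with `s` the standardized target
#' signature and `eps` standard normal, so their expected Pearson
#' correlation with the signature is `rho`; the remaining compounds are
#' pure standard-normal noise.
#'
#' @param signature per-gene numeric vector (named, or names are
#'   generated); the query-side target.
#' @param M number of compounds.
#' @param planted number of correlated compounds (<= M).
#' @param rho target correlation in [0, 1].
#' @param seed integer seed.
#' @return list with `library` (class `profile_library`) and `truth`
#'   (data frame: compound, planted flag).
#' @export
simulate_drug_library <- function(signature, M, planted, rho, seed) {
  stopifnot(rho >= 0, rho <= 1, planted >= 0, planted <= M, M >= 1)
  G <- length(signature)
  stopifnot(G >= 4)
  if (is.null(names(signature)))
    names(signature) <- sprintf("GENE%05d", seq_len(G))
  set.seed(seed)
  s <- (signature - mean(signature)) / stats::sd(signature)
  which_planted <- sort(sample(M, planted))
  nm <- sprintf("drug%04d", seq_len(M))
  lib <- vector("list", M)
  for (i in seq_len(M)) {
    eps <- stats::rnorm(G)
    z <- if (i %in% which_planted) rho * s + sqrt(1 - rho^2) * eps else eps
    lib[[i]] <- stats::setNames(as.numeric(z), names(signature))
  }
  names(lib) <- nm
  list(library = structure(lib, class = "profile_library"),
       truth = data.frame(compound = nm,
                          planted = seq_len(M) %in% which_planted,
                          stringsAsFactors = FALSE))
}

#' Construct the generative truth for a synthetic prescription registry
#'
#' Parameters of the logistic outcome model and of the age-dependent
#' exposure prevalence model used by [simulate_registry()]. The defaults
#' describe a cohort in which the outcome drug (lithium-like) has a
#' baseline prevalence of about 1%, exposure (cardiotonic-like) about 2%
#' rising with age, a strongly negative exposure-outcome log odds, and
#' around ten dispensings per positive medication status.
#'
#' @param beta0 baseline outcome log odds.
#' @param beta_exposure injected exposure->outcome log odds.
#' @param beta_age per-year log odds.
#' @param beta_sex male-vs-female log odds.
#' @param exposure_intercept,exposure_age logit-linear age model of
#'   exposure prevalence (confounding by age is on by default).
#' @param lambda mean number of dispensings per positive status (>= 1).
#' @return list of class `registry_truth`.
#' @export
registry_truth <- function(beta0 = -5.75, beta_exposure = -1.15,
                           beta_age = 0.02, beta_sex = 0.3,
                           exposure_intercept = -7, exposure_age = 0.06,
                           lambda = 10) {
  stopifnot(lambda >= 1)
  structure(list(beta0 = beta0, beta_exposure = beta_exposure,
                 beta_age = beta_age, beta_sex = beta_sex,
                 exposure_intercept = exposure_intercept,
                 exposure_age = exposure_age, lambda = lambda),
            class = "registry_truth")
}

# illustrative psychiatric qualifying dispensing codes (antidepressants and
# psycholeptics) used by the generator; the analysis side matches by the
# N05/N06 prefixes
PSYCH_ATC_POOL <- c("N06AB06", "N06AB04", "N06AX11", "N05BA01", "N05AH03")
LI_ATC <- "N05AN01"
CTS_ATC <- c("C01AA05", "C01AA04")

#' Simulate a longitudinal prescription registry with an injected
#' exposure-outcome association
#'
#' Ages are drawn from a truncated normal, sex from a Bernoulli, exposure
#' (cardiotonic-like medication) with age-rising prevalence, and the
#' outcome (lithium-like prescription) from
#' `Bernoulli(logit^-1(b0 + b_age age + b_sex male + b_exp exposed))`.
#' Every person receives at least one qualifying psychiatric dispensing
#' event; each positive exposure/outcome status is materialized as
#' `1 + Poisson(lambda - 1)` dated events with the corresponding ATC code,
#' dates uniform in the window.
#'
#' @param N cohort size (>= 100).
#' @param truth a [registry_truth()].
#' @param window length-2 `Date` vector.
#' @param seed integer seed.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param sex_ratio probability of male.
#' @return list with `persons`, `events` (data frames in the registry CSV
#'   dialects) and `truth`.
#' @export
simulate_registry <- function(N, truth = registry_truth(),
                              window = as.Date(c("2010-01-01", "2021-12-31")),
                              seed = 1, age_mean = 50, age_sd = 18,
                              age_range = c(18, 95), sex_ratio = 0.5) {
  stopifnot(N >= 100, inherits(truth, "registry_truth"))
  window <- as.Date(window)
  set.seed(seed)
  # truncated normal ages via inverse-cdf sampling, in whole years
  plo <- stats::pnorm(age_range[1], age_mean, age_sd)
  phi <- stats::pnorm(age_range[2], age_mean, age_sd)
  age <- round(stats::qnorm(stats::runif(N, plo, phi), age_mean, age_sd))
  sex <- ifelse(stats::runif(N) < sex_ratio, "male", "female")

  p_exp <- stats::plogis(truth$exposure_intercept + truth$exposure_age * age)
  exposed <- stats::rbinom(N, 1, p_exp) == 1
  lp <- truth$beta0 + truth$beta_age * age +
    truth$beta_sex * (sex == "male") + truth$beta_exposure * exposed
  p_out <- stats::plogis(lp)
  if (sum(p_out) < 10)
    stop("expected outcome count below 10: association inestimable ",
         "at these parameters")
  outcome <- stats::rbinom(N, 1, p_out) == 1

  ids <- sprintf("P%07d", seq_len(N))
  # birth dates consistent with whole-year age at window end
  extra <- sample.int(360, N, replace = TRUE) - 1L
  birth <- window[2] - (ceiling(age * 365.25) + extra)
  persons <- data.frame(person_id = ids, sex = sex, birth_date = birth,
                        death_date = as.Date(rep(NA, N)),
                        stringsAsFactors = FALSE)

  span <- as.integer(window[2] - window[1])
  rand_dates <- function(n) window[1] + sample.int(span + 1, n,
                                                   replace = TRUE) - 1L
  event_block <- function(who, codes, counts) {
    pid <- rep(ids[who], counts)
    data.frame(person_id = pid,
               atc_code = sample(codes, length(pid), replace = TRUE),
               dispense_date = rand_dates(length(pid)),
               stringsAsFactors = FALSE)
  }
  n_psych <- 1L + stats::rpois(N, 1)
  n_cts <- 1L + stats::rpois(sum(exposed), truth$lambda - 1)
  n_li <- 1L + stats::rpois(sum(outcome), truth$lambda - 1)
  events <- rbind(event_block(seq_len(N), PSYCH_ATC_POOL, n_psych),
                  event_block(which(exposed), CTS_ATC, n_cts),
                  event_block(which(outcome), LI_ATC, n_li))
  rownames(events) <- NULL
  list(persons = persons, events = events,
       truth = c(truth, list(exposed = exposed, outcome = outcome)))
}
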