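test_that("cohort construction applies qualification, windows and thresholds", {
  reg <- toy_registry()
  coh <- build_cohort(reg$persons, reg$events, reg$window,
                      reg$qualifying, reg$groups)
  # P3 has only a cardiotonic prescription: excluded from the cohort
  expect_false("P3" %in% coh$person_id)
  expect_setequal(coh$person_id, c("P1", "P2", "P4", "P5", "P6"))
  # manual tally of flags (P5's lithium event predates the window)
  expect_equal(stats::setNames(coh$Li, coh$person_id),
               c(P1 = TRUE, P2 = FALSE, P4 = FALSE, P5 = FALSE, P6 = TRUE))
  expect_equal(stats::setNames(coh$CTS, coh$person_id),
               c(P1 = TRUE, P2 = FALSE, P4 = TRUE, P5 = FALSE, P6 = TRUE))
  expect_equal(coh$n_Li[coh$person_id == "P1"], 3L)
  # age in whole years at window end (2020-12-31)
  expect_equal(coh$age[coh$person_id == "P1"], 70)
  expect_equal(coh$age[coh$person_id == "P4"], 75)

  # threshold rule: many lithium events, one digoxin event
  p1 <- reg$persons[reg$persons$person_id == "P1", ]
  ev <- data.frame(
    person_id = "P1",
    atc_code = c(rep("N05AN01", 12), "C01AA05"),
    dispense_date = as.Date("2016-01-01") + seq_len(13),
    stringsAsFactors = FALSE)
  coh10 <- build_cohort(p1, ev, reg$window, reg$qualifying, reg$groups,
                        thresholds = list(Li = 10, CTS = 10))
  expect_true(coh10$Li)
  expect_false(coh10$CTS)

  # filters
  coh_age <- build_cohort(reg$persons, reg$events, reg$window,
                          reg$qualifying, reg$groups, min_age = 60)
  expect_setequal(coh_age$person_id, c("P1", "P4", "P6"))
  coh_m <- build_cohort(reg$persons, reg$events, reg$window,
                        reg$qualifying, reg$groups, sex_filter = "male")
  expect_setequal(coh_m$person_id, c("P2", "P4", "P6"))

  # unknown person in events is a hard error listing the id
  bad <- rbind(reg$events,
               data.frame(person_id = "P99", atc_code = "N05AN01",
                          dispense_date = as.Date("2016-01-01")))
  expect_error(build_cohort(reg$persons, bad, reg$window, reg$qualifying,
                            reg$groups), "P99")
  # malformed ATC codes are rejected
  bad2 <- reg$events
  bad2$atc_code[1] <- "XXX"
  expect_error(build_cohort(reg$persons, bad2, reg$window, reg$qualifying,
                            reg$groups), "ATC")
})

test_that("cohorts are invariant to record duplication and joint date shifts", {
  reg <- toy_registry()
  base <- build_cohort(reg$persons, reg$events, reg$window,
                       reg$qualifying, reg$groups)
  # duplicating every event leaves all flags unchanged (counts double)
  dup <- build_cohort(reg$persons, rbind(reg$events, reg$events),
                      reg$window, reg$qualifying, reg$groups)
  expect_equal(dup$Li, base$Li)
  expect_equal(dup$CTS, base$CTS)
  expect_equal(dup$n_Li, 2L * base$n_Li)
  # shifting all dates and the window by the same offset changes nothing
  off <- 400
  persons2 <- reg$persons
  persons2$birth_date <- persons2$birth_date + off
  events2 <- reg$events
  events2$dispense_date <- events2$dispense_date + off
  shifted <- build_cohort(persons2, events2, reg$window + off,
                          reg$qualifying, reg$groups)
  for (col in names(base))
    expect_equal(shifted[[col]], base[[col]], label = col)
})

test_that("raising a count threshold never increases the exposed count", {
  sim <- simulate_registry(N = 2000, seed = 31)
  win <- as.Date(c("2010-01-01", "2021-12-31"))
  gm <- list(Li = "N05AN01", CTS = c("C01AA05", "C01AA04"))
  exposed <- vapply(c(1, 2, 5, 10, 20), function(thr) {
    coh <- build_cohort(sim$persons, sim$events, win, c("N05", "N06"), gm,
                        thresholds = list(CTS = thr))
    sum(coh$CTS)
  }, 0)
  expect_true(all(diff(exposed) <= 0))
})

test_that("2x2 tables and the crude Woolf log odds have their closed forms", {
  reg <- toy_registry()
  coh <- build_cohort(reg$persons, reg$events, reg$window,
                      reg$qualifying, reg$groups)
  tt <- contingency(coh, "CTS", "Li")
  # manual count: P1 & P6 both; P4 CTS only; P2, P5 neither
  expect_equal(unclass(tt)[c("a", "b", "c", "d")],
               list(a = 2L, b = 1L, c = 0L, d = 2L))

  # all-false cohort
  coh$CTS[] <- FALSE; coh$Li[] <- FALSE
  t0 <- contingency(coh, "CTS", "Li")
  expect_equal(t0$d, nrow(coh))
  expect_equal(t0$a + t0$b + t0$c, 0L)

  # symmetric table: logOR = 0, SE = sqrt(4/10) = 0.6325
  sym <- crude_log_odds(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(sym$logOR, 0)
  expect_equal(sym$SE, 0.6324555, tolerance = 1e-6)

  # cells reconstructed from the full-cohort co-prescription marginals
  all_row <- crude_log_odds(list(a = 88, b = 33146, c = 17400, d = 1875618))
  expect_equal(round(all_row$logOR, 4), -1.2511)
  expect_equal(round(all_row$SE, 4), 0.1070)
  expect_equal(c(all_row$ci_lo, all_row$ci_hi), c(-1.461, -1.041),
               tolerance = 1e-3)

  # zero cells error without the continuity correction, and shift with it
  expect_error(crude_log_odds(list(a = 0, b = 5, c = 5, d = 5)),
               "continuity")
  cont <- crude_log_odds(list(a = 0, b = 5, c = 5, d = 5),
                         continuity = TRUE)
  expect_equal(cont$logOR, log(0.5 * 5.5 / (5.5 * 5.5)))
  expect_equal(crude_log_odds(list(a = 1, b = 1, c = 1, d = 1))$logOR, 0)
})

test_that("Newton-Raphson logistic fits agree with glm to high precision", {
  set.seed(12)
  N <- 4000
  x1 <- rbinom(N, 1, 0.3)
  x2 <- rnorm(N, 50, 10)
  y <- rbinom(N, 1, plogis(-2 + 0.8 * x1 + 0.02 * x2))
  X <- cbind(1, x1, x2)
  fit <- logistic_regression(X, y)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$table$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(fit$converged)
  # deviance decreases monotonically across Newton iterations
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))
  # Wald CI identity
  expect_equal(fit$table$ci_lo, fit$table$estimate - 1.96 * fit$table$se)

  # frequency weights reproduce the expanded fit
  w <- sample(1:3, 200, replace = TRUE)
  xw <- rbinom(200, 1, 0.5)
  yw <- rbinom(200, 1, plogis(-1 + xw))
  fit_w <- logistic_regression(cbind(1, xw), yw, weights = w)
  fit_e <- logistic_regression(cbind(1, rep(xw, w)), rep(yw, w))
  expect_equal(unname(fit_w$coefficients), unname(fit_e$coefficients),
               tolerance = 1e-8)

  # rank deficiency is an error naming the collinear column
  expect_error(logistic_regression(cbind(1, x1, x1), y), "collinear")
})

test_that("exposure-only logistic on a 2x2-collapsible dataset equals ln(ad/bc)", {
  cells <- list(a = 20, b = 80, c = 30, d = 170)
  x <- rep(c(1, 1, 0, 0), unlist(cells))
  y <- rep(c(1, 0, 1, 0), unlist(cells))
  fit <- logistic_regression(cbind(`(Intercept)` = 1, exposure = x), y)
  oracle <- crude_log_odds(cells)
  expect_equal(unname(fit$coefficients["exposure"]), oracle$logOR,
               tolerance = 1e-6)
  expect_equal(fit$table$se[fit$table$term == "exposure"], oracle$SE,
               tolerance = 1e-6)
})

test_that("null exposure effects are recovered near zero and separation is flagged", {
  set.seed(77)
  N <- 50000
  x <- rbinom(N, 1, 0.05)
  y <- rbinom(N, 1, 0.02)          # independent of x
  fit <- logistic_regression(cbind(1, x), y)
  est <- fit$coefficients[2]
  se <- fit$table$se[2]
  expect_lt(abs(est), 3 * se)

  # perfectly separated data: flag, warning, non-converged
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  expect_warning(sep <- logistic_regression(cbind(1, xs), ys),
                 "separation")
  expect_false(sep$converged)
  expect_true(sep$separated)
})

test_that("fit_logistic encodes covariates like glm with female reference", {
  sim <- simulate_registry(N = 20000, seed = 5)
  win <- as.Date(c("2010-01-01", "2021-12-31"))
  gm <- list(Li = "N05AN01", CTS = c("C01AA05", "C01AA04"))
  coh <- build_cohort(sim$persons, sim$events, win, c("N05", "N06"), gm)
  fit <- fit_logistic(coh, "Li", "CTS")
  ref <- glm(Li ~ CTS + age + factor(sex, levels = c("female", "male")),
             data = coh, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$table$term,
               c("(Intercept)", "CTS", "age", "sexmale"))
  # age bands instead of linear age
  fitb <- fit_logistic(coh, "Li", "CTS", age_bands = c(0, 40, 70, 200))
  expect_true(any(grepl("^age\\[", fitb$table$term)))
})

test_that("the sensitivity grid emits the six standard rows and survives failures", {
  sim <- simulate_registry(N = 100000, seed = 13)
  win <- as.Date(c("2010-01-01", "2021-12-31"))
  gm <- list(Li = "N05AN01", CTS = c("C01AA05", "C01AA04"))
  grid <- sensitivity_grid(sim$persons, sim$events, win, c("N05", "N06"),
                           gm, exposure = "CTS", outcome = "Li")
  expect_equal(grid$label, c("ALL", "Pr >= 10", ">40 years", ">70 years",
                             "men", "women"))
  expect_true(all(is.finite(grid$estimate)))
  # injected negative association shows up in every stratum
  expect_true(all(grid$estimate < 0))
  expect_true(all(grid$n_total[-1] <= grid$n_total[1], na.rm = TRUE))

  # an impossible stratum yields an NA row but the grid continues
  rows <- list(list(label = "ALL"), list(label = "imposs", min_age = 200))
  g2 <- suppressMessages(
    sensitivity_grid(sim$persons, sim$events, win, c("N05", "N06"), gm,
                     "CTS", "Li", rows = rows))
  expect_true(is.na(g2$estimate[2]))
  expect_false(is.na(g2$estimate[1]))

  # TSV + JSON emission round-trips the row estimates
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_grid(grid, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(back$estimate, grid$estimate, tolerance = 1e-9)
  expect_length(jsonlite::read_json(js), nrow(grid))
})

test_that("registry CSV readers validate and round-trip", {
  reg <- toy_registry()
  pdir <- withr::local_tempdir()
  pp <- file.path(pdir, "persons.csv")
  ep <- file.path(pdir, "events.csv")
  utils::write.csv(reg$persons, pp, row.names = FALSE, na = "")
  utils::write.csv(reg$events, ep, row.names = FALSE)
  persons <- read_persons(pp)
  events <- read_events(ep)
  expect_equal(persons$person_id, reg$persons$person_id)
  expect_s3_class(persons$birth_date, "Date")
  expect_true(all(is.na(persons$death_date)))
  expect_equal(events$atc_code, reg$events$atc_code)
  # malformed ATC in the file is rejected on read
  bad <- reg$events; bad$atc_code[2] <- "12345"
  utils::write.csv(bad, ep, row.names = FALSE)
  expect_error(read_events(ep), "ATC")
})
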