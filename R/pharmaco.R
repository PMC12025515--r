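# Cohort construction from longitudinal prescription records (ATC-coded
# dispensing events) and co-prescription association analysis: crude 2x2
# odds ratios with Woolf standard errors, covariate-adjusted logistic
# fits, and the sensitivity grid over count thresholds, age restrictions
# and sex strata.

ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Read a persons table from CSV
#'
#' Columns: `person_id`, `sex` (male/female), `birth_date`, `death_date`
#' (ISO-8601; empty death date means alive).
#'
#' @param path CSV path.
#' @return data frame with `Date` columns.
#' @export
read_persons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("person_id", "sex", "birth_date") %in% names(df)))
  df$birth_date <- as.Date(df$birth_date)
  df$death_date <- if ("death_date" %in% names(df))
    as.Date(ifelse(df$death_date == "", NA, df$death_date)) else
      as.Date(rep(NA, nrow(df)))
  validate_persons(df)
  df
}

#' Read a prescription-events table from CSV
#'
#' Columns: `person_id`, `atc_code` (7-character WHO ATC code, e.g.
#' `N05AN01` for lithium), `dispense_date` (ISO-8601).
#'
#' @param path CSV path.
#' @return data frame with a `Date` dispense column.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("person_id", "atc_code", "dispense_date") %in% names(df)))
  df$dispense_date <- as.Date(df$dispense_date)
  bad <- !grepl(ATC_PATTERN, df$atc_code)
  if (any(bad))
    stop("malformed ATC code(s): ",
         paste(utils::head(unique(df$atc_code[bad]), 5), collapse = ", "))
  df
}

validate_persons <- function(persons) {
  if (anyDuplicated(persons$person_id))
    stop("duplicate person_id in persons table")
  if (!all(persons$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  bad <- !is.na(persons$death_date) & persons$death_date < persons$birth_date
  if (any(bad))
    stop("death before birth for person(s): ",
         paste(utils::head(persons$person_id[bad], 5), collapse = ", "))
  invisible(persons)
}

# TRUE where an ATC code falls under any of the given codes/prefixes
atc_matches <- function(codes, code_set) {
  hit <- rep(FALSE, length(codes))
  for (p in code_set) hit <- hit | startsWith(codes, p)
  hit
}

#' Build a binary-exposure cohort from prescription records
#'
#' Restricts to persons with at least one in-window dispensing event whose
#' ATC code falls under `qualifying_atc` (the psychiatric-medication
#' qualifying set), then derives, per drug group in `group_map`, the
#' in-window prescription count and a binary exposure flag
#' (count >= threshold, default 1). Age is computed in whole years at the
#' reference date (window end by default). ATC sets may contain full
#' 7-character codes or prefixes (e.g. `"N05"` covers all psycholeptics).
#'
#' @param persons data frame as from [read_persons()].
#' @param events data frame as from [read_events()].
#' @param window length-2 `Date` vector, inclusive observation window.
#' @param qualifying_atc character vector of ATC codes/prefixes defining
#'   cohort membership.
#' @param group_map named list: drug-group name -> ATC codes/prefixes.
#' @param thresholds named numeric vector/list: group -> minimum in-window
#'   prescription count for a positive flag (default 1 for every group).
#' @param min_age retain persons of at least this age in whole years at the
#'   reference date (default 0).
#' @param sex_filter optional `"male"` or `"female"`.
#' @param age_ref reference date for age: `"window_end"` (default),
#'   `"window_start"`, or `"first_qualifying"` (first in-window qualifying
#'   prescription).
#' @param require_alive if TRUE, drop persons who died before the window
#'   start (default FALSE: prescription-ever semantics).
#' @return an object of class `cohort_matrix`: data frame with columns
#'   `person_id`, `age`, `sex`, one logical flag column per group and one
#'   `n_<group>` count column per group.
#' @export
build_cohort <- function(persons, events, window, qualifying_atc, group_map,
                         thresholds = NULL, min_age = 0, sex_filter = NULL,
                         age_ref = c("window_end", "window_start",
                                     "first_qualifying"),
                         require_alive = FALSE) {
  age_ref <- match.arg(age_ref)
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] < window[2])
  stopifnot(is.list(group_map), length(group_map) > 0,
            !is.null(names(group_map)))
  if (any(vapply(group_map, length, 1L) == 0))
    stop("every drug group needs a non-empty ATC code set")
  validate_persons(persons)

  pid_idx <- match(events$person_id, persons$person_id)
  if (anyNA(pid_idx))
    stop("events reference unknown person(s): ",
         paste(utils::head(unique(events$person_id[is.na(pid_idx)]), 5),
               collapse = ", "))
  bad <- !grepl(ATC_PATTERN, events$atc_code)
  if (any(bad))
    stop("malformed ATC code(s): ",
         paste(utils::head(unique(events$atc_code[bad]), 5), collapse = ", "))

  N <- nrow(persons)
  in_win <- events$dispense_date >= window[1] &
    events$dispense_date <= window[2]
  qual <- in_win & atc_matches(events$atc_code, qualifying_atc)
  qualifies <- tabulate(pid_idx[qual], nbins = N) > 0

  counts <- matrix(0L, nrow = N, ncol = length(group_map),
                   dimnames = list(NULL, names(group_map)))
  for (g in names(group_map)) {
    sel <- in_win & atc_matches(events$atc_code, group_map[[g]])
    counts[, g] <- tabulate(pid_idx[sel], nbins = N)
  }

  ref_date <- switch(age_ref,
    window_end = rep(window[2], N),
    window_start = rep(window[1], N),
    first_qualifying = {
      rd <- rep(window[2], N)
      ev <- events[qual, , drop = FALSE]
      idx <- pid_idx[qual]
      ord <- order(ev$dispense_date)
      first <- !duplicated(idx[ord])
      rd[idx[ord][first]] <- ev$dispense_date[ord][first]
      rd
    })
  age <- floor(as.numeric(ref_date - persons$birth_date) / 365.25)

  keep <- qualifies & age >= min_age
  if (!is.null(sex_filter)) {
    stopifnot(sex_filter %in% c("male", "female"))
    keep <- keep & persons$sex == sex_filter
  }
  if (require_alive)
    keep <- keep & (is.na(persons$death_date) |
                      persons$death_date >= window[1])
  if (!any(keep)) stop("empty cohort after restriction")

  out <- data.frame(person_id = persons$person_id[keep],
                    age = age[keep], sex = persons$sex[keep],
                    stringsAsFactors = FALSE)
  thr <- stats::setNames(rep(1, length(group_map)), names(group_map))
  if (!is.null(thresholds)) thr[names(thresholds)] <- unlist(thresholds)
  for (g in names(group_map)) {
    out[[g]] <- counts[keep, g] >= thr[[g]]
    out[[paste0("n_", g)]] <- counts[keep, g]
  }
  structure(out, class = c("cohort_matrix", "data.frame"),
            window = window, groups = names(group_map), thresholds = thr)
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", format(nrow(x), big.mark = ","), "persons; window",
      paste(attr(x, "window"), collapse = " .. "), "\n")
  for (g in attr(x, "groups"))
    cat(sprintf("  %s: %s exposed (threshold %g)\n", g,
                format(sum(x[[g]]), big.mark = ","),
                attr(x, "thresholds")[[g]]))
  invisible(x)
}

#' Cross-tabulate two binary drug-group flags
#'
#' @param cohort a [build_cohort()] result.
#' @param exposure,outcome drug-group names (flag columns).
#' @return an object of class `two_by_two`: list with cells `a`
#'   (exposure and outcome), `b` (exposure only), `c` (outcome only),
#'   `d` (neither).
#' @export
contingency <- function(cohort, exposure, outcome) {
  stopifnot(exposure %in% names(cohort), outcome %in% names(cohort))
  e <- cohort[[exposure]]; o <- cohort[[outcome]]
  structure(list(a = sum(e & o), b = sum(e & !o),
                 c = sum(!e & o), d = sum(!e & !o)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome", "no outcome")))
  print(m)
  invisible(x)
}

#' Crude log odds ratio from a 2x2 table with Woolf standard error
#'
#' `logOR = ln(ad / bc)` with Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, a symmetric 95% Wald interval and a
#' two-sided normal p-value. With `continuity = TRUE`, 0.5 is added to
#' every cell whenever any cell is zero (Haldane-Anscombe correction).
#'
#' @param t a [contingency()] result or list with cells `a`, `b`, `c`, `d`.
#' @param continuity apply the 0.5 correction when a cell is zero.
#' @return list with `logOR`, `SE`, `ci_lo`, `ci_hi`, `p`
#'   (class `crude_odds`).
#' @export
crude_log_odds <- function(t, continuity = FALSE) {
  cells <- c(t$a, t$b, t$c, t$d)
  stopifnot(length(cells) == 4, all(cells >= 0))
  if (any(cells == 0)) {
    if (!continuity)
      stop("zero cell in 2x2 table; consider continuity = TRUE ",
           "(adds 0.5 to every cell)")
    cells <- cells + 0.5
  }
  logOR <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  SE <- sqrt(sum(1 / cells))
  structure(list(logOR = logOR, SE = SE,
                 ci_lo = logOR - 1.96 * SE, ci_hi = logOR + 1.96 * SE,
                 p = 2 * stats::pnorm(-abs(logOR / SE))),
            class = "crude_odds")
}

#' @export
print.crude_odds <- function(x, ...) {
  cat(sprintf("crude log OR = %.4f (Woolf SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$logOR, x$SE, x$ci_lo, x$ci_hi, x$p))
  invisible(x)
}

#' Covariate-adjusted logistic fit on a cohort
#'
#' Regresses the outcome drug-group flag on the exposure flag(s) plus the
#' requested covariates by Newton-Raphson maximum likelihood
#' ([logistic_regression()]). Sex enters as a male indicator (female is
#' the reference level); age enters linearly in years, or in bands when
#' `age_bands` is given.
#'
#' @param cohort a [build_cohort()] result.
#' @param outcome outcome drug-group name.
#' @param exposures character vector of exposure drug-group names.
#' @param covariates subset of `c("age", "sex")` (default both).
#' @param age_bands optional numeric breaks; age is then one-hot encoded
#'   against the first band instead of entering linearly.
#' @param tol,max_iter convergence control for [logistic_regression()].
#' @return a `logistic_fit`.
#' @export
fit_logistic <- function(cohort, outcome, exposures,
                         covariates = c("age", "sex"), age_bands = NULL,
                         tol = 1e-8, max_iter = 25) {
  stopifnot(outcome %in% names(cohort), all(exposures %in% names(cohort)))
  y <- as.numeric(cohort[[outcome]])
  X <- cbind(`(Intercept)` = rep(1, nrow(cohort)))
  for (e in exposures) {
    X <- cbind(X, as.numeric(cohort[[e]]))
    colnames(X)[ncol(X)] <- e
  }
  if ("age" %in% covariates) {
    if (is.null(age_bands)) {
      X <- cbind(X, age = cohort$age)
    } else {
      band <- cut(cohort$age, breaks = age_bands, include.lowest = TRUE,
                  right = FALSE)
      for (l in levels(band)[-1]) {
        X <- cbind(X, as.numeric(band == l))
        colnames(X)[ncol(X)] <- paste0("age", l)
      }
    }
  }
  if ("sex" %in% covariates) {
    X <- cbind(X, sexmale = as.numeric(cohort$sex == "male"))
  }
  logistic_regression(X, y, tol = tol, max_iter = max_iter)
}

default_grid_rows <- function() list(
  list(label = "ALL"),
  list(label = "Pr >= 10", threshold = 10),
  list(label = ">40 years", min_age = 41),
  list(label = ">70 years", min_age = 71),
  list(label = "men", sex = "male"),
  list(label = "women", sex = "female")
)

#' Sensitivity grid of cohort restrictions and logistic fits
#'
#' Re-derives the cohort and refits the adjusted logistic model under a
#' list of row specifications (prescription-count threshold for exposure
#' and outcome groups, minimum age, sex restriction). The default rows are
#' the full cohort, a count >= 10 positivity rule, age > 40, age > 70, and
#' the two sexes. Rows that fail (e.g. an empty stratum) are reported with
#' NA statistics and the grid continues.
#'
#' @param persons,events,window,qualifying_atc,group_map as
#'   [build_cohort()].
#' @param exposure,outcome drug-group names for the association of
#'   interest.
#' @param covariates passed to [fit_logistic()].
#' @param rows list of row specs: `label`, optional `threshold` (applied
#'   to both exposure and outcome groups), `min_age`, `sex`.
#' @return an object of class `sensitivity_grid`: data frame with one row
#'   per spec — `label`, `estimate` (adjusted log odds), `ci_lo`, `ci_hi`,
#'   `p`, cells `a` (both), `n_outcome`, `n_exposure`, `n_total`,
#'   `converged`; fits attached as attribute `fits`.
#' @export
sensitivity_grid <- function(persons, events, window, qualifying_atc,
                             group_map, exposure, outcome,
                             covariates = c("age", "sex"),
                             rows = default_grid_rows()) {
  res <- vector("list", length(rows))
  fits <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    spec <- rows[[i]]
    lab <- spec$label %||% paste0("row", i)
    res[[i]] <- tryCatch({
      thr <- NULL
      if (!is.null(spec$threshold))
        thr <- stats::setNames(rep(spec$threshold, 2), c(exposure, outcome))
      cohort <- build_cohort(persons, events, window, qualifying_atc,
                             group_map, thresholds = thr,
                             min_age = spec$min_age %||% 0,
                             sex_filter = spec$sex)
      # sex is constant within a sex-restricted stratum
      covs <- if (is.null(spec$sex)) covariates else
        setdiff(covariates, "sex")
      fit <- fit_logistic(cohort, outcome, exposure, covs)
      fits[[i]] <- fit
      tab <- fit$table[fit$table$term == exposure, ]
      tt <- contingency(cohort, exposure, outcome)
      data.frame(label = lab, estimate = tab$estimate, ci_lo = tab$ci_lo,
                 ci_hi = tab$ci_hi, p = tab$p, a = tt$a,
                 n_outcome = tt$a + tt$c, n_exposure = tt$a + tt$b,
                 n_total = nrow(cohort), converged = fit$converged,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("sensitivity row '", lab, "' failed: ", conditionMessage(e))
      data.frame(label = lab, estimate = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, p = NA_real_, a = NA_integer_,
                 n_outcome = NA_integer_, n_exposure = NA_integer_,
                 n_total = NA_integer_, converged = FALSE,
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_grid", "data.frame"),
            fits = fits, exposure = exposure, outcome = outcome)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("sensitivity_grid:", attr(x, "exposure"), "->", attr(x, "outcome"),
      "(adjusted log odds)\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 3)
  df$ci_lo <- round(df$ci_lo, 3)
  df$ci_hi <- round(df$ci_hi, 3)
  df$p <- signif(df$p, 3)
  print.data.frame(df)
  invisible(x)
}

#' Write a sensitivity grid as TSV plus structured JSON
#'
#' @param grid a [sensitivity_grid()] result.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, the grid.
#' @export
write_grid <- function(grid, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(grid), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    fits <- attr(grid, "fits")
    payload <- lapply(seq_len(nrow(grid)), function(i) {
      row <- as.list(as.data.frame(grid)[i, ])
      if (!is.null(fits[[i]])) row$coefficients <- fits[[i]]$table
      row
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(grid)
}
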