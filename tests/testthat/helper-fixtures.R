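# fixtures built in code: tiny expression studies and a hand-tallied
# six-person prescription registry

make_study <- function(mat, groups, covariates = NULL) {
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  ann <- data.frame(sample_id = colnames(mat), group = groups,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) ann <- cbind(ann, covariates)
  expression_study(mat, ann)
}

random_study <- function(G, n_per_group, seed, delta = 0) {
  set.seed(seed)
  m <- matrix(rnorm(G * 2 * n_per_group), G)
  m[, seq_len(n_per_group)] <- m[, seq_len(n_per_group)] + delta
  make_study(m, rep(c("case", "control"), each = n_per_group))
}

random_zprof <- function(G, seed) {
  set.seed(seed)
  stats::setNames(rnorm(G), sprintf("GENE%05d", seq_len(G)))
}

# six persons; window 2015-01-01 .. 2020-12-31
# P1: 3 lithium events in window, 1 digoxin in window   -> Li, CTS (thr 1)
# P2: 1 sertraline event in window                      -> neither
# P3: 1 digitoxin in window only (no psychiatric)       -> excluded
# P4: 2 digoxin + 1 diazepam in window                  -> CTS
# P5: 1 lithium event BEFORE the window + 1 sertraline  -> neither
# P6: 1 lithium + 1 digoxin in window                   -> Li, CTS
toy_registry <- function() {
  persons <- data.frame(
    person_id = paste0("P", 1:6),
    sex = c("female", "male", "female", "male", "female", "male"),
    birth_date = as.Date(c("1950-06-15", "1980-01-01", "1960-03-10",
                           "1945-12-31", "1990-07-04", "1955-05-05")),
    death_date = as.Date(c(NA, NA, NA, NA, NA, NA)),
    stringsAsFactors = FALSE)
  events <- data.frame(
    person_id = c("P1", "P1", "P1", "P1",
                  "P2",
                  "P3",
                  "P4", "P4", "P4",
                  "P5", "P5",
                  "P6", "P6"),
    atc_code = c("N05AN01", "N05AN01", "N05AN01", "C01AA05",
                 "N06AB06",
                 "C01AA04",
                 "C01AA05", "C01AA05", "N05BA01",
                 "N05AN01", "N06AB06",
                 "N05AN01", "C01AA05"),
    dispense_date = as.Date(c("2016-02-01", "2017-03-01", "2018-04-01",
                              "2016-06-01",
                              "2019-01-15",
                              "2018-08-08",
                              "2015-05-05", "2016-06-06", "2017-07-07",
                              "2014-12-31", "2018-09-09",
                              "2020-10-10", "2020-11-11")),
    stringsAsFactors = FALSE)
  list(persons = persons, events = events,
       window = as.Date(c("2015-01-01", "2020-12-31")),
       qualifying = c("N05", "N06"),
       groups = list(Li = "N05AN01", CTS = c("C01AA05", "C01AA04")))
}
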