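# Stage orchestration: each stage reads validated inputs, writes its
# outputs atomically (temp file + rename) together with a JSON run
# manifest (parameters, seed, input checksums, package version), and never
# mutates its inputs. Logging goes to stderr; file artifacts are the only
# results.

PIPELINE_STAGES <- c("de", "combine", "connect", "concord", "epi",
                     "simulate-expression", "simulate-library",
                     "simulate-registry", "demo")

log_msg <- function(level, ..., log_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[log_level]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

# write a table/text artifact atomically
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

write_manifest <- function(out_dir, stage, params, inputs = character()) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage, parameters = params,
                   input_checksums = checksums,
                   package = "sigrev",
                   version = as.character(utils::packageVersion("sigrev")))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Read a pipeline configuration file (YAML)
#'
#' @param path YAML file; top-level keys are stage names plus shared keys
#'   (`seed`, `out`).
#' @return the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run one pipeline stage
#'
#' Stages: `simulate-expression`, `simulate-library`, `simulate-registry`
#' (synthetic inputs), `de` (differential profile), `combine` (composite
#' meta-profile), `connect` (connectivity table), `concord` (sign
#' concordance), `epi` (cohort + sensitivity grid), and `demo` (a seeded
#' end-to-end run of all stages). Outputs are written under `out_dir`
#' together with a per-stage JSON manifest.
#'
#' @param stage stage name.
#' @param config configuration list (see the package vignette) or a path
#'   to a YAML file.
#' @param out_dir output directory (created if missing); overrides
#'   `config$out`.
#' @param seed integer seed for stages that draw random numbers; overrides
#'   `config$seed`.
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_stage <- function(stage, config = list(), out_dir = NULL, seed = NULL,
                      log_level = "info") {
  if (!stage %in% PIPELINE_STAGES)
    stop("unknown stage '", stage, "'; available: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  if (is.character(config)) config <- read_config(config)
  out_dir <- out_dir %||% config$out %||% "."
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("info", "stage ", stage, " -> ", out_dir, " (seed ", seed, ")",
          log_level = log_level)

  artifacts <- switch(stage,
    "simulate-expression" = stage_sim_expression(config, out_dir, seed),
    "simulate-library" = stage_sim_library(config, out_dir, seed),
    "simulate-registry" = stage_sim_registry(config, out_dir, seed),
    "de" = stage_de(config, out_dir),
    "combine" = stage_combine(config, out_dir),
    "connect" = stage_connect(config, out_dir),
    "concord" = stage_concord(config, out_dir),
    "epi" = stage_epi(config, out_dir),
    "demo" = stage_demo(config, out_dir, seed, log_level))
  invisible(artifacts)
}

stage_sim_expression <- function(config, out_dir, seed) {
  p <- config$simulate_expression %||% list()
  sim <- simulate_expression_studies(
    n_studies = p$n_studies %||% 3, G = p$genes %||% 2000,
    n_case = p$n_case %||% 10, n_ctrl = p$n_ctrl %||% 10,
    sparsity = p$sparsity %||% 0.05, delta = p$delta %||% 1,
    sigma = p$sigma %||% 1, seed = seed)
  paths <- character()
  for (nm in names(sim$studies)) {
    st <- sim$studies[[nm]]
    mp <- file.path(out_dir, paste0(nm, "_matrix.tsv"))
    ap <- file.path(out_dir, paste0(nm, "_samples.tsv"))
    atomic_write(function(f) {
      df <- data.frame(gene = rownames(st$matrix), st$matrix,
                       check.names = FALSE)
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }, mp)
    atomic_write(function(f)
      utils::write.table(st$samples, f, sep = "\t", quote = FALSE,
                         row.names = FALSE), ap)
    paths <- c(paths, mp, ap)
  }
  tp <- file.path(out_dir, "expression_truth.json")
  jsonlite::write_json(list(affected = sim$truth$affected,
                            multipliers = sim$truth$multipliers,
                            sigma = sim$truth$sigma),
                       tp, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate-expression",
                 c(p, list(seed = seed)))
  list(files = paths, truth = tp)
}

stage_sim_library <- function(config, out_dir, seed) {
  p <- config$simulate_library %||% list()
  signature <- if (!is.null(p$signature_profile)) {
    as_z_profile(read_profile(p$signature_profile))
  } else {
    set.seed(seed + 1L)
    stats::setNames(stats::rnorm(p$genes %||% 1000),
                    sprintf("GENE%05d", seq_len(p$genes %||% 1000)))
  }
  sim <- simulate_drug_library(signature, M = p$compounds %||% 100,
                               planted = p$planted %||% 5,
                               rho = p$rho %||% 0.5, seed = seed)
  lp <- file.path(out_dir, "library.tsv")
  atomic_write(function(f) write_library(sim$library, f), lp)
  tp <- file.path(out_dir, "library_truth.json")
  jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate-library", c(p, list(seed = seed)))
  list(library = lp, truth = tp)
}

stage_sim_registry <- function(config, out_dir, seed) {
  p <- config$simulate_registry %||% list()
  tr_args <- p$truth %||% list()
  sim <- simulate_registry(
    N = p$persons %||% 50000,
    truth = do.call(registry_truth, tr_args),
    window = as.Date(p$window %||% c("2010-01-01", "2021-12-31")),
    seed = seed)
  pp <- file.path(out_dir, "persons.csv")
  ep <- file.path(out_dir, "events.csv")
  atomic_write(function(f) utils::write.csv(sim$persons, f,
                                            row.names = FALSE, na = ""), pp)
  atomic_write(function(f) utils::write.csv(sim$events, f,
                                            row.names = FALSE), ep)
  tp <- file.path(out_dir, "registry_truth.json")
  jsonlite::write_json(sim$truth[c("beta0", "beta_exposure", "beta_age",
                                   "beta_sex", "lambda")],
                       tp, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate-registry", c(p, list(seed = seed)))
  list(persons = pp, events = ep, truth = tp)
}

stage_de <- function(config, out_dir) {
  p <- config$de %||% list()
  if (is.null(p$matrix) || is.null(p$annotations))
    stop("de stage needs config$de$matrix and config$de$annotations")
  for (f in c(p$matrix, p$annotations))
    if (!file.exists(f)) stop("input file not found: ", f)
  study <- load_expression_table(p$matrix, p$annotations)
  prof <- differential_profile(study,
                               contrast = unlist(p$contrast %||%
                                                   c("case", "control")),
                               covariates = unlist(p$covariates %||%
                                                     character()))
  if (!is.null(p$species) && p$species != "human")
    prof <- harmonize_symbols(prof, p$species)
  out <- file.path(out_dir, p$name %||% "profile.tsv")
  atomic_write(function(f) write_profile(prof, f), out)
  write_manifest(out_dir, "de", p, c(p$matrix, p$annotations))
  list(profile = out)
}

stage_combine <- function(config, out_dir) {
  p <- config$combine %||% list()
  if (is.null(p$profiles) || length(p$profiles) == 0)
    stop("combine stage needs config$combine$profiles (list of paths)")
  for (f in unlist(p$profiles))
    if (!file.exists(f)) stop("input file not found: ", f)
  profs <- lapply(unlist(p$profiles), read_profile)
  names(profs) <- basename(unlist(p$profiles))
  comp <- combine_profiles(profs, min_studies = p$min_studies %||% 1)
  out <- file.path(out_dir, p$name %||% "composite.tsv")
  atomic_write(function(f) write_profile(comp, f), out)
  write_manifest(out_dir, "combine", p, unlist(p$profiles))
  list(composite = out)
}

stage_connect <- function(config, out_dir) {
  p <- config$connect %||% list()
  if (is.null(p$query) || is.null(p$library))
    stop("connect stage needs config$connect$query and $library")
  for (f in c(p$query, p$library))
    if (!file.exists(f)) stop("input file not found: ", f)
  tab <- score_library(read_profile(p$query), read_library(p$library),
                       min_overlap = p$min_overlap %||% 50)
  out <- file.path(out_dir, "connectivity.tsv")
  atomic_write(function(f)
    utils::write.table(as.data.frame(tab), f, sep = "\t", quote = FALSE,
                       row.names = FALSE), out)
  write_manifest(out_dir, "connect", p, c(p$query, p$library))
  list(connectivity = out)
}

stage_concord <- function(config, out_dir) {
  p <- config$concord %||% list()
  if (is.null(p$a) || is.null(p$b))
    stop("concord stage needs config$concord$a and $b (profile paths)")
  for (f in c(p$a, p$b))
    if (!file.exists(f)) stop("input file not found: ", f)
  res <- sign_concordance(read_profile(p$a), read_profile(p$b),
                          top_k = p$top_k %||% 40)
  out <- file.path(out_dir, "concordance.json")
  jsonlite::write_json(res[c("n_opposite", "n_total", "p", "genes")],
                       out, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "concord", p, c(p$a, p$b))
  list(concordance = out)
}

stage_epi <- function(config, out_dir) {
  p <- config$epi %||% list()
  if (is.null(p$persons) || is.null(p$events))
    stop("epi stage needs config$epi$persons and $events (CSV paths)")
  for (f in c(p$persons, p$events))
    if (!file.exists(f)) stop("input file not found: ", f)
  persons <- read_persons(p$persons)
  events <- read_events(p$events)
  grid <- sensitivity_grid(
    persons, events,
    window = as.Date(unlist(p$window %||% c("2010-01-01", "2021-12-31"))),
    qualifying_atc = unlist(p$qualifying_atc %||% c("N05", "N06")),
    group_map = lapply(p$group_map %||%
                         list(Li = "N05AN01",
                              CTS = c("C01AA05", "C01AA04")), unlist),
    exposure = p$exposure %||% "CTS", outcome = p$outcome %||% "Li")
  tsv <- file.path(out_dir, "sensitivity_grid.tsv")
  js <- file.path(out_dir, "sensitivity_grid.json")
  write_grid(grid, tsv, js)
  write_manifest(out_dir, "epi", p, c(p$persons, p$events))
  list(grid_tsv = tsv, grid_json = js)
}

stage_demo <- function(config, out_dir, seed, log_level) {
  cfg <- utils::modifyList(list(
    simulate_expression = list(n_studies = 3, genes = 2000, n_case = 8,
                               n_ctrl = 8, sparsity = 0.05, delta = 1.5,
                               sigma = 1)
  ), config)
  a <- list()
  a$sim_expr <- run_stage("simulate-expression", cfg, out_dir, seed,
                          log_level)
  profs <- character()
  for (s in seq_len(cfg$simulate_expression$n_studies)) {
    nm <- sprintf("study%02d", s)
    cfg$de <- list(matrix = file.path(out_dir, paste0(nm, "_matrix.tsv")),
                   annotations = file.path(out_dir,
                                           paste0(nm, "_samples.tsv")),
                   contrast = c("case", "control"),
                   name = paste0(nm, "_profile.tsv"))
    profs <- c(profs, run_stage("de", cfg, out_dir,
                                log_level = log_level)$profile)
  }
  cfg$combine <- list(profiles = as.list(profs))
  a$composite <- run_stage("combine", cfg, out_dir, log_level = log_level)
  cfg$simulate_library <- utils::modifyList(
    list(compounds = 60, planted = 5, rho = 0.6),
    c(cfg$simulate_library %||% list(),
      list(signature_profile = a$composite$composite)))
  a$library <- run_stage("simulate-library", cfg, out_dir, seed, log_level)
  cfg$connect <- list(query = a$composite$composite,
                      library = a$library$library, min_overlap = 50)
  a$connect <- run_stage("connect", cfg, out_dir, log_level = log_level)
  cfg$concord <- list(a = profs[1], b = profs[2], top_k = 40)
  a$concord <- run_stage("concord", cfg, out_dir, log_level = log_level)
  cfg$simulate_registry <- utils::modifyList(
    list(persons = 30000), cfg$simulate_registry %||% list())
  a$registry <- run_stage("simulate-registry", cfg, out_dir, seed,
                          log_level)
  cfg$epi <- list(persons = a$registry$persons, events = a$registry$events)
  a$epi <- run_stage("epi", cfg, out_dir, log_level = log_level)
  a
}

#' Command-line entry point for the pipeline
#'
#' Usage: `sigrev <stage> [--config PATH] [--seed INT] [--out DIR]
#' [--log-level LEVEL]`. Exit codes: 0 success, 1 data/stage error,
#' 2 usage error.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (invisibly); callers should `quit(status = )`
#'   with it.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: sigrev <stage> [--config PATH] [--seed INT] ",
                  "[--out DIR] [--log-level LEVEL]\nstages: ",
                  paste(PIPELINE_STAGES, collapse = ", "))
  if (length(argv) < 1 || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv) < 1) 2L else 0L))
  }
  stage <- argv[1]
  if (!stage %in% PIPELINE_STAGES) {
    message("unknown stage '", stage, "'\n", usage)
    return(invisible(2L))
  }
  opts <- list(config = list(), out = NULL, seed = NULL,
               log_level = "info")
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!key %in% c("--config", "--seed", "--out", "--log-level") ||
        i == length(argv)) {
      message("bad argument: ", key, "\n", usage)
      return(invisible(2L))
    }
    val <- argv[i + 1]
    switch(key,
           "--config" = { opts$config <- val },
           "--seed" = { opts$seed <- as.integer(val) },
           "--out" = { opts$out <- val },
           "--log-level" = { opts$log_level <- val })
    i <- i + 2
  }
  status <- tryCatch({
    run_stage(stage, opts$config, out_dir = opts$out, seed = opts$seed,
              log_level = opts$log_level)
    0L
  }, error = function(e) {
    message("[ERROR] stage ", stage, " failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
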