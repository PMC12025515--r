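# Profile file dialect: tab-separated tables with "#"-prefixed metadata
# header lines ("#key: value"). Differential profiles carry columns
# gene/effect/t/p/z, composite profiles gene/S/n.

#' Write a differential or composite profile to TSV
#'
#' Metadata (contrast, species, sample sizes, contributing studies) is
#' stored as `#key: value` header lines above the column header.
#'
#' @param profile a `differential_profile` or `composite_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  meta <- list()
  if (inherits(profile, "differential_profile")) {
    meta$type <- "differential"
    meta$contrast <- paste(attr(profile, "contrast"), collapse = " vs ")
    meta$species <- attr(profile, "species") %||% "unknown"
    meta$n_test <- attr(profile, "n_test")
    meta$n_ref <- attr(profile, "n_ref")
  } else if (inherits(profile, "composite_profile")) {
    meta$type <- "composite"
    meta$sources <- paste(attr(profile, "sources"), collapse = ",")
  } else stop("unsupported profile class")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    if (!is.null(meta[[k]]) && nzchar(meta[[k]]))
      writeLines(sprintf("#%s: %s", k, meta[[k]]), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile TSV written by [write_profile()]
#'
#' @param path file path.
#' @return a `differential_profile` or `composite_profile`, depending on
#'   the file's columns.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- regmatches(l, regexec("^#([^:]+): ?(.*)$", l))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  df <- utils::read.delim(text = lines[setdiff(seq_along(lines), hdr)],
                          stringsAsFactors = FALSE)
  if (all(c("gene", "S", "n") %in% names(df))) {
    structure(df, class = c("composite_profile", "data.frame"),
              sources = strsplit(meta$sources %||% "", ",")[[1]])
  } else if (all(c("gene", "z") %in% names(df))) {
    if (is.null(df$flag)) df$flag <- FALSE
    structure(df, class = c("differential_profile", "data.frame"),
              contrast = strsplit(meta$contrast %||% "", " vs ")[[1]],
              species = meta$species %||% "unknown",
              n_test = as.integer(meta$n_test %||% NA),
              n_ref = as.integer(meta$n_ref %||% NA))
  } else stop("unrecognized profile file: ", path)
}

#' Write a compound-profile library to a long TSV
#'
#' @param library a named list of named z vectors (class `profile_library`).
#' @param path output path; columns `compound`, `gene`, `z`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(is.list(library), !is.null(names(library)))
  df <- do.call(rbind, lapply(names(library), function(cp) {
    z <- library[[cp]]
    data.frame(compound = cp, gene = names(z), z = unname(z),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound-profile library from a long TSV
#'
#' @param path TSV with columns `compound`, `gene`, `z`.
#' @return a `profile_library`: named list of named z vectors.
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "gene", "z") %in% names(df)))
  sp <- split(df, df$compound)
  lib <- lapply(sp, function(d) stats::setNames(d$z, d$gene))
  structure(lib[unique(df$compound)], class = "profile_library")
}
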