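# Expression studies and per-gene differential Z profiles.
#
# The differential stage deliberately uses ordinary per-gene least squares
# with the exact t reference distribution rather than empirical-Bayes
# variance moderation: the Z-score contract downstream only needs a signed
# per-gene p-value, and plain OLS keeps the stage self-contained and
# exactly testable against the classical pooled two-sample t.

#' Construct a validated expression study
#'
#' Bundles a normalized log-scale expression matrix with its sample sheet.
#' Usually created via [load_expression_table()]; exposed so that simulated
#' studies can be built in memory.
#'
#' @param matrix numeric gene-by-sample matrix with unique rownames (gene
#'   symbols) and colnames (sample ids). Values are normalized log-scale
#'   expression, unitless.
#' @param annotations data frame with one row per sample: mandatory columns
#'   `sample_id` and `group`, any further columns are covariates
#'   (categorical or numeric).
#' @return an object of class `expression_study`: a list with elements
#'   `matrix` and `samples` (annotations reordered to match the matrix
#'   columns).
#' @export
expression_study <- function(matrix, annotations) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample ids in matrix")
  if (!all(is.finite(matrix)))
    stop("expression matrix contains non-finite values")
  if (!is.data.frame(annotations) ||
      !all(c("sample_id", "group") %in% names(annotations)))
    stop("annotations must be a data frame with columns sample_id, group")
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample ids in annotations")

  orphan_mat <- setdiff(colnames(matrix), annotations$sample_id)
  orphan_ann <- setdiff(annotations$sample_id, colnames(matrix))
  if (length(orphan_mat) || length(orphan_ann))
    stop("sample ids mismatch between matrix and annotations; ",
         if (length(orphan_mat))
           paste0("missing from annotations: ",
                  paste(orphan_mat, collapse = ", "), "; ") else "",
         if (length(orphan_ann))
           paste0("missing from matrix: ",
                  paste(orphan_ann, collapse = ", ")) else "")
  if (any(is.na(annotations$group)) || any(annotations$group == ""))
    stop("every sample needs a group label")

  annotations <- annotations[match(colnames(matrix), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(matrix = matrix, samples = annotations),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$matrix), "genes x",
      ncol(x$matrix), "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  covs <- setdiff(names(x$samples), c("sample_id", "group"))
  if (length(covs)) cat("covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

#' Load an expression matrix and sample sheet from TSV files
#'
#' The matrix file is tab-separated with a first column named `gene` and one
#' column per sample; the sample sheet is tab-separated with mandatory
#' columns `sample_id` and `group`, extra columns being covariates.
#' Duplicate gene symbols are collapsed to their row-wise mean (reported via
#' a message).
#'
#' @param matrix_path path to the expression TSV.
#' @param annotation_path path to the sample-sheet TSV.
#' @return an [expression_study()] object.
#' @export
load_expression_table <- function(matrix_path, annotation_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if (names(raw)[1] != "gene")
    stop("first column of ", matrix_path, " must be named 'gene'")
  genes <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop("non-numeric cell in column '", names(vals)[j], "', row ",
           if (length(bad)) bad[1] else "?", " (gene ",
           if (length(bad)) genes[bad[1]] else "?", ")")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup), " duplicated gene symbol(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    m <- rowsum(m, group = genes) / as.vector(table(genes)[unique(genes)])
    m <- m[unique(genes), , drop = FALSE]
  }
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  expression_study(m, ann)
}

# one-hot design matrix for the requested covariates; categorical covariates
# are encoded against a lexicographically first reference level
build_design <- function(samples, test_group, covariates) {
  n <- nrow(samples)
  X <- cbind(`(Intercept)` = rep(1, n),
             group = as.numeric(samples$group == test_group))
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1]) {
        X <- cbind(X, as.numeric(v == l))
        colnames(X)[ncol(X)] <- paste0(cv, l)
      }
    }
  }
  as.matrix(X)
}

#' Per-gene differential expression profile by least squares
#'
#' Fits, for every gene, `expression ~ intercept + group + covariates` by
#' ordinary least squares on the samples belonging to the two contrast
#' groups. The group coefficient is the log-expression difference
#' (test minus reference); its t statistic is referred to the t distribution
#' with the residual degrees of freedom, and the two-sided p-value is
#' converted to a signed Z score `z = sign(t) * qnorm(1 - p/2)` capped at
#' `+/- 8.21`. Genes with zero residual variance get `z = 0` and are
#' flagged.
#'
#' @param study an [expression_study()].
#' @param contrast character vector of two group labels,
#'   `c(test, reference)`; genes higher in the test group get positive z.
#' @param covariates character vector naming sample-sheet columns to adjust
#'   for (default none).
#' @return an object of class `differential_profile`: a data frame with
#'   columns `gene`, `effect`, `t`, `p`, `z`, `flag` and attributes
#'   `contrast`, `species`, `n_test`, `n_ref`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- paste0("s", 1:6)
#' ann <- data.frame(sample_id = paste0("s", 1:6),
#'                   group = rep(c("ctrl", "treated"), each = 3))
#' differential_profile(expression_study(m, ann), c("treated", "ctrl"))
#' @export
differential_profile <- function(study, contrast, covariates = character()) {
  stopifnot(inherits(study, "expression_study"), length(contrast) == 2)
  samples <- study$samples
  keep <- samples$group %in% contrast
  if (!any(samples$group == contrast[1]) || !any(samples$group == contrast[2]))
    stop("contrast groups not found in study: ",
         paste(setdiff(contrast, samples$group), collapse = ", "))
  samples <- samples[keep, , drop = FALSE]
  Y <- t(study$matrix[, keep, drop = FALSE])  # samples x genes
  n_test <- sum(samples$group == contrast[1])
  n_ref <- sum(samples$group == contrast[2])
  if (n_test < 2 || n_ref < 2)
    stop("both contrast groups need >= 2 samples (have ",
         n_test, " and ", n_ref, ")")
  missing_cov <- setdiff(covariates, names(samples))
  if (length(missing_cov))
    stop("covariate(s) not in sample sheet: ",
         paste(missing_cov, collapse = ", "))

  X <- build_design(samples, contrast[1], covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- nrow(X) - ncol(X)
  if (df < 1)
    stop("residual degrees of freedom < 1 after covariates")

  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  rss <- colSums(res^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  v_group <- xtx_inv[2, 2]
  effect <- coefs["group", ]
  # zero residual variance relative to the scale of the data
  zero_var <- sigma2 <= .Machine$double.eps^0.75 * (1 + colMeans(Y^2))
  se <- sqrt(sigma2 * v_group)
  tstat <- ifelse(zero_var, NA_real_, effect / se)
  p <- ifelse(zero_var, NA_real_, 2 * stats::pt(-abs(tstat), df))
  z <- ifelse(zero_var, 0, signed_z(pmax(p, .Machine$double.xmin),
                                    sign(tstat)))
  out <- data.frame(gene = rownames(study$matrix), effect = effect,
                    t = tstat, p = p, z = z, flag = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            class = c("differential_profile", "data.frame"),
            contrast = contrast, covariates = covariates,
            species = attr(study, "species") %||% "unknown",
            n_test = n_test, n_ref = n_ref, df = df)
}

#' @export
print.differential_profile <- function(x, ...) {
  cat("differential_profile:", nrow(x), "genes; contrast",
      paste(attr(x, "contrast"), collapse = " vs "),
      sprintf("(n = %d vs %d)", attr(x, "n_test"), attr(x, "n_ref")), "\n")
  if (length(attr(x, "covariates")))
    cat("covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  ord <- order(-abs(x$z))
  print.data.frame(utils::head(x[ord, ], 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more genes)\n", sep = "")
  invisible(x)
}

#' Volcano plot of a differential profile
#'
#' @param x a [differential_profile()].
#' @param p_cut significance line (default 0.05).
#' @param ... passed to [graphics::plot()].
#' @export
plot.differential_profile <- function(x, p_cut = 0.05, ...) {
  ok <- !x$flag
  graphics::plot(x$effect[ok], -log10(x$p[ok]),
                 xlab = "log-expression difference",
                 ylab = expression(-log[10](p)),
                 pch = 20, col = ifelse(x$p[ok] < p_cut,
                                        ifelse(x$z[ok] > 0, "firebrick",
                                               "steelblue"), "grey60"),
                 ...)
  graphics::abline(h = -log10(p_cut), lty = 2, col = "grey40")
  invisible(x)
}

#' Harmonize gene symbols to a human-style uppercase namespace
#'
#' Rodent symbols (e.g. `Nr4a1`) are upper-cased to their human-style
#' equivalents (`NR4A1`); symbols that collide after upper-casing are
#' collapsed to the entry with maximum `|z|`, which preserves the extreme
#' responders that drive concordance statistics. Idempotent on
#' already-harmonized profiles.
#'
#' @param profile a [differential_profile()] (or any data frame with `gene`
#'   and `z` columns).
#' @param species one of `"rat"`, `"mouse"`, `"human"`; recorded in the
#'   output metadata.
#' @return the profile with upper-cased, unique gene symbols.
#' @export
harmonize_symbols <- function(profile, species = c("rat", "mouse", "human")) {
  species <- match.arg(species)
  stopifnot(is.data.frame(profile), all(c("gene", "z") %in% names(profile)))
  at <- attributes(profile)
  profile$gene <- toupper(profile$gene)
  if (anyDuplicated(profile$gene)) {
    dup <- unique(profile$gene[duplicated(profile$gene)])
    message("collapsing ", length(dup),
            " colliding symbol(s) to max |z| entry")
    ord <- order(profile$gene, -abs(profile$z))
    profile <- profile[ord, , drop = FALSE]
    profile <- profile[!duplicated(profile$gene), , drop = FALSE]
    rownames(profile) <- NULL
  }
  for (a in setdiff(names(at), c("names", "row.names", "class")))
    attr(profile, a) <- at[[a]]
  class(profile) <- at$class %||% class(profile)
  attr(profile, "species") <- "human"
  profile
}
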