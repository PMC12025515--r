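# Stouffer combination of per-study Z profiles into a composite disease
# meta-profile.

#' Combine differential Z profiles into a composite meta-profile
#'
#' For each gene g present in at least `min_studies` of the input profiles,
#' the composite score is Stouffer's combined Z,
#' `S_g = sum_i(z_gi) / sqrt(n_g)`, where the sum runs over the `n_g`
#' profiles that report gene g. Using the per-gene count (rather than the
#' global number of studies) keeps S approximately standard normal for
#' partially measured genes.
#'
#' @param profiles non-empty list of [differential_profile()] objects (or
#'   named z vectors), symbol-harmonized to a common namespace.
#' @param min_studies minimum number of contributing studies per retained
#'   gene (default 1 keeps the union of all genes).
#' @return an object of class `composite_profile`: data frame with columns
#'   `gene`, `S`, `n` and attribute `sources`.
#' @examples
#' p1 <- c(BDNF = 2, FOS = 1)
#' p2 <- c(BDNF = 2, NR4A1 = -1)
#' combine_profiles(list(a = p1, b = p2))
#' @export
combine_profiles <- function(profiles, min_studies = 1) {
  if (!is.list(profiles) || length(profiles) == 0)
    stop("`profiles` must be a non-empty list")
  zs <- lapply(profiles, as_z_profile)
  ids <- names(profiles) %||% paste0("profile", seq_along(profiles))
  if (is.null(names(profiles))) names(zs) <- ids
  all_genes <- sort(unique(unlist(lapply(zs, names))))
  sum_z <- numeric(length(all_genes))
  n <- integer(length(all_genes))
  names(sum_z) <- names(n) <- all_genes
  for (z in zs) {
    if (!all(is.finite(z))) stop("non-finite z values in input profile")
    idx <- match(names(z), all_genes)
    sum_z[idx] <- sum_z[idx] + z
    n[idx] <- n[idx] + 1L
  }
  keep <- n >= min_studies
  out <- data.frame(gene = all_genes[keep],
                    S = sum_z[keep] / sqrt(n[keep]),
                    n = n[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("composite_profile", "data.frame"),
            sources = ids)
}

#' @export
print.composite_profile <- function(x, ...) {
  cat("composite_profile:", nrow(x), "genes from",
      length(attr(x, "sources")), "studies\n")
  ord <- order(-abs(x$S))
  print.data.frame(utils::head(x[ord, ], 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more genes)\n", sep = "")
  invisible(x)
}
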