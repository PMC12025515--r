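# Connectivity scoring of a query signature against a compound-profile
# library, profile-profile Pearson correlation with Fisher-transform CIs,
# and top-gene sign-concordance (signature reversal) statistics.

#' Pearson correlation between two z profiles with a Fisher-transform CI
#'
#' Correlates two profiles over their shared genes (optionally restricted
#' to `gene_subset`). The 95% confidence interval comes from the Fisher
#' transform, `atanh(r) +/- 1.96/sqrt(n - 3)` back-transformed, and the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param a,b z profiles: named numeric vectors, [differential_profile()]
#'   or [combine_profiles()] objects.
#' @param gene_subset optional character vector restricting the gene
#'   universe.
#' @param conf confidence level (default 0.95).
#' @return an object of class `correlation_estimate`: list with elements
#'   `r`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @examples
#' a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
#' correlate_profiles(a, 2 * a)   # r = 1
#' @export
correlate_profiles <- function(a, b, gene_subset = NULL, conf = 0.95) {
  za <- as_z_profile(a)
  zb <- as_z_profile(b)
  shared <- intersect(names(za), names(zb))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  n <- length(shared)
  if (n < 4)
    stop("need >= 4 shared genes to correlate (have ", n, ")")
  x <- za[shared]; y <- zb[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance over shared genes; correlation undefined")
  r <- stats::cor(x, y)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  if (abs(r) >= 1 - .Machine$double.eps^0.5) {
    warning("|r| = 1: degenerate CI clamped to +/-1, p = 0")
    ci <- c(sign(r), sign(r))
    p <- 0
  } else {
    fz <- atanh(r)
    ci <- tanh(fz + c(-1, 1) * zcrit / sqrt(n - 3))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(r = r, ci_lo = ci[1], ci_hi = ci[2], p = p, n = n),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("r = %.3f [%.3f %.3f], p = %.3g (n = %d gene pairs)\n",
              x$r, x$ci_lo, x$ci_hi, x$p, x$n))
  invisible(x)
}

#' Score a query profile against a compound-profile library
#'
#' Each compound profile is correlated with the query over their shared
#' genes; the correlations are standardized across the library,
#' `Z_c = (r_c - mean(r)) / sd(r)` (population sd), and compounds are
#' ranked by descending Z (`rank_pos`) and ascending Z (`rank_neg`), ties
#' broken by compound name so the output is deterministic. A permutation
#' null (shuffling the query's gene labels) is available as an alternative
#' per-compound Z.
#'
#' @param query a z profile (named numeric vector or profile object).
#' @param library a `profile_library` (named list of named z vectors), e.g.
#'   from [read_library()] or [simulate_drug_library()].
#' @param min_overlap minimum number of genes each compound must share with
#'   the query (default 50).
#' @param method `"standardize"` (default, deterministic) or
#'   `"permutation"`: Z from the mean/sd of each compound's correlation
#'   under `n_perm` random relabelings of the query genes.
#' @param n_perm permutations when `method = "permutation"`.
#' @return an object of class `connectivity_table`: data frame with columns
#'   `compound`, `r`, `n_overlap`, `Z`, `rank_pos`, `rank_neg`, sorted by
#'   `rank_pos`.
#' @export
score_library <- function(query, library, min_overlap = 50,
                          method = c("standardize", "permutation"),
                          n_perm = 1000) {
  method <- match.arg(method)
  zq <- as_z_profile(query)
  stopifnot(is.list(library), !is.null(names(library)))
  if (anyDuplicated(names(library)))
    stop("compound names must be unique")
  M <- length(library)
  if (M < 2) stop("library must contain >= 2 compounds")

  r <- numeric(M)
  n_overlap <- integer(M)
  shared_list <- vector("list", M)
  for (i in seq_len(M)) {
    zc <- library[[i]]
    shared <- intersect(names(zq), names(zc))
    if (length(shared) < min_overlap)
      stop("compound '", names(library)[i], "' shares only ",
           length(shared), " genes with the query (min_overlap = ",
           min_overlap, ")")
    shared_list[[i]] <- shared
    n_overlap[i] <- length(shared)
    r[i] <- stats::cor(zq[shared], zc[shared])
  }

  if (method == "standardize") {
    sd_pop <- sqrt(mean((r - mean(r))^2))
    if (sd_pop == 0)
      stop("degenerate library: all correlations identical (sd = 0)")
    Z <- (r - mean(r)) / sd_pop
  } else {
    Z <- numeric(M)
    for (i in seq_len(M)) {
      shared <- shared_list[[i]]
      zc <- library[[i]][shared]
      x <- zq[shared]
      null_r <- replicate(n_perm, stats::cor(sample(x), zc))
      sdn <- stats::sd(null_r)
      if (sdn == 0) stop("degenerate permutation null for compound '",
                         names(library)[i], "'")
      Z[i] <- (r[i] - mean(null_r)) / sdn
    }
  }

  nm <- names(library)
  ord_pos <- order(-Z, nm)
  rank_pos <- integer(M); rank_pos[ord_pos] <- seq_len(M)
  ord_neg <- order(Z, nm)
  rank_neg <- integer(M); rank_neg[ord_neg] <- seq_len(M)

  out <- data.frame(compound = nm, r = r, n_overlap = n_overlap, Z = Z,
                    rank_pos = rank_pos, rank_neg = rank_neg,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("connectivity_table", "data.frame"),
            method = method)
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat("connectivity_table:", nrow(x), "compounds (method: ",
      attr(x, "method"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more compounds)\n", sep = "")
  invisible(x)
}

#' Top-gene sign concordance between two profiles (signature reversal)
#'
#' Takes the `top_k` genes of profile `a` by absolute z among those present
#' in `b`, counts how many have the opposite sign in `b`, and tests the
#' count against a fair-coin null with an exact two-sided binomial p
#' (doubling the smaller tail, capped at 1). A large `n_opposite` indicates
#' that `b` reverses `a`'s strongest signature genes.
#'
#' @param a,b z profiles.
#' @param top_k number of top-|z| genes of `a` to examine.
#' @return an object of class `concordance_result`: list with
#'   `n_opposite`, `n_total`, `p`, and the examined `genes`.
#' @export
sign_concordance <- function(a, b, top_k) {
  za <- as_z_profile(a)
  zb <- as_z_profile(b)
  shared <- intersect(names(za), names(zb))
  if (length(shared) < top_k)
    stop("only ", length(shared), " genes of the query are present in the ",
         "comparison profile; top_k = ", top_k, " requested")
  za <- za[shared]
  top <- names(za)[order(-abs(za))][seq_len(top_k)]
  opposite <- sign(za[top]) * sign(zb[top]) < 0
  k <- sum(opposite)
  structure(list(n_opposite = k, n_total = top_k,
                 p = binom_two_sided(k, top_k), genes = top),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("sign concordance: %d of %d top genes opposite-signed, exact binomial p = %.3g\n",
              x$n_opposite, x$n_total, x$p))
  invisible(x)
}
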