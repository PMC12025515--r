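# shared numerical helpers

# Z at p ~ 2.2e-16; caps the normal quantile for underflowing p-values
Z_CAP <- 8.21

#' Convert a two-sided p-value and a sign into a signed Z score
#'
#' `z = sign * qnorm(1 - p/2)`, capped at `+/- cap` so that underflowing
#' p-values do not produce infinite quantiles.
#'
#' @param p two-sided p-values in (0, 1].
#' @param sign direction of the effect (+1/-1; 0 gives z = 0).
#' @param cap absolute bound on z (default 8.21, the Z at p of about
#'   2.2e-16).
#' @return signed Z scores with `|z| <= cap`.
#' @examples
#' signed_z(0.05, 1)
#' signed_z(1e-300, -1)   # capped at -8.21
#' @export
signed_z <- function(p, sign, cap = Z_CAP) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  z <- qnorm(1 - p / 2)
  pmin(z, cap) * base::sign(sign)
}

# exact two-sided binomial p at success probability 1/2:
# double the smaller tail, capped at 1
binom_two_sided <- function(k, n) {
  stopifnot(k >= 0, k <= n)
  lo <- pbinom(k, n, 0.5)                 # P(X <= k)
  hi <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  min(1, 2 * min(lo, hi))
}

# named-numeric z-vector view of a profile object
as_z_profile <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    if (anyDuplicated(names(x)) > 0)
      stop("duplicate gene names in z profile")
    return(x)
  }
  if (inherits(x, "differential_profile")) {
    z <- x$z
    names(z) <- x$gene
    return(z)
  }
  if (inherits(x, "composite_profile")) {
    z <- x$S
    names(z) <- x$gene
    return(z)
  }
  if (is.data.frame(x) && all(c("gene", "z") %in% names(x))) {
    z <- x$z
    names(z) <- x$gene
    return(z)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a z profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
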