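#' Top acute-lithium-response genes with depression meta-profile scores
#'
#' The thirty most lithium-regulated genes (signed Z scores from acute
#' lithium treatment of cortical neurons, `alp_z`) together with their Z
#' scores in a composite major-depression brain meta-profile (`mdd_z`).
#' A worked example for [sign_concordance()] and [correlate_profiles()]:
#' most of the strongest lithium-responsive genes move in the opposite
#' direction in the disease profile.
#'
#' @return data frame with columns `gene`, `alp_z`, `mdd_z`.
#' @examples
#' d <- alp_mdd_example()
#' sign_concordance(stats::setNames(d$alp_z, d$gene),
#'                  stats::setNames(d$mdd_z, d$gene), top_k = 30)
#' @export
alp_mdd_example <- function() {
  utils::read.delim(system.file("extdata", "alp_mdd_top30.tsv",
                                package = "sigrev"),
                    stringsAsFactors = FALSE)
}
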