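#' passageStability: passage-to-passage genomic stability from variant callsets
#'
#' See the package DESCRIPTION and the methods vignette
#' (`vignette("passage-stability")`) for an overview of the pipeline:
#' callset I/O, site filtering, passage analysis, genome metrics and the
#' seeded simulator.
#'
#' @import data.table
#' @importFrom stats median pnorm qnorm runif rbinom rpois rnorm setNames
#' @importFrom utils combn read.table tail
#' @keywords internal
"_PACKAGE"

# Truncated normal draws via inverse-CDF; exact and vectorised, no
# rejection loop.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
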