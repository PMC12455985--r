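#' Heatmap of recoded genotypes across samples
#'
#' Plots the sites-by-samples matrix of recoded genotypes
#' ([recode_matrix()]) as a tile heatmap, sites on the y axis in callset
#' order and one column per sample — the visual summary of how passage
#' replicates drift apart. Restricting to the variable sites
#' (`variable_only = TRUE`) is usually what you want: fixed sites are a
#' constant band of code 1.
#'
#' @param cs a [callset()].
#' @param variable_only plot only the variable sites of
#'   [classify_sites()].
#' @return a `ggplot` object. Requires the ggplot2 package.
#' @export
plot_recode_matrix <- function(cs, variable_only = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_recode_matrix requires the ggplot2 package")
  }
  codes <- suppressWarnings(recode_matrix(cs))
  if (variable_only) {
    codes <- codes[classify_sites(cs)$variable_sites, , drop = FALSE]
  }
  df <- data.frame(
    site = rep(seq_len(nrow(codes)), ncol(codes)),
    sample = factor(rep(colnames(codes), each = nrow(codes)),
                    levels = colnames(codes)),
    code = factor(as.vector(codes), levels = 0:6)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$site,
                                   fill = .data$code)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(name = "genotype code", na.value = "grey85",
                                  drop = FALSE) +
    ggplot2::labs(x = NULL, y = "site (callset order)") +
    ggplot2::theme_minimal()
}
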