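# Build a small callset from genotype strings, e.g.
#   toy_callset(rbind(c("0/1", "0/1"), c("1/1", "./.")))
# gt: sites x samples character matrix ("a/b", "a|b", "./.", ".").
# info: named list of per-site numeric vectors (QD, FS, ..., DP); unlisted
# keys stay absent (NA). Optional dp/gq matrices parallel to gt.
toy_callset <- function(gt, samples = paste0("S", seq_len(ncol(gt))),
                        dp = NULL, gq = NULL,
                        chrom = "1", pos = seq_len(nrow(gt)) * 100L,
                        ref = NULL, alts = NULL, qual = 100,
                        info = list(), filter = NULL) {
  n <- nrow(gt)
  m <- ncol(gt)
  parse1 <- function(g) {
    ph <- grepl("|", g, fixed = TRUE)
    p <- strsplit(g, "[/|]")[[1]]
    a <- suppressWarnings(as.integer(p[1]))
    b <- if (length(p) > 1) suppressWarnings(as.integer(p[2])) else a
    c(a, b, as.integer(ph))
  }
  parsed <- vapply(as.vector(gt), parse1, integer(3))
  dm <- list(NULL, samples)
  geno <- list(
    a = matrix(parsed[1, ], n, m, dimnames = dm),
    b = matrix(parsed[2, ], n, m, dimnames = dm),
    phased = matrix(parsed[3, ] == 1L, n, m, dimnames = dm),
    dp = if (is.null(dp)) matrix(30L, n, m, dimnames = dm) else
      matrix(as.integer(dp), n, m, dimnames = dm),
    gq = if (is.null(gq)) matrix(99L, n, m, dimnames = dm) else
      matrix(as.integer(gq), n, m, dimnames = dm)
  )
  nalt <- pmax(apply(cbind(rep(1L, n), geno$a, geno$b), 1, max, na.rm = TRUE), 1L)
  bases <- c("A", "C", "G", "T")
  sites <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                      ref = if (is.null(ref)) rep("A", n) else rep_len(ref, n),
                      stringsAsFactors = FALSE)
  sites$alts <- if (is.null(alts)) lapply(nalt, function(k) bases[1 + seq_len(k)]) else alts
  sites$qual <- rep_len(as.numeric(qual), n)
  for (key in c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum", "DP")) {
    sites[[key]] <- if (is.null(info[[key]])) rep(NA_real_, n) else
      rep_len(as.numeric(info[[key]]), n)
  }
  sites$filter <- if (is.null(filter)) rep(list(NULL), n) else filter
  callset(samples, sites, geno)
}

# Linear truth positions of simulated callset sites (wrapper kept for
# readability in tests).
sim_global_pos <- function(cs, cfg) global_positions(cs, cfg)
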