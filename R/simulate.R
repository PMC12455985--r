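#' Simulator configuration
#'
#' Parameters of the passage-callset simulator: a diploid founder individual
#' with heterozygous sites scattered at `het_rate` per bp, a set of
#' passage samples (each passage level with independent replicate lineages
#' splitting from passage 0), novel single-nucleotide mutations accumulating
#' at `mu` per bp per passage, Poisson read depth around `depth_lambda`,
#' genotype quality saturating at `gq_max`, a small rate of artifact calls
#' with depressed depth and quality, and missing genotypes at
#' `missing_rate`. The defaults emulate the study design this package was
#' built around: heterozygosity 0.2\% (2 het sites / kb), median depth
#' ~27x, GQ ~99, one primary-tissue sample (passage 0) plus an optional
#' HiFi-like reference sample, 3 replicates of passage 5 and 4 replicates
#' of passage 10. The default genome length is 1 Mb — a scaled-down genome
#' that keeps every statistical feature of the design while remaining fast
#' to simulate.
#'
#' @param genome_length genome size in bp (>= 1).
#' @param chrom_weights relative chromosome sizes (mix of a few large and
#'   several small chromosomes, mimicking a macro/micro karyotype);
#'   normalised internally.
#' @param het_rate founder per-bp heterozygosity fraction.
#' @param passages `data.frame` with columns `label`, `passage`
#'   (passage number) and `n_replicates`.
#' @param include_hifi add a HiFi-like extra reference sample (a second
#'   passage-0 lineage, as in the study's 9-sample table).
#' @param mu novel mutations per bp per passage.
#' @param depth_lambda mean per-sample per-site read depth (Poisson).
#' @param gq_max genotype-quality saturation value.
#' @param artifact_rate fraction of retained sites per sample receiving a
#'   spurious low-quality call (placed at otherwise hom-ref positions).
#' @param artifact_depth_shift depth offset added at artifact calls
#'   (negative; result floored at 1).
#' @param missing_rate per-call probability of a missing genotype.
#' @param info_dists named list of `c(mean, sd, lo, hi)` truncated-normal
#'   parameters for the site annotations QD, FS, MQ, SOR, MQRankSum,
#'   ReadPosRankSum and QUAL. The defaults are "passing" distributions:
#'   they exist to exercise the filters, not to model a caller faithfully,
#'   and default hard filters retain essentially all simulated sites.
#' @param seed integer seed; fixes the full output (truth and callset)
#'   exactly.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       chrom_weights = c(0.35, 0.25, 0.12, 0.10, 0.10, 0.08),
                       het_rate = 0.002,
                       passages = data.frame(label = c("P0", "P5", "P10"),
                                             passage = c(0, 5, 10),
                                             n_replicates = c(1, 3, 4)),
                       include_hifi = TRUE,
                       mu = 1e-6,
                       depth_lambda = 27,
                       gq_max = 99,
                       artifact_rate = 0.001,
                       artifact_depth_shift = -10,
                       missing_rate = 0.002,
                       info_dists = default_info_dists(),
                       seed = 1) {
  stopifnot(genome_length >= 1, het_rate >= 0, het_rate <= 1,
            mu >= 0, mu <= 1, artifact_rate >= 0, artifact_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, depth_lambda > 0,
            gq_max >= 0, gq_max <= 99, all(chrom_weights > 0),
            all(c("label", "passage", "n_replicates") %in% names(passages)))
  cfg <- list(genome_length = as.numeric(genome_length),
              chrom_weights = chrom_weights / sum(chrom_weights),
              het_rate = het_rate, passages = passages,
              include_hifi = include_hifi, mu = mu,
              depth_lambda = depth_lambda, gq_max = as.integer(gq_max),
              artifact_rate = artifact_rate,
              artifact_depth_shift = artifact_depth_shift,
              missing_rate = missing_rate, info_dists = info_dists,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' @describeIn sim_config the packaged study-design default: 0.2\%
#'   heterozygosity, depth 27x, GQ cap 99, passage 0 + 3 replicates of
#'   passage 5 + 4 replicates of passage 10, plus a HiFi-like reference
#'   sample when `include_hifi = TRUE`.
#' @param ... overrides passed on to `sim_config()`.
#' @export
scenario_study <- function(...) sim_config(...)

#' @rdname sim_config
#' @export
default_info_dists <- function() {
  list(QD = c(mean = 25, sd = 6, lo = 5, hi = 40),
       FS = c(mean = 2, sd = 2, lo = 0, hi = 30),
       MQ = c(mean = 60, sd = 2, lo = 45, hi = 70),
       SOR = c(mean = 1, sd = 0.4, lo = 0.1, hi = 2.5),
       MQRankSum = c(mean = 0, sd = 1, lo = -5, hi = 5),
       ReadPosRankSum = c(mean = 0, sd = 1, lo = -4, hi = 4),
       QUAL = c(mean = 500, sd = 150, lo = 50, hi = 2000))
}

#' Sample identifiers of a simulator configuration
#'
#' Expands the passage design into sample names: `HiFi` (when included),
#' then one name per replicate — the passage label alone for a single
#' replicate (`P0`), `label.i` otherwise (`P5.1` ... `P10.4`).
#'
#' @param cfg a [sim_config()].
#' @return `data.frame` with columns `sample` and `passage`.
#' @export
sim_samples <- function(cfg) {
  rows <- lapply(seq_len(nrow(cfg$passages)), function(i) {
    p <- cfg$passages[i, ]
    nm <- if (p$n_replicates == 1) p$label else paste0(p$label, ".", seq_len(p$n_replicates))
    data.frame(sample = nm, passage = p$passage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (isTRUE(cfg$include_hifi)) {
    out <- rbind(data.frame(sample = "HiFi", passage = 0, stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' Simulate the ground truth of a passage experiment
#'
#' Draws the founder's heterozygous sites (Bernoulli(`het_rate`) per bp,
#' genotype `0/1`), then lets every replicate lineage independently
#' accumulate `Poisson(mu * L * passage)` novel mutations at uniform
#' positions. A mutation at a hom-ref position creates a heterozygous call
#' with a new allele; a mutation at a founder heterozygous site converts it,
#' with equal probability among the legal moves, to `0/0`, `1/1`, or a
#' heterozygote involving a new allele (`0/x`, `1/x`). Novel allele indices
#' are assigned per site in order of appearance (capped at index 3, so the
#' recode domain and its sentinel overflow path are both exercised).
#' Artifact positions for each sample are drawn at positions hom-ref in all
#' samples — disjoint from the founder's het sites and from every sample's
#' mutations — with count Binomial(number of retained sites,
#' `artifact_rate`); each gets a spurious heterozygous genotype.
#'
#' Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_truth`: list with `het_pos` (founder
#'   heterozygous positions, genotype `0/1`), `mutations` (named list per
#'   sample of `data.frame(pos, a, b)`), `artifacts` (named list per sample
#'   of `data.frame(pos, a, b)`), `samples`, and the `cfg` echo.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  smp <- sim_samples(cfg)

  n_het <- stats::rbinom(1, L, cfg$het_rate)
  het_pos <- sort(sample.int(L, n_het))

  # allele registry: number of distinct non-ref alleles seen per position
  n_alleles <- new.env(hash = TRUE, parent = emptyenv())
  for (p in het_pos) assign(as.character(p), 1L, envir = n_alleles)
  novel_allele <- function(p) {
    key <- as.character(p)
    k <- if (exists(key, envir = n_alleles)) get(key, envir = n_alleles) else 0L
    assign(key, k + 1L, envir = n_alleles)
    min(k + 1L, 3L)  # cap: at most alt index 3
  }

  is_het <- logical(L)
  is_het[het_pos] <- TRUE

  mutations <- lapply(seq_len(nrow(smp)), function(i) {
    n_mut <- stats::rpois(1, cfg$mu * L * smp$passage[i])
    if (n_mut == 0) return(data.frame(pos = integer(0), a = integer(0), b = integer(0)))
    pos <- sort(sample.int(L, n_mut))
    a <- integer(n_mut); b <- integer(n_mut)
    for (j in seq_len(n_mut)) {
      if (is_het[pos[j]]) {
        move <- sample.int(4, 1)  # 0/0, 1/1, 0/new, 1/new
        g <- switch(move,
                    c(0L, 0L), c(1L, 1L),
                    c(0L, novel_allele(pos[j])),
                    c(1L, novel_allele(pos[j])))
      } else {
        g <- c(0L, novel_allele(pos[j]))
      }
      a[j] <- g[1]; b[j] <- g[2]
    }
    data.frame(pos = pos, a = a, b = b)
  })
  names(mutations) <- smp$sample

  mut_pos_all <- unique(unlist(lapply(mutations, `[[`, "pos")))
  n_retained <- length(unique(c(het_pos, mut_pos_all)))
  occupied <- is_het
  occupied[mut_pos_all] <- TRUE

  artifacts <- lapply(seq_len(nrow(smp)), function(i) {
    n_art <- stats::rbinom(1, n_retained, cfg$artifact_rate)
    if (n_art == 0) return(data.frame(pos = integer(0), a = integer(0), b = integer(0)))
    pos <- integer(0)
    while (length(pos) < n_art) {  # rejection: hom-ref-everywhere positions only
      cand <- sample.int(L, n_art - length(pos))
      cand <- cand[!occupied[cand] & !cand %in% pos]
      pos <- c(pos, cand)
    }
    pos <- sort(pos)
    ab <- vapply(pos, novel_allele, 0L)
    data.frame(pos = pos, a = rep(0L, n_art), b = ab)
  })
  names(artifacts) <- smp$sample

  structure(list(het_pos = het_pos, mutations = mutations,
                 artifacts = artifacts, samples = smp, cfg = cfg),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", length(x$het_pos), " founder het site(s), ",
      nrow(x$samples), " sample(s)\n", sep = "")
  cat("  mutations per sample: ",
      paste(sprintf("%s=%d", x$samples$sample, vapply(x$mutations, nrow, 0L)),
            collapse = " "), "\n", sep = "")
  cat("  artifact calls per sample: ",
      paste(vapply(x$artifacts, nrow, 0L), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Truth class of a sample's call at a position
#'
#' @param truth a [simulate_truth()] result.
#' @param sample sample identifier.
#' @param pos genome position(s).
#' @return character vector in `{"artifact", "mutation", "het", "hom_ref"}`.
#' @export
truth_class <- function(truth, sample, pos) {
  out <- rep("hom_ref", length(pos))
  out[pos %in% truth$het_pos] <- "het"
  out[pos %in% truth$mutations[[sample]]$pos] <- "mutation"
  out[pos %in% truth$artifacts[[sample]]$pos] <- "artifact"
  out
}

#' Simulate a multi-sample callset from a truth table
#'
#' Emits one variant record per genome position that is non-hom-ref in at
#' least one sample: the founder's heterozygous sites (genotype `0/1`
#' unless a lineage mutated them away), each sample's novel mutations, and
#' each sample's artifact calls. Per-call depth is Poisson around
#' `depth_lambda`; genotype quality saturates at `gq_max`; artifact calls
#' get depth shifted by `artifact_depth_shift` (floored at 1) and reduced
#' quality; genotypes go missing independently at `missing_rate` (the call's
#' GQ is dropped with it). Site-level annotations are drawn from the
#' configured truncated-normal "passing" distributions and INFO/DP is the
#' sum of the per-sample depths. Deterministic under `cfg$seed` (the
#' callset stream is seeded from `cfg$seed` with a fixed offset so truth
#' and callset draws do not interleave).
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()] the truth was built from.
#' @param path optional output VCF path, written with [write_callset()].
#' @return a [callset()].
#' @export
simulate_callset <- function(truth, cfg = truth$cfg, path = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  set.seed((cfg$seed + 500009L) %% .Machine$integer.max)
  smp <- truth$samples
  m <- nrow(smp)
  pos_all <- sort(unique(c(truth$het_pos,
                           unlist(lapply(truth$mutations, `[[`, "pos")),
                           unlist(lapply(truth$artifacts, `[[`, "pos")))))
  n <- length(pos_all)
  dm <- list(NULL, smp$sample)
  a <- matrix(0L, n, m, dimnames = dm)
  b <- matrix(0L, n, m, dimnames = dm)
  ishet <- pos_all %in% truth$het_pos
  b[ishet, ] <- 1L
  art_flag <- matrix(FALSE, n, m, dimnames = dm)
  for (j in seq_len(m)) {
    sm <- smp$sample[j]
    mu <- truth$mutations[[sm]]
    if (nrow(mu)) {
      i <- match(mu$pos, pos_all)
      a[i, j] <- mu$a; b[i, j] <- mu$b
    }
    ar <- truth$artifacts[[sm]]
    if (nrow(ar)) {
      i <- match(ar$pos, pos_all)
      a[i, j] <- ar$a; b[i, j] <- ar$b
      art_flag[i, j] <- TRUE
    }
  }
  keep <- rowSums(a > 0 | b > 0) > 0  # drop rows hom-ref in every sample
  pos_all <- pos_all[keep]
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  art_flag <- art_flag[keep, , drop = FALSE]
  n <- length(pos_all)
  if (n == 0) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), stringsAsFactors = FALSE)
    sites$alts <- list()
    sites$qual <- numeric(0)
    for (key in INFO_KEYS) sites[[key]] <- numeric(0)
    sites$filter <- list()
    cs <- callset(smp$sample, sites, empty_geno(0, smp$sample))
    if (!is.null(path)) write_callset(cs, path)
    return(cs)
  }

  # depth and quality
  dp <- matrix(stats::rpois(n * m, cfg$depth_lambda), n, m, dimnames = dm)
  gq <- matrix(pmin(cfg$gq_max, pmax(0L, as.integer(round(stats::rnorm(n * m, 130, 30))))),
               n, m, dimnames = dm)
  if (any(art_flag)) {
    k <- sum(art_flag)
    dp[art_flag] <- pmax(1L, as.integer(stats::rpois(k, cfg$depth_lambda) +
                                          cfg$artifact_depth_shift))
    gq[art_flag] <- pmin(cfg$gq_max,
                         pmax(0L, as.integer(round(rtrunc_norm(k, 25, 10, 1, 60)))))
  }
  storage.mode(dp) <- "integer"

  # alternate-allele count per site, from the true (pre-missingness) calls
  nalt <- pmax(apply(cbind(a, b), 1, max), 1L)

  # missing calls
  miss <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
  a[miss] <- NA_integer_; b[miss] <- NA_integer_; gq[miss] <- NA_integer_

  # site annotations
  dists <- cfg$info_dists
  dr <- function(key) {
    d <- dists[[key]]
    rtrunc_norm(n, d[["mean"]], d[["sd"]], d[["lo"]], d[["hi"]])
  }
  # map linear positions to (chrom, local pos)
  cl <- unname(sim_chrom_lengths(cfg))
  ends <- cumsum(cl)
  ci <- findInterval(pos_all - 1, c(0, ends[-length(ends)]))
  local <- pos_all - c(0, ends[-length(ends)])[ci]

  bases <- c("A", "C", "G", "T")
  refs <- sample(bases, n, replace = TRUE)
  alts <- lapply(seq_len(n), function(i) sample(setdiff(bases, refs[i]), nalt[i]))

  sites <- data.frame(chrom = paste0("chr", ci), pos = as.integer(local),
                      ref = refs, stringsAsFactors = FALSE)
  sites$alts <- alts
  sites$qual <- round(dr("QUAL"), 2)
  sites$QD <- round(dr("QD"), 2)
  sites$FS <- round(dr("FS"), 3)
  sites$MQ <- round(dr("MQ"), 2)
  sites$SOR <- round(dr("SOR"), 3)
  sites$MQRankSum <- round(dr("MQRankSum"), 3)
  sites$ReadPosRankSum <- round(dr("ReadPosRankSum"), 3)
  sites$DP <- as.numeric(rowSums(dp))
  sites$filter <- rep(list(NULL), n)

  cs <- callset(smp$sample, sites,
                list(a = a, b = b,
                     phased = matrix(FALSE, n, m, dimnames = dm),
                     dp = dp, gq = gq),
                provenance = sprintf(
                  "simulate_callset: seed=%d genome_length=%g het_rate=%g mu=%g depth_lambda=%g artifact_rate=%g missing_rate=%g",
                  cfg$seed, cfg$genome_length, cfg$het_rate, cfg$mu,
                  cfg$depth_lambda, cfg$artifact_rate, cfg$missing_rate))
  if (!is.null(path)) write_callset(cs, path)
  cs
}

#' Chromosome layout of a simulated genome
#'
#' `sim_chrom_lengths()` gives the chromosome lengths a [sim_config()]
#' implies (weights scaled to the genome length, named `chr1`, `chr2`, ...);
#' `global_positions()` maps a simulated callset's (chrom, pos) coordinates
#' back to the linear 1..L positions used by the truth tables of
#' [simulate_truth()].
#'
#' @param cfg a [sim_config()].
#' @return named numeric vector of lengths in bp.
#' @export
sim_chrom_lengths <- function(cfg) {
  cl <- round(cfg$chrom_weights * cfg$genome_length)
  cl[length(cl)] <- cfg$genome_length - sum(cl[-length(cl)])
  stats::setNames(cl, paste0("chr", seq_along(cl)))
}

#' @rdname sim_chrom_lengths
#' @param cs a [callset()] produced by [simulate_callset()] under `cfg`.
#' @return `global_positions()`: numeric vector of linear genome positions,
#'   one per site.
#' @export
global_positions <- function(cs, cfg) {
  cl <- sim_chrom_lengths(cfg)
  offs <- stats::setNames(c(0, cumsum(cl)[-length(cl)]), names(cl))
  unname(cs$sites$pos + offs[cs$sites$chrom])
}

#' Simulate a toy genome annotation with contrasting chromosome classes
#'
#' Generates chromosome lengths (two macrochromosomes above the 30 Mb
#' cutoff, four microchromosomes below it) and a gene/mRNA/exon GFF3
#' annotation in which microchromosomes carry `density_ratio` times the
#' gene density of macrochromosomes and micro introns are `intron_scale`
#' times the macro mean intron length. Gene bodies are placed
#' non-overlapping; exon counts are Poisson, exon and intron lengths are
#' log-normal with the class-specific intron mean. Realised (not just
#' requested) ratios are returned so recovery can be checked exactly.
#'
#' @param cfg a [sim_config()] (only `seed` is used).
#' @param density_ratio target micro/macro genes-per-Mb ratio (> 0).
#' @param intron_scale target micro/macro mean-intron-length ratio (> 0).
#' @param n_genes total genes to place.
#' @param gff_path optional path to write the annotation as GFF3
#'   (via `rtracklayer::export`).
#' @param lengths_path optional path to write a two-column name/length table.
#' @return list with `lengths` (named bp vector), `genes` (a
#'   `GenomicRanges::GRanges` of gene/mRNA/exon features) and `truth`
#'   (realised `density_ratio` and `intron_ratio`, and per-class gene
#'   counts).
#' @export
simulate_annotation <- function(cfg, density_ratio = 2, intron_scale = 0.5,
                                n_genes = 2000, gff_path = NULL,
                                lengths_path = NULL) {
  stopifnot(density_ratio > 0, intron_scale > 0, n_genes >= 0)
  set.seed((cfg$seed + 901001L) %% .Machine$integer.max)
  lens <- c(chrM1 = 40e6, chrM2 = 35e6,
            chrm1 = 6e6, chrm2 = 5e6, chrm3 = 5e6, chrm4 = 4e6)
  klass <- ifelse(lens >= 30e6, "macro", "micro")
  l_mac <- sum(lens[klass == "macro"]) / 1e6
  l_mic <- sum(lens[klass == "micro"]) / 1e6
  d_mac <- n_genes / (l_mac + density_ratio * l_mic)
  n_per_class <- c(macro = round(d_mac * l_mac),
                   micro = round(d_mac * density_ratio * l_mic))

  sdlog <- 0.5
  meanlog <- c(macro = log(1500) - sdlog^2 / 2,
               micro = log(1500 * intron_scale) - sdlog^2 / 2)

  feats <- list()
  gid <- 0
  intron_sum <- c(macro = 0, micro = 0)
  intron_n <- c(macro = 0, micro = 0)
  for (chr in names(lens)) {
    kl <- klass[[chr]]
    ngc <- round(n_per_class[[kl]] * lens[[chr]] / (if (kl == "macro") l_mac else l_mic) / 1e6)
    if (ngc == 0) next
    nex <- 1 + stats::rpois(ngc, 4)
    exlens <- lapply(nex, function(k) pmax(50, round(stats::rlnorm(k, log(200), 0.5))))
    inlens <- lapply(nex, function(k) {
      if (k < 2) return(numeric(0))
      pmax(20, round(stats::rlnorm(k - 1, meanlog[[kl]], sdlog)))
    })
    spans <- vapply(seq_len(ngc), function(i) sum(exlens[[i]]) + sum(inlens[[i]]), 0)
    slack <- lens[[chr]] - sum(spans)
    if (slack < ngc + 1) stop("chromosome ", chr, " too small for requested gene load")
    gaps <- as.vector(stats::rmultinom(1, slack - (ngc + 1), rep(1, ngc + 1))) + 1
    starts <- cumsum(gaps[seq_len(ngc)]) + cumsum(c(0, spans[-ngc])) + 1
    for (i in seq_len(ngc)) {
      gid <- gid + 1
      g <- sprintf("gene%05d", gid)
      tx <- paste0(g, ".t1")
      ex_st <- starts[i] + cumsum(c(0, head_pairsum(exlens[[i]], inlens[[i]])))
      ex_en <- ex_st + exlens[[i]] - 1
      feats[[length(feats) + 1]] <- data.frame(
        chrom = chr,
        start = c(starts[i], starts[i], ex_st),
        end = c(starts[i] + spans[i] - 1, starts[i] + spans[i] - 1, ex_en),
        type = c("gene", "mRNA", rep("exon", nex[i])),
        ID = c(g, tx, paste0(tx, ".e", seq_len(nex[i]))),
        Parent = c(NA, g, rep(tx, nex[i])),
        stringsAsFactors = FALSE
      )
      intron_sum[[kl]] <- intron_sum[[kl]] + sum(inlens[[i]])
      intron_n[[kl]] <- intron_n[[kl]] + length(inlens[[i]])
    }
  }
  df <- if (length(feats)) do.call(rbind, feats) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               type = character(0), ID = character(0), Parent = character(0))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = rep("+", nrow(df))
  )
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p) {
    if (is.na(p)) character(0) else p
  }))

  realized_counts <- c(macro = sum(df$type == "gene" & df$chrom %in% names(lens)[klass == "macro"]),
                       micro = sum(df$type == "gene" & df$chrom %in% names(lens)[klass == "micro"]))
  truth <- list(
    density_ratio = (realized_counts[["micro"]] / l_mic) / (realized_counts[["macro"]] / l_mac),
    intron_ratio = (intron_sum[["micro"]] / intron_n[["micro"]]) /
      (intron_sum[["macro"]] / intron_n[["macro"]]),
    gene_counts = realized_counts
  )
  if (!is.null(gff_path)) rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(lengths_path)) {
    utils::write.table(data.frame(names(lens), as.numeric(lens)), lengths_path,
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(lengths = lens, genes = gr, truth = truth)
}

# Interleave exon and intron lengths into per-exon offsets: for exons
# e1..ek and introns i1..i(k-1), returns e1+i1, e2+i2, ... as the step from
# one exon start to the next.
head_pairsum <- function(exlens, inlens) {
  k <- length(exlens)
  if (k < 2) return(numeric(0))
  exlens[-k] + inlens
}
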