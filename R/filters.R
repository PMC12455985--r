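#  Labels used in the FILTER column, one per hard-filter condition.
HARD_FILTER_LABELS <- c("QD", "FS", "MQ", "SOR", "MQRS", "RPRS", "QUAL")

#' Hard-filter thresholds for site-level annotations
#'
#' Container for the seven GATK-style hard-filter thresholds applied to
#' jointly genotyped SNP sites. The defaults are the standard hard-filter
#' recommendations used by the pipeline this package models: a site fails
#' when `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`, `SOR > 3.0`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8.0` or `QUAL < 30.0`.
#'
#' @param qd_min minimum variant confidence by depth (QD).
#' @param fs_max maximum Phred-scaled Fisher strand bias (FS).
#' @param mq_min minimum RMS mapping quality (MQ).
#' @param sor_max maximum symmetric strand odds ratio (SOR).
#' @param mqrs_min minimum mapping-quality rank-sum (MQRankSum).
#' @param rprs_min minimum read-position rank-sum (ReadPosRankSum).
#' @param qual_min minimum site QUAL.
#' @return an object of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                                   sor_max = 3.0, mqrs_min = -12.5,
                                   rprs_min = -8.0, qual_min = 30.0) {
  t <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min, sor_max = sor_max,
            mqrs_min = mqrs_min, rprs_min = rprs_min, qual_min = qual_min)
  stopifnot(all(vapply(t, is.finite, TRUE)))
  structure(t, class = "hard_filter_thresholds")
}

#' Keep only single-nucleotide variant records
#'
#' Retains exactly the sites whose reference allele and every alternate
#' allele are single nucleotides (multi-allelic SNPs included), in their
#' original order. Insertions, deletions and MNPs are dropped.
#'
#' @param cs a [callset()].
#' @return the SNP-only [callset()].
#' @export
select_snps <- function(cs) {
  is_nt <- function(x) nchar(x) == 1L & x %in% c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- is_nt(cs$sites$ref) &
    vapply(cs$sites$alts, function(al) length(al) > 0 && all(is_nt(al)), TRUE)
  out <- callset_subset(cs, keep)
  add_provenance(out, sprintf("select_snps: %d of %d sites retained", sum(keep), length(keep)))
}

#' Apply hard site filters
#'
#' Evaluates the seven threshold conditions of [hard_filter_thresholds()]
#' against each site's annotations. A site PASSes iff none of the conditions
#' triggers; a condition on an absent annotation never triggers (rank-sum
#' annotations are undefined at sites without heterozygous calls, and
#' penalising their absence would mass-drop hom-alt sites). Failed sites are
#' labeled in the FILTER column with the names of the conditions they failed
#' (`QD`, `FS`, `MQ`, `SOR`, `MQRS`, `RPRS`, `QUAL`), not deleted, unless
#' `drop_failed = TRUE`.
#'
#' @param cs a [callset()].
#' @param thresholds a [hard_filter_thresholds()].
#' @param drop_failed if `TRUE`, remove failed sites instead of labeling them.
#' @return the filtered [callset()]; idempotent for fixed thresholds.
#' @export
apply_hard_filters <- function(cs, thresholds = hard_filter_thresholds(),
                               drop_failed = FALSE) {
  t <- thresholds
  trig <- function(x) !is.na(x) & x  # absent annotation never triggers
  fails <- cbind(
    QD   = trig(cs$sites$QD < t$qd_min),
    FS   = trig(cs$sites$FS > t$fs_max),
    MQ   = trig(cs$sites$MQ < t$mq_min),
    SOR  = trig(cs$sites$SOR > t$sor_max),
    MQRS = trig(cs$sites$MQRankSum < t$mqrs_min),
    RPRS = trig(cs$sites$ReadPosRankSum < t$rprs_min),
    QUAL = trig(cs$sites$qual < t$qual_min)
  )
  cs$sites$filter <- lapply(seq_len(n_sites(cs)), function(i) {
    HARD_FILTER_LABELS[fails[i, ]]
  })
  nfail <- sum(rowSums(fails) > 0)
  cs <- add_provenance(cs, sprintf(
    "apply_hard_filters: QD<%g FS>%g MQ<%g SOR>%g MQRankSum<%g ReadPosRankSum<%g QUAL<%g; %d of %d site(s) failed%s",
    t$qd_min, t$fs_max, t$mq_min, t$sor_max, t$mqrs_min, t$rprs_min, t$qual_min,
    nfail, n_sites(cs), if (drop_failed) " (dropped)" else ""))
  if (drop_failed) cs <- callset_subset(cs, rowSums(fails) == 0)
  cs
}

#' Cohort-level filter parameters
#'
#' Bounds on site-level INFO/DP, minimum minor allele frequency and maximum
#' genotype missingness, applied after the hard filters. The source pipeline
#' leaves the four values to the analyst; [default_cohort_params()] derives
#' documented stand-ins from the callset itself.
#'
#' @param min_depth inclusive lower bound on INFO/DP (site failed when
#'   `INFO/DP < min_depth`).
#' @param max_depth inclusive upper bound on INFO/DP.
#' @param maf_min site kept when minor allele frequency `> maf_min`.
#' @param miss_max site kept when the fraction of missing genotypes
#'   `<= miss_max`.
#' @return an object of class `cohort_filter_params`.
#' @export
cohort_filter_params <- function(min_depth, max_depth, maf_min = 0.05,
                                 miss_max = 0.125) {
  stopifnot(min_depth >= 1, max_depth >= min_depth,
            maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  structure(list(min_depth = as.integer(min_depth), max_depth = as.integer(max_depth),
                 maf_min = maf_min, miss_max = miss_max),
            class = "cohort_filter_params")
}

#' @describeIn cohort_filter_params Derive defaults from a callset:
#'   `min_depth = ceiling(mean site DP / 3)`, `max_depth = 2 * mean site DP`,
#'   `maf_min = 0.05`, `miss_max = 0.125` (at most one missing sample of
#'   eight). The derived values are echoed to provenance by the filters that
#'   use them.
#' @param cs a [callset()] with INFO/DP on at least one site.
#' @export
default_cohort_params <- function(cs) {
  mdp <- mean(cs$sites$DP, na.rm = TRUE)
  if (!is.finite(mdp)) stop("cannot derive depth bounds: no site has INFO/DP")
  cohort_filter_params(min_depth = max(1L, ceiling(mdp / 3)),
                       max_depth = ceiling(2 * mdp))
}

#' Filter sites on total (INFO) depth
#'
#' Removes sites whose site-level INFO/DP is below `min_depth` or above
#' `max_depth` (strict inequalities, mirroring the cohort expression
#' `INFO/DP < MIN || INFO/DP > MAX`). Sites lacking INFO/DP are excluded and
#' counted in provenance, not fatal.
#'
#' @param cs a [callset()].
#' @param params a [cohort_filter_params()].
#' @return the depth-filtered [callset()].
#' @export
cohort_depth_filter <- function(cs, params) {
  dp <- cs$sites$DP
  keep <- !is.na(dp) & dp >= params$min_depth & dp <= params$max_depth
  n_absent <- sum(is.na(dp))
  out <- callset_subset(cs, keep)
  add_provenance(out, sprintf(
    "cohort_depth_filter: min_depth=%d max_depth=%d; kept %d of %d site(s); %d site(s) lacked INFO/DP and were excluded",
    params$min_depth, params$max_depth, sum(keep), length(keep), n_absent))
}

#' Filter sites on minor allele frequency and missingness
#'
#' Keeps a site iff `MAF > maf_min` and `F_MISSING <= miss_max`. MAF is
#' allele-based: the frequency of the least frequent called allele among all
#' non-missing called alleles at the site (for multi-allelic sites, the
#' minimum over alleles with non-zero count); a site at which only one
#' allele is called has no minor allele and gets MAF 0. F_MISSING is the
#' fraction of cohort samples with a missing genotype. Sites where every
#' genotype is missing have undefined MAF and are removed and counted.
#'
#' @param cs a [callset()].
#' @param params a [cohort_filter_params()].
#' @return the filtered [callset()].
#' @export
cohort_maf_missing_filter <- function(cs, params) {
  maf <- site_maf(cs)
  fmiss <- site_missingness(cs)
  all_missing <- fmiss >= 1
  keep <- !is.na(maf) & maf > params$maf_min & fmiss <= params$miss_max
  out <- callset_subset(cs, keep)
  add_provenance(out, sprintf(
    "cohort_maf_missing_filter: maf_min=%g miss_max=%g; kept %d of %d site(s); %d all-missing site(s) removed",
    params$maf_min, params$miss_max, sum(keep), length(keep), sum(all_missing)))
}

#' Per-site minor allele frequency and missingness
#'
#' @param cs a [callset()].
#' @return `site_maf`: numeric vector of allele-based MAF per site (`NA`
#'   when no genotype is called); `site_missingness`: fraction of samples
#'   with a missing genotype per site.
#' @export
site_maf <- function(cs) {
  a <- cs$geno$a
  b <- cs$geno$b
  miss <- is.na(a) | is.na(b)
  a[miss] <- NA_integer_
  b[miss] <- NA_integer_
  vapply(seq_len(n_sites(cs)), function(i) {
    al <- c(a[i, ], b[i, ])
    al <- al[!is.na(al)]
    if (length(al) == 0) return(NA_real_)
    counts <- table(al)
    if (length(counts) < 2) return(0)  # monomorphic: no minor allele
    min(counts) / length(al)
  }, 0)
}

#' @rdname site_maf
#' @export
site_missingness <- function(cs) {
  miss <- is.na(cs$geno$a) | is.na(cs$geno$b)
  rowMeans(miss)
}

#' Tabulate filter status of a callset
#'
#' Summary of the FILTER column after [apply_hard_filters()]: number of
#' sites in, per-label fail counts, and sites passing. Suitable for the TSV
#' report emitted by the command-line `filter` subcommand.
#'
#' @param cs a [callset()].
#' @return a `data.frame` with columns `label` and `n_sites`.
#' @export
filter_summary <- function(cs) {
  labs <- cs$sites$filter
  assessed <- !vapply(labs, is.null, TRUE)
  counts <- vapply(HARD_FILTER_LABELS,
                   function(l) sum(vapply(labs, function(f) l %in% f, TRUE)), 0L)
  data.frame(
    label = c("sites_total", "sites_assessed", "sites_pass", HARD_FILTER_LABELS),
    n_sites = c(length(labs), sum(assessed),
                sum(assessed & lengths(labs) == 0), counts),
    stringsAsFactors = FALSE
  )
}
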