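#  Recode table for unordered diploid genotypes, keyed as "min/max".
#  The mapping covers the genotype classes observed across passages:
#  hom-ref, het and hom of the first alternate allele, and the combinations
#  involving a second or third alternate allele that arise at multi-allelic
#  sites. Anything outside this domain (including missing calls) maps to the
#  sentinel NA.
RECODE_MAP <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "0/2" = 3L,
                "1/2" = 4L, "2/2" = 5L, "0/3" = 6L)

#' Recode unordered genotypes to small integers
#'
#' Maps allele pairs to the integer codes used by the per-passage genotype
#' matrix: `0/0 = 0`, `0/1 = 1`, `1/1 = 2`, `0/2 = 3`, `1/2 = 4`, `2/2 = 5`,
#' `0/3 = 6`, insensitive to allele order (`1|0` codes as 1). Any pair
#' outside this domain — including missing genotypes — yields the sentinel
#' `NA`, with a warning when a fully called pair falls outside the mapping.
#'
#' @param a,b integer allele indices (vectors of equal length; `NA` =
#'   missing allele).
#' @return integer vector of codes in `0..6`, sentinel `NA` elsewhere.
#' @export
recode_genotype <- function(a, b) {
  key <- paste0(pmin(a, b), "/", pmax(a, b))
  key[is.na(a) | is.na(b)] <- NA_character_
  code <- unname(RECODE_MAP[key])
  unmapped <- !is.na(key) & is.na(code)
  if (any(unmapped)) {
    warning(sum(unmapped), " called genotype(s) outside the recode domain mapped to sentinel (e.g. ",
            key[unmapped][1], ")")
  }
  code
}

#' Sites-by-samples matrix of recoded genotypes
#'
#' Applies [recode_genotype()] to every call of the callset. Values are the
#' codes `0..6`; the sentinel `NA` marks missing calls and genotypes outside
#' the recode domain.
#'
#' @param cs a [callset()].
#' @return integer matrix (sites x samples).
#' @export
recode_matrix <- function(cs) {
  n <- n_sites(cs)
  code <- recode_genotype(as.vector(cs$geno$a), as.vector(cs$geno$b))
  matrix(code, nrow = n, dimnames = list(NULL, cs$samples))
}

# Deterministic total order over unordered genotype keys used for modal
# tie-breaking: recode value where defined, then (a, b) lexicographically.
genotype_order_key <- function(key) {
  code <- unname(RECODE_MAP[key])
  ab <- strsplit(key, "/", fixed = TRUE)
  a <- as.numeric(vapply(ab, `[`, "", 1))
  b <- as.numeric(vapply(ab, `[`, "", 2))
  ifelse(is.na(code), 1000 + a * 100 + b, code)
}

#' Partition sites into cross-sample fixed versus variable
#'
#' A site is *fixed* iff every sample carries the same non-missing unordered
#' genotype there; any disagreement or any missing call makes it *variable*.
#' In a single-individual passage design the fixed class is dominated by
#' true heterozygous sites of the founder that the reference represents with
#' one allele; the variable class carries the candidate passage mutations.
#'
#' @param cs a [callset()] with at least 2 samples (with a single sample
#'   every called site is trivially fixed).
#' @return an object of class `site_partition`: list with integer index
#'   vectors `fixed_sites` and `variable_sites` (disjoint, union = all
#'   sites).
#' @export
classify_sites <- function(cs) {
  k <- geno_key(cs)
  if (n_sites(cs) == 0) {
    fixed <- logical(0)
  } else {
    k1 <- k[, 1, drop = FALSE][, 1]  # keep length-n, drop names
    fixed <- unname(!is.na(k1) & rowSums(is.na(k)) == 0 &
                      rowSums(k == k1) == ncol(k))
  }
  structure(list(fixed_sites = which(fixed), variable_sites = which(!fixed)),
            class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  cat("site partition: ", length(x$fixed_sites), " fixed, ",
      length(x$variable_sites), " variable site(s)\n", sep = "")
  invisible(x)
}

#' Private sites of a sample
#'
#' A site is private to a sample when that sample's unordered genotype is
#' non-missing and no other sample carries the same genotype there. Private
#' genotypes are the strongest candidates for replicate-specific mutations
#' — or, when their depth and quality are depressed, for artifact calls
#' (see [compare_private_quality()]).
#'
#' @param cs a [callset()].
#' @param sample a sample identifier present in `cs$samples`.
#' @return integer vector of site indices, ascending.
#' @export
private_sites <- function(cs, sample) {
  s <- match_sample(cs, sample)
  k <- geno_key(cs)
  mine <- unname(k[, s, drop = FALSE][, 1])
  shared <- rep(FALSE, n_sites(cs))
  for (j in seq_len(ncol(k))[-s]) {
    kj <- unname(k[, j, drop = FALSE][, 1])
    shared <- shared | (!is.na(kj) & kj == mine)
  }
  which(!is.na(mine) & !shared)
}

#' Modal genotype per site
#'
#' The consensus unordered genotype at each site: the most frequent
#' non-missing genotype, provided it is carried by at least two samples;
#' ties among equally frequent genotypes are broken by the smallest recode
#' value ([recode_genotype()]), then lexicographically by allele pair. When
#' no genotype is shared by two samples there is no consensus and `NA` is
#' returned for the site.
#'
#' @param cs a [callset()].
#' @return character vector of `"a/b"` keys, `NA` where no consensus exists.
#' @export
modal_genotypes <- function(cs) {
  n <- n_sites(cs)
  if (n == 0) return(character(0))
  k <- geno_key(cs)
  dt <- data.table::data.table(site = rep(seq_len(n), ncol(k)), gkey = as.vector(k))
  dt <- dt[!is.na(gkey)]
  if (nrow(dt) == 0) return(rep(NA_character_, n))
  cnt <- dt[, .N, by = .(site, gkey)]
  cnt <- cnt[N >= 2]
  if (nrow(cnt) == 0) return(rep(NA_character_, n))
  cnt[, ord := genotype_order_key(gkey)]
  data.table::setorder(cnt, site, -N, ord)
  top <- cnt[!duplicated(site)]
  out <- rep(NA_character_, n)
  out[top$site] <- top$gkey
  out
}

#' Deviant sites of a sample
#'
#' Variable sites at which the sample departs from the cohort consensus:
#' its genotype is missing, or there is no consensus genotype at the site,
#' or its genotype differs from the modal genotype (see
#' [modal_genotypes()]). Fixed sites contribute to no sample's deviant set.
#' Every private site of a sample is also deviant.
#'
#' @param cs a [callset()].
#' @param sample a sample identifier.
#' @param partition optionally a precomputed [classify_sites()] result.
#' @param modes optionally a precomputed [modal_genotypes()] vector.
#' @return integer vector of site indices, ascending.
#' @export
deviant_sites <- function(cs, sample, partition = NULL, modes = NULL) {
  s <- match_sample(cs, sample)
  if (is.null(partition)) partition <- classify_sites(cs)
  if (is.null(modes)) modes <- modal_genotypes(cs)
  v <- partition$variable_sites
  mine <- unname(geno_key(cs)[, s, drop = FALSE][, 1])[v]
  m <- modes[v]
  dev <- is.na(mine) | is.na(m) | mine != m
  sort(v[dev])
}

#' Genotype differences between two samples
#'
#' Counts the retained sites at which two samples' unordered genotypes
#' differ. A site where exactly one of the two genotypes is missing counts
#' as a difference; a site missing in both does not. The count is symmetric
#' in the two samples and zero when a sample is compared with itself.
#'
#' @param cs a [callset()].
#' @param sample,reference_sample sample identifiers.
#' @return integer count of differing sites.
#' @export
diff_vs_reference <- function(cs, sample, reference_sample) {
  s <- match_sample(cs, sample)
  r <- match_sample(cs, reference_sample)
  k <- geno_key(cs)
  x <- unname(k[, s, drop = FALSE][, 1])
  y <- unname(k[, r, drop = FALSE][, 1])
  sum(xor(is.na(x), is.na(y)) | (!is.na(x) & !is.na(y) & x != y))
}

match_sample <- function(cs, sample) {
  s <- match(sample, cs$samples)
  if (is.na(s)) stop("sample '", sample, "' not found in callset (samples: ",
                     paste(cs$samples, collapse = ", "), ")")
  s
}

#' Percentage helpers used by the passage report
#'
#' `pct_of_genome()` expresses a site count as a percentage of the genome
#' size, rounded (half-to-even) to 4 decimal places; `pct_of_total()`
#' expresses a count as a percentage of the total retained sites, rounded to
#' `digits` decimal places (2 for the difference-versus-reference column).
#'
#' @param count non-negative integer site count.
#' @param genome_size genome size in bp.
#' @param total total number of retained sites.
#' @param digits decimal places to round to.
#' @return numeric percentage.
#' @export
pct_of_genome <- function(count, genome_size) round(100 * count / genome_size, 4)

#' @rdname pct_of_genome
#' @export
pct_of_total <- function(count, total, digits = 2) round(100 * count / total, digits)

#' Per-sample passage statistics table
#'
#' Builds the per-sample summary of a filtered multi-passage callset: median
#' FORMAT depth and genotype quality over the sample's non-missing calls,
#' the number of non-fixed (deviant) sites and how many of those are private
#' to the sample, the deviant count as a percentage of the genome (4 dp),
#' counts of deviant sites that are heterozygous `0/1` and of those that are
#' neither `0/1` nor `1/1`, the latter as a percentage of all retained sites,
#' and the number and percentage (2 dp) of sites at which the sample differs
#' from the reference sample (absent for the reference row itself).
#'
#' @param cs a filtered [callset()].
#' @param reference_sample the baseline sample (the primary-tissue passage);
#'   must be present in `cs$samples`.
#' @param genome_size genome size in bp (> 0), the denominator of the
#'   genome-percentage column.
#' @return a `data.frame` with one row per sample and columns `sample`,
#'   `median_dp`, `median_gq`, `nonfixed_count`, `private_count`,
#'   `pct_of_genome`, `het01_count`, `other_count`, `pct_nonfixed`,
#'   `diff_vs_p0`, `pct_diff_vs_p0`. The `pct_nonfixed` column (share of
#'   `other_count` in all retained sites) is carried with metadata attribute
#'   `pct_nonfixed_note` flagging that its published analogue is not
#'   internally consistent and the percent definition is used here.
#' @export
passage_table <- function(cs, reference_sample, genome_size) {
  stopifnot(genome_size > 0)
  match_sample(cs, reference_sample)  # fatal if absent
  total <- n_sites(cs)
  part <- classify_sites(cs)
  modes <- modal_genotypes(cs)
  k <- geno_key(cs)
  rows <- lapply(cs$samples, function(sm) {
    s <- match_sample(cs, sm)
    called <- !is.na(k[, s])
    dev <- deviant_sites(cs, sm, partition = part, modes = modes)
    priv <- private_sites(cs, sm)
    devk <- k[dev, s]
    is_ref <- sm == reference_sample
    d <- if (is_ref) NA_integer_ else diff_vs_reference(cs, sm, reference_sample)
    data.frame(
      sample = sm,
      median_dp = stats::median(cs$geno$dp[, s][called], na.rm = TRUE),
      median_gq = stats::median(cs$geno$gq[, s][called], na.rm = TRUE),
      nonfixed_count = length(dev),
      private_count = length(priv),
      pct_of_genome = pct_of_genome(length(dev), genome_size),
      het01_count = sum(devk == "0/1", na.rm = TRUE),
      other_count = sum(is.na(devk) | !(devk %in% c("0/1", "1/1"))),
      pct_nonfixed = pct_of_total(sum(is.na(devk) | !(devk %in% c("0/1", "1/1"))),
                                  total, digits = 3),
      diff_vs_p0 = d,
      pct_diff_vs_p0 = if (is_ref) NA_real_ else pct_of_total(d, total, digits = 2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pct_nonfixed_note") <-
    paste("pct_nonfixed = 100 * other_count / total retained sites;",
          "the published analogue of this column mixes scales and is not",
          "reproduced as printed")
  out
}

#' Rank-sum comparison of private-site depth or quality
#'
#' Tests whether a sample's per-site depth (FORMAT DP) or genotype quality
#' (FORMAT GQ) at its private sites differs from the same metric at all its
#' other retained sites, with a two-sided two-sample Mann-Whitney rank-sum
#' test ([rank_sum_test()]). Consistently depressed depth and quality at
#' private sites indicates artifact calls rather than true passage
#' mutations.
#'
#' @param cs a filtered [callset()].
#' @param sample a sample identifier.
#' @param metric `"depth"` (FORMAT DP) or `"quality"` (FORMAT GQ).
#' @return a `rank_sum_result`: list with `statistic` (Mann-Whitney U of the
#'   private group), `n_private`, `n_other`, `p_two_sided` and `method`
#'   (`"exact"` or `"normal-approx-with-tie-correction"`).
#' @export
compare_private_quality <- function(cs, sample, metric = c("depth", "quality")) {
  metric <- match.arg(metric)
  s <- match_sample(cs, sample)
  vals <- if (metric == "depth") cs$geno$dp[, s] else cs$geno$gq[, s]
  called <- !is.na(geno_key(cs)[, s]) & !is.na(vals)
  priv <- rep(FALSE, n_sites(cs))
  priv[private_sites(cs, sample)] <- TRUE
  x <- vals[called & priv]
  y <- vals[called & !priv]
  if (length(x) == 0) stop("no private site with a non-missing ", metric,
                           " for sample '", sample, "'")
  if (length(y) == 0) stop("no non-private site with a non-missing ", metric,
                           " for sample '", sample, "'")
  res <- rank_sum_test(x, y)
  names(res)[names(res) == "n_x"] <- "n_private"
  names(res)[names(res) == "n_y"] <- "n_other"
  res
}
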