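#' Multi-sample variant callset
#'
#' A `callset` is the central container of the package: an ordered vector of
#' sample identifiers plus one row per variant site, with per-sample genotype
#' calls stored as parallel sites-by-samples matrices. All coordinates are
#' 1-based, as in VCF and GFF3; there is no internal 0-based layer.
#'
#' @details
#' The object is a list with components:
#' \describe{
#'   \item{samples}{character vector of unique sample identifiers, in column
#'     order of the genotype matrices.}
#'   \item{sites}{a `data.frame` with one row per site and columns `chrom`,
#'     `pos` (1-based integer), `ref` (single nucleotide), `alts`
#'     (list column of single-nucleotide alternate alleles), `qual` (QUAL,
#'     `NA` if absent), the seven site-level annotations `QD`, `FS`, `MQ`,
#'     `SOR`, `MQRankSum`, `ReadPosRankSum`, `DP` (numeric, `NA` means the
#'     annotation is absent, never 0), and `filter` (list column: `NULL` =
#'     not yet assessed, `character(0)` = PASS, otherwise the labels of the
#'     failed filters).}
#'   \item{geno}{list of sites-by-samples matrices: `a` and `b` (integer
#'     allele indices, `NA` = missing; a genotype is missing iff either
#'     allele is `NA`), `phased` (logical), `dp` (FORMAT DP, integer, `NA`
#'     allowed), `gq` (FORMAT GQ, integer in [0, 99], `NA` allowed).}
#'   \item{provenance}{character vector logging the operations applied.}
#' }
#'
#' Genotypes are stored as ordered pairs with a phased flag, but every
#' comparison in the package (fixed/variable classification, private and
#' deviant sites, genotype recoding) uses the unordered allele pair, so
#' `0|1` and `1|0` are the same genotype throughout.
#'
#' @param samples character vector of sample names.
#' @param sites site `data.frame` as described above.
#' @param geno list of genotype matrices as described above.
#' @param provenance character vector of log lines.
#' @return An object of class `callset`.
#' @seealso [read_callset()], [write_callset()], [validate_callset()]
#' @export
callset <- function(samples, sites, geno, provenance = character()) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(sites), is.list(geno))
  needed <- c("chrom", "pos", "ref", "alts", "qual", INFO_KEYS, "filter")
  miss <- setdiff(needed, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  for (m in c("a", "b", "phased", "dp", "gq")) {
    if (!is.matrix(geno[[m]]) ||
        nrow(geno[[m]]) != nrow(sites) ||
        ncol(geno[[m]]) != length(samples)) {
      stop("geno$", m, " must be a ", nrow(sites), " x ", length(samples), " matrix")
    }
    colnames(geno[[m]]) <- samples
  }
  structure(
    list(samples = samples, sites = sites, geno = geno,
         provenance = as.character(provenance)),
    class = "callset"
  )
}

#  Site-level INFO annotations modeled by the package (GATK names).
INFO_KEYS <- c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum", "DP")

#' @export
print.callset <- function(x, ...) {
  cat("callset: ", n_sites(x), " site(s) x ", n_samples(x), " sample(s)\n", sep = "")
  cat("samples: ", paste(x$samples, collapse = ", "), "\n", sep = "")
  if (length(x$provenance)) {
    cat("provenance:\n")
    cat(paste0("  ", utils::tail(x$provenance, 5), collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Number of sites / samples in a callset
#' @param cs a [callset()].
#' @return integer count.
#' @export
n_sites <- function(cs) nrow(cs$sites)

#' @rdname n_sites
#' @export
n_samples <- function(cs) length(cs$samples)

#' Append a line to a callset's provenance log
#' @param cs a [callset()].
#' @param msg character line to append.
#' @return the callset with the line appended.
#' @export
add_provenance <- function(cs, msg) {
  cs$provenance <- c(cs$provenance, msg)
  cs
}

#' Subset a callset by site index
#'
#' Keeps the given sites (logical or integer index into site rows) in their
#' current order; all genotype matrices are subset in parallel.
#'
#' @param cs a [callset()].
#' @param idx logical or integer index over sites.
#' @return a [callset()] with the selected sites.
#' @export
callset_subset <- function(cs, idx) {
  cs$sites <- cs$sites[idx, , drop = FALSE]
  rownames(cs$sites) <- NULL
  for (m in names(cs$geno)) {
    cs$geno[[m]] <- cs$geno[[m]][idx, , drop = FALSE]
  }
  cs
}

#' Unordered genotype keys
#'
#' Returns a sites-by-samples character matrix encoding each call's unordered
#' allele pair as `"min/max"` (e.g. `"0/1"` for both `0|1` and `1|0`), with
#' `NA` for missing genotypes. This is the comparison currency used by the
#' fixed/variable partition, private- and deviant-site detection and
#' genotype recoding.
#'
#' @param cs a [callset()].
#' @return character matrix, `NA` = missing call.
#' @export
geno_key <- function(cs) {
  a <- cs$geno$a
  b <- cs$geno$b
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  k <- matrix(paste0(lo, "/", hi), nrow = nrow(a), ncol = ncol(a),
              dimnames = dimnames(a))
  k[is.na(lo) | is.na(hi)] <- NA_character_
  k
}

#' Validate a callset against its structural invariants
#'
#' Report-only check of the container invariants: unique sample names, sites
#' sorted by (chrom, pos) with no chromosome revisited, genotype matrices
#' aligned to sites and samples, allele indices within `0..n_alt`,
#' non-negative depths, GQ within `[0, 99]`, positions >= 1, and alternate
#' alleles non-empty and distinct from the reference allele.
#'
#' @param cs a [callset()].
#' @return character vector of human-readable violations; `character(0)` iff
#'   the callset is valid.
#' @export
validate_callset <- function(cs) {
  bad <- character()
  if (anyDuplicated(cs$samples)) {
    bad <- c(bad, paste0("duplicated sample name(s): ",
                         paste(unique(cs$samples[duplicated(cs$samples)]), collapse = ", ")))
  }
  n <- n_sites(cs)
  if (n > 0) {
    if (any(cs$sites$pos < 1, na.rm = TRUE)) {
      bad <- c(bad, "position < 1")
    }
    srt <- unsorted_at(cs$sites$chrom, cs$sites$pos)
    if (!is.na(srt)) {
      bad <- c(bad, sprintf("sites unsorted at %s:%d",
                            cs$sites$chrom[srt], cs$sites$pos[srt]))
    }
    for (m in c("a", "b", "phased", "dp", "gq")) {
      g <- cs$geno[[m]]
      if (!is.matrix(g) || nrow(g) != n || ncol(g) != n_samples(cs)) {
        bad <- c(bad, sprintf("call/sample mismatch in geno$%s (%d x %d, expected %d x %d)",
                              m, NROW(g), NCOL(g), n, n_samples(cs)))
      }
    }
    nalt <- lengths(cs$sites$alts)
    for (m in c("a", "b")) {
      g <- cs$geno[[m]]
      if (is.matrix(g) && nrow(g) == n) {
        over <- which(g > nalt | g < 0, arr.ind = TRUE)  # recycles nalt by row
        if (nrow(over)) {
          i <- over[1, 1]
          bad <- c(bad, sprintf("allele index out of range at %s:%d (index %d, %d alt allele(s))",
                                cs$sites$chrom[i], cs$sites$pos[i],
                                g[over[1, 1], over[1, 2]], nalt[i]))
        }
      }
    }
    if (any(cs$geno$dp < 0, na.rm = TRUE)) bad <- c(bad, "negative depth")
    if (any(cs$geno$gq < 0 | cs$geno$gq > 99, na.rm = TRUE)) {
      bad <- c(bad, "GQ outside [0, 99]")
    }
    if (any(lengths(cs$sites$alts) == 0)) bad <- c(bad, "site with no alternate allele")
    same <- mapply(function(r, al) any(al == r), cs$sites$ref, cs$sites$alts)
    if (any(same)) {
      i <- which(same)[1]
      bad <- c(bad, sprintf("alt equals ref at %s:%d", cs$sites$chrom[i], cs$sites$pos[i]))
    }
  }
  bad
}

# First row index (or NA) at which (chrom, pos) order is violated: positions
# must be non-decreasing within a chromosome and a chromosome block must not
# reappear after another chromosome intervened.
unsorted_at <- function(chrom, pos) {
  if (length(chrom) < 2) return(NA_integer_)
  same <- chrom[-1] == chrom[-length(chrom)]
  bad_pos <- which(same & pos[-1] < pos[-length(pos)])
  bad <- if (length(bad_pos)) min(bad_pos) + 1L else NA_integer_
  r <- rle(chrom)
  if (anyDuplicated(r$values)) {  # chromosome block reappears later
    ends <- cumsum(r$lengths)
    rb <- ends[which(duplicated(r$values))[1] - 1L] + 1L
    bad <- min(bad, rb, na.rm = TRUE)
  }
  bad
}

# Build an all-missing genotype matrix set for n sites x m samples.
empty_geno <- function(n, samples) {
  m <- length(samples)
  int <- matrix(NA_integer_, n, m, dimnames = list(NULL, samples))
  list(a = int, b = int,
       phased = matrix(FALSE, n, m, dimnames = list(NULL, samples)),
       dp = int, gq = int)
}
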