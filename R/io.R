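#' Read a multi-sample VCF into a callset
#'
#' Parses a VCF 4.x file (plain or gzipped) into the package's [callset()]
#' model. Per-sample `GT`, `DP` and `GQ` are extracted; all other FORMAT
#' fields are ignored. The seven site-level annotations `QD`, `FS`, `MQ`,
#' `SOR`, `MQRankSum`, `ReadPosRankSum` and `DP` are taken from INFO; an
#' absent key is recorded as `NA` (absent), never as 0. Multi-allelic
#' records are kept as-is.
#'
#' @param path path to a VCF file with `GT` in FORMAT.
#' @return a [callset()].
#' @section Errors:
#' A record whose FORMAT lacks `GT`, duplicated sample names, and records
#' out of (chrom, pos) order are fatal; the sort error names the offending
#' position.
#' @export
read_callset <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  if (is.null(gt) || is.null(colnames(gt)) || ncol(gt) < 2) {
    stop("VCF has no sample columns")
  }
  samples <- colnames(gt)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample name(s) in VCF header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  fix <- v@fix
  n <- nrow(fix)
  if (n > 0 && any(!grepl("(^|:)GT(:|$)", gt[, "FORMAT"]))) {
    stop("VCF record without GT in FORMAT (record ",
         which(!grepl("(^|:)GT(:|$)", gt[, "FORMAT"]))[1], ")")
  }
  pos <- as.integer(fix[, "POS"])
  bad <- unsorted_at(as.character(fix[, "CHROM"]), pos)
  if (!is.na(bad)) {
    stop(sprintf("VCF records are not sorted by position: offending record at %s:%d",
                 fix[bad, "CHROM"], pos[bad]))
  }

  info_num <- function(key) {
    if (n == 0) return(numeric(0))
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = pos,
    ref = as.character(fix[, "REF"]),
    stringsAsFactors = FALSE
  )
  sites$alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", as.character(fix[, "ALT"])), ",",
                         fixed = TRUE)
  sites$qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  for (key in INFO_KEYS) sites[[key]] <- info_num(key)
  filt <- as.character(fix[, "FILTER"])
  sites$filter <- lapply(filt, function(f) {
    if (is.na(f) || f == ".") NULL
    else if (f == "PASS") character(0)
    else strsplit(f, ";", fixed = TRUE)[[1]]
  })

  geno <- empty_geno(n, samples)
  if (n > 0) {
    gtm <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
    parts <- strsplit(as.vector(gtm), "[/|]")
    first <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".", "")
    second <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
    dm <- list(NULL, samples)
    geno$a <- matrix(suppressWarnings(as.integer(first)), n, length(samples), dimnames = dm)
    geno$b <- matrix(suppressWarnings(as.integer(second)), n, length(samples), dimnames = dm)
    geno$phased <- matrix(grepl("|", as.vector(gtm), fixed = TRUE), n,
                          length(samples), dimnames = dm)
    geno$dp <- format_int_matrix(v, "DP", n, samples)
    geno$gq <- format_int_matrix(v, "GQ", n, samples)
  }
  prov <- sub("^##passage_stability_cmd=", "",
              grep("^##passage_stability_cmd=", v@meta, value = TRUE))
  callset(samples, sites, geno, provenance = prov)
}

# FORMAT field as an integer matrix; all-NA when the field is absent.
format_int_matrix <- function(v, key, n, samples) {
  m <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = key, as.numeric = TRUE)),
    error = function(e) NULL
  )
  if (is.null(m)) m <- matrix(NA_real_, n, length(samples))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, samples)
  m
}

#' Write a callset to a VCF 4.2 file
#'
#' Emits the modeled field set: CHROM/POS/REF/ALT/QUAL, the seven INFO
#' annotations (only when present), FILTER (`.` when never assessed, `PASS`
#' or the failed-filter labels otherwise), and per-sample `GT:DP:GQ`.
#' Provenance lines are written as `##passage_stability_cmd=` header lines,
#' so `read_callset(write_callset(cs))` reproduces `cs` on the whole modeled
#' field set.
#'
#' @param cs a [callset()].
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_callset <- function(cs, path) {
  num <- function(x) ifelse(is.na(x), ".", vapply(x, num2str, ""))
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant confidence by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias (Phred)">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio strand bias">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank-sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank-sum">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Combined site depth">',
    sprintf('##FILTER=<ID=%s,Description="Failed hard filter %s">',
            HARD_FILTER_LABELS, HARD_FILTER_LABELS),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste0("##passage_stability_cmd=", cs$provenance),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            cs$samples), collapse = "\t")
  )
  n <- n_sites(cs)
  body <- character(0)
  if (n > 0) {
    info <- vapply(seq_len(n), function(i) {
      vals <- vapply(INFO_KEYS, function(k) cs$sites[[k]][i], 0)
      keep <- !is.na(vals)
      if (!any(keep)) return(".")
      paste0(INFO_KEYS[keep], "=",
             vapply(vals[keep], num2str, ""), collapse = ";")
    }, "")
    filt <- vapply(cs$sites$filter, function(f) {
      if (is.null(f)) "." else if (length(f) == 0) "PASS" else paste(f, collapse = ";")
    }, "")
    al <- function(x) ifelse(is.na(x), ".", as.character(x))
    sep <- ifelse(cs$geno$phased, "|", "/")
    gtstr <- matrix(paste0(al(cs$geno$a), sep, al(cs$geno$b), ":",
                           al(cs$geno$dp), ":", al(cs$geno$gq)),
                    nrow = n)
    body <- vapply(seq_len(n), function(i) {
      paste(c(cs$sites$chrom[i], cs$sites$pos[i], ".", cs$sites$ref[i],
              paste(cs$sites$alts[[i]], collapse = ","),
              num(cs$sites$qual[i]), filt[i], info[i], "GT:DP:GQ",
              gtstr[i, ]), collapse = "\t")
    }, "")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

# Numeric to VCF string without precision loss or scientific notation for
# integers; as.character keeps 15 significant digits.
num2str <- function(x) {
  if (is.na(x)) return(".")
  if (abs(x) < 2^31 && x == as.integer(x)) return(as.character(as.integer(x)))
  as.character(x)
}
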