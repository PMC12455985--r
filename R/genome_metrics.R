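#' Phred quality / error-rate conversion
#'
#' Converts a Phred-scaled consensus quality value (QV) to the base-call
#' error rate it encodes, `10^(-qv/10)`, and back, `-10 * log10(err)`. A QV
#' of 60 corresponds to about one error per megabase. The two functions are
#' mutual inverses to within 1e-9 relative tolerance on `(0, 100]`.
#'
#' @param qv Phred-scaled quality (>= 0).
#' @param err error rate as a fraction in `(0, 1]`.
#' @return `qv_to_error()`: the error-rate fraction; `error_to_qv()`: the
#'   Phred-scaled quality.
#' @examples
#' error_to_qv(3.82794e-07)  # 64.17 at 2 dp
#' qv_to_error(30)           # 1e-3
#' @export
qv_to_error <- function(qv) {
  stopifnot(all(qv >= 0))
  10^(-qv / 10)
}

#' @rdname qv_to_error
#' @export
error_to_qv <- function(err) {
  stopifnot(all(err > 0), all(err <= 1))
  -10 * log10(err)
}

#' Heterozygous-site density from a heterozygosity fraction
#'
#' Expresses a genome-wide heterozygosity fraction as heterozygous sites per
#' kilobase, the diversity indicator conventionally reported for birds
#' (0.2\% heterozygosity = 2 het sites / kb).
#'
#' @param het_fraction fraction of sites heterozygous, in `[0, 1]`.
#' @return sites per kb (`het_fraction * 1000`).
#' @export
het_per_kb <- function(het_fraction) {
  stopifnot(all(het_fraction >= 0), all(het_fraction <= 1))
  het_fraction * 1000
}

#' Assembly contiguity statistics
#'
#' Computes the standard contiguity summary of a sequence set: total size,
#' sequence count, Nx/Lx for x = 50 and 90 (Nx = length of the sequence at
#' which the cumulative sorted-descending length first reaches x\% of the
#' total; Lx = its 1-based rank), and — when residues are supplied — GC
#' percentage and Ns per 100 kb.
#'
#' @param lengths positive sequence lengths in bp, or `NULL` to derive them
#'   from `sequences`.
#' @param sequences optional residues as a `Biostrings::DNAStringSet` or a
#'   character vector of sequences.
#' @return list of class `assembly_stats`: `total_size`, `n_sequences`,
#'   `n50`, `l50`, `n90`, `l90`, and `gc_percent` / `n_per_100kb` (`NA`
#'   without residues).
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1))  # N50 = 4, L50 = 2; N90 = 2, L90 = 4
#' @export
assembly_stats <- function(lengths = NULL, sequences = NULL) {
  if (!is.null(sequences) && is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(lengths)) {
    if (is.null(sequences)) stop("either lengths or sequences must be given")
    lengths <- Biostrings::width(sequences)
  }
  if (length(lengths) == 0) stop("no sequences: lengths must be non-empty")
  stopifnot(all(lengths > 0))
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(srt)
  total <- cum[length(cum)]
  nx <- function(x) {
    i <- which(cum >= x / 100 * total)[1]
    c(n = srt[i], l = i)
  }
  s50 <- nx(50)
  s90 <- nx(90)
  gc <- n_rate <- NA_real_
  if (!is.null(sequences)) {
    freq <- colSums(Biostrings::alphabetFrequency(sequences, baseOnly = TRUE))
    acgt <- sum(freq[c("A", "C", "G", "T")])
    gc <- 100 * sum(freq[c("C", "G")]) / acgt
    n_tot <- sum(Biostrings::vcountPattern("N", sequences))
    n_rate <- 1e5 * n_tot / total
  }
  structure(list(total_size = total, n_sequences = length(lengths),
                 n50 = s50[["n"]], l50 = s50[["l"]],
                 n90 = s90[["n"]], l90 = s90[["l"]],
                 gc_percent = gc, n_per_100kb = n_rate),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly: %s bp in %d sequence(s)\n",
              format(x$total_size, big.mark = ","), x$n_sequences))
  cat(sprintf("  N50 %s (L50 %d), N90 %s (L90 %d)\n",
              format(x$n50, big.mark = ","), x$l50,
              format(x$n90, big.mark = ","), x$l90))
  if (!is.na(x$gc_percent)) {
    cat(sprintf("  GC %.2f%%, Ns per 100 kb %.2f\n", x$gc_percent, x$n_per_100kb))
  }
  invisible(x)
}

#' Classify chromosomes as macro- or microchromosomes
#'
#' Avian karyotypes split into large macrochromosomes and small, gene-dense
#' microchromosomes; the conventional boundary used here is 30 Mb, with the
#' boundary length itself assigned to the macro class (configurable).
#'
#' @param lengths named (or unnamed) chromosome lengths in bp.
#' @param cutoff length at or above which a chromosome is a macrochromosome
#'   (default 30,000,000 bp).
#' @return a `data.frame` with columns `name`, `length`, `klass`
#'   (`"macro"`/`"micro"`), with per-class counts in attribute `counts`.
#' @export
classify_chromosomes <- function(lengths, cutoff = 30e6) {
  stopifnot(all(lengths > 0), cutoff > 0)
  nm <- names(lengths)
  if (is.null(nm)) nm <- paste0("seq", seq_along(lengths))
  klass <- ifelse(lengths >= cutoff, "macro", "micro")
  out <- data.frame(name = nm, length = as.numeric(lengths), klass = klass,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(macro = sum(klass == "macro"),
                           micro = sum(klass == "micro"))
  out
}

#' Read sequence lengths from FASTA or a two-column length table
#'
#' Accepts either a FASTA file (lengths taken from the sequences) or a
#' `.fai`-style whitespace-separated table whose first two columns are
#' sequence name and length.
#'
#' @param path input file.
#' @return named numeric vector of lengths in bp.
#' @export
read_seq_lengths <- function(path) {
  head1 <- readLines(path, n = 1)
  if (startsWith(head1, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    lens <- Biostrings::width(seqs)
    names(lens) <- sub("\\s.*$", "", names(seqs))
    return(lens)
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Per-class gene and intron summaries from a GFF3 annotation
#'
#' Summarises gene structure separately for macro- and microchromosomes:
#' gene count, gene density (genes per Mb of summed class chromosome
#' length), mean gene length (gene feature span, 1-based inclusive), mean
#' intron length and mean exon count of the retained transcript. One
#' transcript is retained per gene — the one with the largest summed exon
#' length, ties broken by lexicographically smallest transcript ID —
#' mirroring a longest-isoform annotation reduction. Introns are the gaps
#' between consecutive exons of the retained transcript (exons are sorted
#' by start; overlapping exons are a fatal annotation error naming the
#' transcript).
#'
#' @param gff path to a GFF3 file with gene/mRNA/exon features, or a
#'   `GenomicRanges::GRanges` as returned by `rtracklayer::import`.
#' @param classes chromosome classification from [classify_chromosomes()].
#' @return a `data.frame` with one row per class (`macro`, `micro`) and
#'   columns `klass`, `class_length_mb`, `gene_count`, `genes_per_mb`,
#'   `mean_gene_length`, `mean_intron_length`, `mean_exons_per_gene`
#'   (means `NA` for a class with no genes).
#' @export
gene_class_summary <- function(gff, classes) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3") else gff
  type <- as.character(gr$type)
  id <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else as.character(gr$ID)
  parent <- if (is.null(gr$Parent)) {
    rep(NA_character_, length(gr))
  } else {
    vapply(as.list(gr$Parent),
           function(p) if (length(p)) p[1] else NA_character_, "")
  }

  genes <- gr[type == "gene"]
  txs <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]
  tx_id <- id[type %in% c("mRNA", "transcript")]
  tx_parent <- parent[type %in% c("mRNA", "transcript")]
  ex_parent <- parent[type == "exon"]

  # longest isoform per gene by summed exon length, ties by transcript ID
  exlen <- tapply(GenomicRanges::width(exons), ex_parent, sum)
  pick <- data.frame(tx = tx_id, gene = tx_parent,
                     exlen = as.numeric(exlen[tx_id]), stringsAsFactors = FALSE)
  pick <- pick[order(pick$gene, -pick$exlen, pick$tx), ]
  pick <- pick[!duplicated(pick$gene), ]

  intron_len <- function(tx) {
    e <- exons[!is.na(ex_parent) & ex_parent == tx]
    st <- sort(GenomicRanges::start(e))
    en <- GenomicRanges::end(e)[order(GenomicRanges::start(e))]
    if (length(st) < 2) return(numeric(0))
    gaps <- st[-1] - en[-length(en)] - 1
    if (any(gaps < 0)) stop("overlapping exons in transcript '", tx, "'")
    gaps
  }

  gene_chrom <- as.character(GenomicRanges::seqnames(genes))
  gene_len <- GenomicRanges::width(genes)
  gene_id <- id[type == "gene"]
  klass_of <- stats::setNames(classes$klass, classes$name)

  out <- lapply(c("macro", "micro"), function(kl) {
    chroms <- classes$name[classes$klass == kl]
    class_mb <- sum(classes$length[classes$klass == kl]) / 1e6
    on_class <- gene_chrom %in% chroms
    gcount <- sum(on_class)
    if (gcount == 0) {
      return(data.frame(klass = kl, class_length_mb = class_mb, gene_count = 0L,
                        genes_per_mb = if (class_mb > 0) 0 else NA_real_,
                        mean_gene_length = NA_real_, mean_intron_length = NA_real_,
                        mean_exons_per_gene = NA_real_, stringsAsFactors = FALSE))
    }
    gids <- gene_id[on_class]
    ptx <- pick$tx[match(gids, pick$gene)]
    ptx <- ptx[!is.na(ptx)]
    introns <- unlist(lapply(ptx, intron_len))
    nex <- vapply(ptx, function(tx) sum(!is.na(ex_parent) & ex_parent == tx), 0L)
    data.frame(
      klass = kl, class_length_mb = class_mb, gene_count = gcount,
      genes_per_mb = gcount / class_mb,
      mean_gene_length = mean(gene_len[on_class]),
      mean_intron_length = if (length(introns)) mean(introns) else NA_real_,
      mean_exons_per_gene = mean(nex),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
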