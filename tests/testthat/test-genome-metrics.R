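test_that("Phred QV / error conversions are exact and mutually inverse", {
  expect_equal(qv_to_error(0), 1)
  expect_equal(qv_to_error(30), 1e-3)
  expect_equal(qv_to_error(64.17), 3.828e-7, tolerance = 1e-3)
  expect_equal(error_to_qv(1), 0)
  expect_equal(round(error_to_qv(3.82794e-07), 2), 64.17)
  expect_equal(round(error_to_qv(1.80919e-06), 2), 57.43)
  qv <- seq(0.5, 100, by = 0.5)
  expect_equal(error_to_qv(qv_to_error(qv)), qv, tolerance = 1e-9)
  expect_error(error_to_qv(0))
})

test_that("heterozygosity converts to sites per kb", {
  expect_equal(het_per_kb(0.002), 2)
  expect_equal(het_per_kb(0), 0)
  expect_equal(het_per_kb(0.0059), 5.9)
})

test_that("contiguity statistics match the brute-force definition", {
  one <- assembly_stats(10)
  expect_equal(one$n50, 10)
  expect_equal(one$l50, 1)

  s <- assembly_stats(c(5, 4, 3, 2, 1))  # total 15
  expect_equal(s$n50, 4)
  expect_equal(s$l50, 2)
  expect_equal(s$n90, 2)
  expect_equal(s$l90, 4)
  expect_equal(s$total_size, 15)

  # brute-force oracle on random length sets, plus monotonicity
  nx_oracle <- function(lens, x) {
    srt <- sort(lens, decreasing = TRUE)
    tot <- sum(srt)
    acc <- 0
    for (i in seq_along(srt)) {
      acc <- acc + srt[i]
      if (acc >= x / 100 * tot) return(c(n = srt[i], l = i))
    }
  }
  set.seed(5)
  for (i in 1:25) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    st <- assembly_stats(lens)
    o50 <- nx_oracle(lens, 50)
    o90 <- nx_oracle(lens, 90)
    expect_equal(c(st$n50, st$l50), unname(o50))
    expect_equal(c(st$n90, st$l90), unname(o90))
    expect_gte(st$n50, st$n90)
    expect_lte(st$l50, st$l90)
    expect_lte(st$l90, st$n_sequences)
    expect_lte(st$n50 * st$l50, st$total_size)
  }
  expect_error(assembly_stats(numeric(0)), "non-empty")
})

test_that("GC and N content come from the residues", {
  s <- assembly_stats(sequences = c("ACGT"))
  expect_equal(s$gc_percent, 50)
  s2 <- assembly_stats(sequences = c("ACGTN", "GGGGG"))
  expect_equal(s2$gc_percent, 100 * 7 / 9)   # Ns excluded from the GC base
  expect_equal(s2$n_per_100kb, 1e5 * 1 / 10)
})

test_that("chromosome classification splits at the cutoff, boundary to macro", {
  cl <- classify_chromosomes(c(a = 40e6, b = 12e6))
  expect_equal(cl$klass, c("macro", "micro"))
  expect_equal(classify_chromosomes(30e6)$klass, "macro")  # boundary length
  expect_equal(classify_chromosomes(30e6 - 1)$klass, "micro")
  lens <- c(50e6, 31e6, 29e6, 8e6, 3.4e6)
  cl2 <- classify_chromosomes(lens)
  expect_equal(unname(attr(cl2, "counts")), c(2L, 3L))
  expect_equal(sum(attr(cl2, "counts")), length(lens))    # partition
  # the cutoff side is configurable
  expect_equal(classify_chromosomes(12e6, cutoff = 10e6)$klass, "macro")
})

test_that("length tables and FASTA both feed the length readers", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 something", "ACGTACGT", ">chr2", "ACG"), fa)
  lens <- read_seq_lengths(fa)
  expect_equal(lens, c(chr1 = 8L, chr2 = 3L))
  tab <- tempfile(fileext = ".txt")
  writeLines(c("chr1\t8\t0\t0", "chr2\t3\t0\t0"), tab)  # .fai-like
  expect_equal(read_seq_lengths(tab), c(chr1 = 8, chr2 = 3))
})

test_that("gene/intron arithmetic on a toy annotation is exact", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tID=g1.t1.e1;Parent=g1.t1",
    "chr1\ttest\texon\t301\t400\t.\t+\t.\tID=g1.t1.e2;Parent=g1.t1"
  ), gff)
  classes <- classify_chromosomes(c(chr1 = 40e6, chr2 = 5e6))
  out <- gene_class_summary(gff, classes)
  macro <- out[out$klass == "macro", ]
  micro <- out[out$klass == "micro", ]
  expect_equal(macro$gene_count, 1)
  expect_equal(macro$mean_gene_length, 300)   # 1-based inclusive span
  expect_equal(macro$mean_intron_length, 100)
  expect_equal(macro$mean_exons_per_gene, 2)
  expect_equal(macro$genes_per_mb, 1 / 40)
  expect_equal(micro$gene_count, 0)           # empty class: means absent
  expect_true(is.na(micro$mean_gene_length))
})

test_that("longest isoform wins, ties by transcript id; overlapping exons are fatal", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t1000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t1000\t.\t+\t.\tID=g1.tA;Parent=g1",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tID=eA1;Parent=g1.tA",
    "chr1\ttest\tmRNA\t101\t1000\t.\t+\t.\tID=g1.tB;Parent=g1",
    "chr1\ttest\texon\t101\t300\t.\t+\t.\tID=eB1;Parent=g1.tB",
    "chr1\ttest\texon\t801\t1000\t.\t+\t.\tID=eB2;Parent=g1.tB"
  ), gff)
  classes <- classify_chromosomes(c(chr1 = 40e6))
  out <- gene_class_summary(gff, classes)
  macro <- out[out$klass == "macro", ]
  expect_equal(macro$mean_exons_per_gene, 2)      # tB (400 bp) beats tA (100 bp)
  expect_equal(macro$mean_intron_length, 500)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t101\t250\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\ttest\texon\t200\t400\t.\t+\t.\tID=e2;Parent=g1.t1"
  ), bad)
  expect_error(gene_class_summary(bad, classes), "overlapping exons.*g1.t1")
})

test_that("a simulated annotation with known density and intron ratios is recovered", {
  cfg <- sim_config(seed = 9)
  ann <- simulate_annotation(cfg, density_ratio = 2, intron_scale = 0.5,
                             n_genes = 2000)
  classes <- classify_chromosomes(ann$lengths)
  expect_equal(unname(attr(classes, "counts")), c(2L, 4L))
  out <- gene_class_summary(ann$genes, classes)
  dens_ratio <- out$genes_per_mb[out$klass == "micro"] /
    out$genes_per_mb[out$klass == "macro"]
  intr_ratio <- out$mean_intron_length[out$klass == "micro"] /
    out$mean_intron_length[out$klass == "macro"]
  expect_equal(sum(out$gene_count), sum(ann$truth$gene_counts))
  expect_lt(abs(dens_ratio / 2 - 1), 0.05)
  expect_lt(abs(intr_ratio / 0.5 - 1), 0.05)
  # and the realised truth the simulator recorded agrees with the summary
  expect_equal(dens_ratio, unname(ann$truth$density_ratio), tolerance = 1e-6)
  expect_equal(intr_ratio, unname(ann$truth$intron_ratio), tolerance = 1e-6)

  # null case: equal densities and intron scales
  ann0 <- simulate_annotation(cfg, density_ratio = 1, intron_scale = 1,
                              n_genes = 600)
  out0 <- gene_class_summary(ann0$genes, classify_chromosomes(ann0$lengths))
  expect_lt(abs(out0$genes_per_mb[2] / out0$genes_per_mb[1] - 1), 0.1)
  expect_lt(abs(out0$mean_intron_length[2] / out0$mean_intron_length[1] - 1), 0.1)

  # empty request yields a valid empty annotation
  ann_empty <- simulate_annotation(cfg, n_genes = 0)
  expect_equal(length(ann_empty$genes), 0)
  out_empty <- gene_class_summary(ann_empty$genes,
                                  classify_chromosomes(ann_empty$lengths))
  expect_equal(out_empty$gene_count, c(0L, 0L))
})
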