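test_that("feature_length handles plain, single-base and wrapping spans", {
  expect_equal(feature_length(1, 1563, 14778), 1563)
  expect_equal(feature_length(5, 5, 10), 1)
  expect_equal(feature_length(9, 2, 10), 4)
  expect_error(feature_length(0, 5, 10), "outside")
  expect_error(feature_length(9, 2, 10, circular = FALSE), "wrapping")
})

test_that("subsequence wraps through the origin and matches feature_length", {
  g <- mito_genome("g", "ACGT")
  expect_equal(subsequence(g, 2, 3), "CG")
  expect_equal(subsequence(g, 4, 1), "TA")
  expect_equal(subsequence(g, 1, 4), "ACGT")
  lin <- mito_genome("g", "ACGT", topology = "linear")
  expect_error(subsequence(lin, 4, 1), "linear")

  set.seed(11)
  g2 <- mito_genome("r", random_dna(200))
  for (k in 1:100) {
    s <- sample(200, 1)
    e <- sample(200, 1)
    expect_equal(nchar(subsequence(g2, s, e)), feature_length(s, e, 200))
  }
})

test_that("the genetic-code wrapper exposes the invertebrate table", {
  code <- genetic_code()
  expect_length(code$map, 64)
  expect_setequal(code$stop_codons, c("TAA", "TAG"))
  expect_true(all(c("ATT", "ATA", "TTG") %in% code$start_codons))
})

test_that("gap/overlap census reproduces the printed intergenic structure", {
  bx <- gap_overlap_census(bx_features, 14778L)
  expect_equal(nrow(bx), 36)
  expect_equal(sum(bx$length > 0), 9)
  expect_equal(max(bx$length), 1650)  # terminal non-coding region
  expect_equal(bx$length[bx$left_gene == "cox2"], -2)
  expect_equal(bx$length[bx$left_gene == "nad1"], -5)
  expect_equal(range(bx$length[bx$length > 0]), c(1, 1650))

  pv <- gap_overlap_census(pv_features, 21656L)
  expect_equal(sum(pv$length > 0), 24)
  expect_equal(sum(pv$length[pv$length > 0]), 8821)
  # the circular junction after the final tRNA
  expect_equal(pv$length[pv$left_gene == "trnE"], 11)
  expect_true(all(pv$length >= 0))
})

test_that("census is invariant under rotation of the origin", {
  rotate <- function(features, L, offset) {
    dplyr::mutate(features,
                  start = (start + offset - 1L) %% L + 1L,
                  end = (end + offset - 1L) %% L + 1L)
  }
  base <- sort(gap_overlap_census(bx_features, 14778L)$length)
  for (offset in c(1000L, 7000L, 13500L)) {
    rot <- rotate(bx_features, 14778L, offset)
    expect_equal(sort(gap_overlap_census(rot, 14778L)$length), base)
  }
})

test_that("partition accounting reconciles both fixtures exactly", {
  bx <- partition_report(bx_features, bx_sim$genome)
  expect_equal(bx$length[bx$partition == "pcg_coding"], 10182)
  expect_equal(bx$length[bx$partition == "rRNA"], 1648)
  expect_equal(bx$length[bx$partition == "tRNA"], 1214)
  expect_equal(bx$length[bx$partition == "NCR"], 1650)
  gb <- glance(bx)
  expect_true(gb$reconciled)
  expect_equal(gb$genome_length, 14778)
  expect_equal(gb$overlap_bp, 9)

  pv <- partition_report(pv_features, pv_sim$genome)
  expect_equal(pv$length[pv$partition == "pcg_coding"], 10002)
  expect_equal(pv$length[pv$partition == "intergenic"], 8821)
  expect_true(glance(pv)$reconciled)
})

test_that("an overlap-free synthetic genome partitions to exactly its length", {
  spec <- random_genome_spec(3, with_ncr = FALSE)
  sim <- generate_genome(spec, seed = 3)
  pr <- partition_report(sim$features, sim$genome, complete = FALSE)
  g <- glance(pr)
  expect_equal(g$residual, 0)
  expect_equal(g$overlap_bp, 0)
  ring <- pr$length[pr$partition %in% c("pcg_span", "rRNA", "tRNA")]
  expect_equal(sum(ring) + g$overlap_bp * 0 +
                 pr$length[pr$partition == "intergenic"],
               sim$genome$length)
})

test_that("feature tables round-trip through the TSV dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(bx_features, path)
  expect_equal(read_feature_tsv(path), bx_features)

  wrap <- tibble::tibble(gene = c("cox1", "trnM"), class = c("PCG", "tRNA"),
                         start = c(90L, 40L), end = c(20L, 95L),
                         strand = "+", start_codon = c("ATG", NA),
                         stop_codon = c("TA", NA), anticodon = NA_character_)
  write_feature_tsv(wrap, path)
  back <- read_feature_tsv(path)
  expect_equal(back$start, sort(wrap$start))
  expect_true(any(back$end < back$start))  # wrap preserved
})

test_that("feature tables round-trip through GFF3, with coordinate checks", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(bx_features, path, genome_id = "bx")
  back <- read_features_gff3(path)
  expect_equal(back[c("gene", "class", "start", "end", "strand",
                      "start_codon", "stop_codon")],
               bx_features[c("gene", "class", "start", "end", "strand",
                             "start_codon", "stop_codon")])

  bad <- c("##gff-version 3",
           "g\tsrc\tgene\t0\t10\t.\t+\t.\tID=cox1;gene_class=PCG")
  bad_path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(bad, bad_path)
  expect_error(read_features_gff3(bad_path), "coordinates")

  wrap <- dplyr::mutate(bx_features[1, ], start = 100L, end = 5L)
  expect_error(write_features_gff3(wrap, path), "wrapping")
})

test_that("written GFF3 is readable by an independent GFF3 parser", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(bx_features, path, genome_id = "bx")
  gr <- as.data.frame(rtracklayer::import(path))
  expect_equal(nrow(gr), nrow(bx_features))
  expect_equal(gr$start, bx_features$start)
  expect_equal(gr$end, bx_features$end)
  expect_equal(gr$gene_class, bx_features$class)
  expect_equal(gr$ID, bx_features$gene)
})

test_that("unknown gene names warn but are retained", {
  odd <- dplyr::mutate(bx_features[1, ], gene = "cox9")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(odd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tab <- read_feature_tsv(path), "cox9")
  expect_equal(tab$gene, "cox9")
})

test_that("genome FASTA I/O round-trips", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(bx_sim$genome, path)
  back <- read_genome_fasta(path)
  expect_equal(back$seq, bx_sim$genome$seq)
  expect_equal(back$id, bx_sim$genome$id)
})
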