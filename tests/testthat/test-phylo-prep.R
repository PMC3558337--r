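non_stop_codons <- local({
  code <- genetic_code()
  setdiff(names(code$map), code$stop_codons)
})

random_cds <- function(n_aa) {
  paste(sample(non_stop_codons, n_aa, replace = TRUE), collapse = "")
}

test_that("PCG translation strips terminators and counts residues", {
  expect_equal(translate_pcg(toy_features, toy_genome), "MK")
  bx_pcgs <- dplyr::filter(bx_sim$features, class == "PCG")
  nad4L <- translate_pcg(bx_pcgs[bx_pcgs$gene == "nad4L", ], bx_sim$genome)
  expect_equal(nchar(nad4L), (234 - 3) / 3)  # 77 residues
  atp6 <- translate_pcg(bx_pcgs[bx_pcgs$gene == "atp6", ], bx_sim$genome)
  expect_equal(nchar(atp6), (595 - 1) / 3)  # 198 residues, incomplete stop
  bad <- mito_genome("g", "ATGTAATAA")
  expect_error(translate_pcg(toy_features, bad), "internal stop")
})

test_that("pcg_sequences pairs every CDS with its translation", {
  tab <- pcg_sequences(bx_sim$features, bx_sim$genome)
  expect_equal(nrow(tab), 12)
  expect_equal(nchar(tab$cds), nchar(tab$protein) * 3)
  code <- genetic_code()
  for (i in seq_len(nrow(tab))) {
    expect_equal(mitocomp:::translate_seq(tab$cds[i], code), tab$protein[i])
  }
})

test_that("pairwise alignment scores equal the exhaustive oracle", {
  pw <- align_pairwise("MKV", "MV")
  expect_equal(nchar(pw$ax), nchar(pw$ay))
  expect_equal(pw$score, oracle_align_score("MKV", "MV"))

  set.seed(40)
  alphabet <- c("M", "K", "V", "L", "F")
  for (k in 1:30) {
    x <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE), collapse = "")
    y <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(align_pairwise(x, y)$score, oracle_align_score(x, y),
                 info = paste(x, y))
  }
  # a couple of longer asymmetric cases, and non-default scoring
  for (pair in list(c("MKVLFMKV", "MKFV"), c("KKKKKKKK", "KVK"))) {
    expect_equal(align_pairwise(pair[1], pair[2])$score,
                 oracle_align_score(pair[1], pair[2]))
    expect_equal(
      align_pairwise(pair[1], pair[2], match = 3, mismatch = -2,
                     gap_open = -6, gap_extend = -2)$score,
      oracle_align_score(pair[1], pair[2], match = 3, mismatch = -2,
                         gap_open = -6, gap_extend = -2))
  }
})

test_that("multiple alignment degaps to its inputs and is deterministic", {
  expect_error(align_proteins("MKV"), "at least two")
  same <- align_proteins(c(a = "MKVF", b = "MKVF", c = "MKVF"))
  expect_false(any(grepl("-", same$rows, fixed = TRUE)))

  set.seed(41)
  base <- strsplit("MKVLFWPGHQERTYMKVLFWPGHQERTY", "")[[1]]
  seqs <- purrr::map_chr(1:4, function(i) {
    mut <- base
    drop <- sample(length(mut), sample(0:3, 1))
    if (length(drop) > 0) mut <- mut[-drop]
    paste(mut, collapse = "")
  })
  names(seqs) <- paste0("t", 1:4)
  aln <- align_proteins(seqs)
  expect_equal(purrr::map_chr(aln$rows, ~ gsub("-", "", .x)),
               seqs[aln$taxa])
  expect_identical(align_proteins(seqs)$rows, aln$rows)
  expect_equal(length(unique(nchar(aln$rows))), 1L)
})

test_that("back-translation maps residues to codons and gaps to ---", {
  aln <- mitocomp:::new_alignment(c(a = "M-K", b = "MLK"), type = "AA")
  nt <- backtranslate(aln, c(a = "ATGAAA", b = "ATGTTAAAA"))
  expect_equal(nt$rows[["a"]], "ATG---AAA")
  expect_equal(nchar(nt$rows[["b"]]), 3 * nchar(aln$rows[["b"]]))
  expect_error(backtranslate(aln, c(a = "ATGCCC", b = "ATGTTAAAA")),
               "does not match")
})

test_that("back-translation round-trips random synthetic gene sets", {
  set.seed(42)
  for (k in 1:10) {
    cds <- purrr::map_chr(1:3, ~ random_cds(sample(20:40, 1)))
    names(cds) <- paste0("t", 1:3)
    code <- genetic_code()
    prots <- purrr::map_chr(cds, mitocomp:::translate_seq, code = code)
    aln <- align_proteins(prots)
    nt <- backtranslate(aln, cds)
    expect_equal(purrr::map_chr(nt$rows, ~ gsub("-", "", .x)), cds[nt$taxa])
    expect_equal(nchar(nt$rows[[1]]), 3 * nchar(aln$rows[[1]]))
  }
})

make_toy_supermatrix <- function() {
  a1 <- mitocomp:::new_alignment(c(t1 = "ATGAAA", t2 = "ATGTTT"),
                                 type = "NT", gene = "cox1")
  a2 <- mitocomp:::new_alignment(c(t1 = "GGGCCCTTT", t2 = "GGG---TTT"),
                                 type = "NT", gene = "atp6")
  concatenate_alignments(list(cox1 = a1, atp6 = a2))
}

test_that("concatenation tiles partitions in canonical order", {
  sm <- make_toy_supermatrix()
  expect_equal(sm$partitions$gene, c("atp6", "cox1"))  # alphabetical
  expect_equal(sm$partitions$start, c(1L, 10L))
  expect_equal(sm$partitions$end, c(9L, 15L))
  expect_equal(nchar(sm$rows[["t1"]]), 15L)
  expect_equal(glance(sm)$n_partitions, 2L)
  # spans tile without overlap
  expect_equal(sm$partitions$start[-1], utils::head(sm$partitions$end, -1) + 1L)

  a3 <- mitocomp:::new_alignment(c(t1 = "AAA", t3 = "TTT"),
                                 type = "NT", gene = "cob")
  expect_error(
    concatenate_alignments(
      list(cox1 = mitocomp:::new_alignment(c(t1 = "AAA"), type = "NT"),
           cob = a3)),
    "lacks taxa")
  filled <- concatenate_alignments(
    list(cox1 = mitocomp:::new_alignment(c(t1 = "AAA"), type = "NT"),
         cob = a3), fill_missing = TRUE)
  expect_equal(filled$rows[["t3"]], "TTT---")
})

test_that("third-position exclusion keeps exactly two thirds of columns", {
  sm <- make_toy_supermatrix()
  red <- exclude_third_positions(sm)
  expect_equal(nchar(red$rows[["t1"]]), 10L)
  expect_equal(red$partitions$end - red$partitions$start + 1L, c(6L, 4L))
  # kept + removed columns reconstruct the input
  keep <- unlist(purrr::map2(sm$partitions$start, sm$partitions$end,
                             function(s, e) {
                               idx <- seq(s, e)
                               idx[(idx - s) %% 3 != 2]
                             }))
  removed <- setdiff(seq_len(15), keep)
  orig <- strsplit(sm$rows[["t1"]], "")[[1]]
  expect_equal(paste(orig[keep], collapse = ""), red$rows[["t1"]])
  expect_equal(length(removed), 5L)

  tiny <- concatenate_alignments(list(
    g = mitocomp:::new_alignment(c(t1 = "ATG", t2 = "ATG"), type = "NT")))
  expect_equal(nchar(exclude_third_positions(tiny)$rows[["t1"]]), 2L)
})

test_that("per-gene exclusion commutes with concatenation", {
  a1 <- mitocomp:::new_alignment(c(t1 = "ATGAAA", t2 = "ATGTTT"),
                                 type = "NT", gene = "cox1")
  a2 <- mitocomp:::new_alignment(c(t1 = "GGGCCC", t2 = "GGG---"),
                                 type = "NT", gene = "cob")
  path_a <- exclude_third_positions(concatenate_alignments(
    list(cox1 = a1, cob = a2)))
  per_gene <- purrr::map(list(cob = a2, cox1 = a1), function(a) {
    sm1 <- concatenate_alignments(setNames(list(a), a$gene))
    red <- exclude_third_positions(sm1)
    mitocomp:::new_alignment(red$rows, type = "NT", gene = a$gene)
  })
  path_b <- concatenate_alignments(per_gene)
  expect_equal(path_a$rows, path_b$rows)
  expect_equal(path_a$partitions, path_b$partitions)
})

test_that("supermatrix writers emit parseable files", {
  sm <- make_toy_supermatrix()
  fa <- withr::local_tempfile(fileext = ".fa")
  phy <- withr::local_tempfile(fileext = ".phy")
  nex <- withr::local_tempfile(fileext = ".nex")
  part <- withr::local_tempfile(fileext = ".txt")
  write_alignment_fasta(sm, fa)
  write_phylip(sm, phy)
  write_nexus(sm, nex)
  write_raxml_partitions(sm, part)

  back <- read_alignment_fasta(fa, type = "NT")
  expect_equal(back$rows[back$taxa], sm$rows[sm$taxa])
  phy_lines <- readLines(phy)
  expect_match(phy_lines[1], "^\\s*2 15$")
  nex_lines <- readLines(nex)
  expect_match(nex_lines[1], "#NEXUS")
  expect_length(grep("CHARSET", nex_lines), 2)
  expect_equal(readLines(part),
               c("DNA, atp6 = 1-9", "DNA, cox1 = 10-15"))
})

test_that("a generated two-genome gene family aligns and back-translates", {
  bx <- pcg_sequences(bx_sim$features, bx_sim$genome)
  pv <- pcg_sequences(pv_sim$features, pv_sim$genome)
  gene <- "nad4L"  # the shortest gene keeps this quick
  prots <- c(Bx = bx$protein[bx$gene == gene], Pv = pv$protein[pv$gene == gene])
  cds <- c(Bx = bx$cds[bx$gene == gene], Pv = pv$cds[pv$gene == gene])
  aln <- align_proteins(prots)
  aln$gene <- gene
  nt <- backtranslate(aln, cds)
  expect_equal(nchar(nt$rows[[1]]), 3 * nchar(aln$rows[[1]]))
  sm <- concatenate_alignments(list(nad4L = nt))
  red <- exclude_third_positions(sm)
  expect_equal(nchar(red$rows[[1]]) * 3, nchar(sm$rows[[1]]) * 2)
})
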