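# Shared fixtures: packaged organization-table transcriptions and one
# generated genome per template (built once per test run).

extdata <- function(file) {
  system.file("extdata", file, package = "mitocomp")
}

bx_features <- read_feature_tsv(extdata("bxylophilus_table1.tsv"))
pv_features <- read_feature_tsv(extdata("pvulnus_table1.tsv"))
table3 <- utils::read.delim(extdata("codon_usage_table3.tsv"))
table2 <- utils::read.delim(extdata("composition_table2.tsv"))

bx_sim <- generate_genome(bx_genome_spec(), seed = 101)
pv_sim <- generate_genome(pv_genome_spec(), seed = 101)

# a tiny hand-built genome: one gene, ATG AAA TAA
toy_genome <- mito_genome("toy", "ATGAAATAA")
toy_features <- tibble::tibble(
  gene = "cox1", class = "PCG", start = 1L, end = 9L, strand = "+",
  start_codon = "ATG", stop_codon = "TAA", anticodon = NA_character_)

random_dna <- function(n, freq = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq),
        collapse = "")
}
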