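#' Circular genome object
#'
#' Container for a (usually circular) mitochondrial genome sequence. All
#' coordinates in the package are 1-based and inclusive, matching the
#' convention of published mitogenome organization tables.
#'
#' @param id Genome identifier (single string).
#' @param seq Nucleotide sequence as a single string over `A`, `C`, `G`, `T`,
#'   `N` (case-insensitive; stored uppercase).
#' @param topology `"circular"` (default) or `"linear"`.
#'
#' @return An object of class `mito_genome`: a list with elements `id`,
#'   `seq`, `length` and `topology`.
#' @examples
#' g <- mito_genome("toy", "ACGTACGT")
#' g$length
#' @export
mito_genome <- function(id, seq, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  chars <- seq_chars(seq)
  bad <- setdiff(unique(chars), c(BASES, "N"))
  if (length(bad) > 0) {
    abort(paste0("invalid residues in genome sequence: ",
                 paste(bad, collapse = ", ")))
  }
  if (nchar(seq) == 0L) abort("genome sequence must be non-empty")
  structure(
    list(id = id, seq = seq, length = nchar(seq), topology = topology),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' @export
format.mito_genome <- function(x, ...) {
  sprintf("<mito_genome %s, %d bp, %s>", x$id, x$length, x$topology)
}

#' Length of a feature span on a (circular) genome
#'
#' Spans are 1-based inclusive. On a circular genome a span with `end <
#' start` wraps through the origin and has length `(L - start + 1) + end`.
#' Vectorised over `start`/`end`.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param genome_length Genome length in bp (or a [mito_genome()]).
#' @param circular Allow origin-wrapping spans (`end < start`)?
#' @return Integer vector of span lengths in bp.
#' @examples
#' feature_length(1, 1563, 14778)   # 1563
#' feature_length(9, 2, 10)         # 4 (wraps)
#' @export
feature_length <- function(start, end, genome_length, circular = TRUE) {
  if (inherits(genome_length, "mito_genome")) {
    circular <- genome_length$topology == "circular"
    genome_length <- genome_length$length
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L | start > genome_length | end < 1L | end > genome_length)) {
    abort("coordinates outside [1, genome length]")
  }
  wraps <- end < start
  if (any(wraps) && !circular) {
    abort("origin-wrapping span on a linear genome")
  }
  ifelse(wraps, (genome_length - start + 1L) + end, end - start + 1L)
}

#' Extract a subsequence, wrapping through the origin when needed
#'
#' @param genome A [mito_genome()].
#' @param start,end 1-based inclusive coordinates; `end < start` wraps through
#'   the origin on circular genomes.
#' @return Nucleotide string in 5' to 3' order.
#' @examples
#' subsequence(mito_genome("g", "ACGT"), 4, 1)  # "TA"
#' @export
subsequence <- function(genome, start, end) {
  stopifnot(inherits(genome, "mito_genome"))
  L <- genome$length
  start <- as.integer(start)
  end <- as.integer(end)
  if (start < 1L || start > L || end < 1L || end > L) {
    abort("coordinates outside [1, genome length]")
  }
  if (end >= start) {
    substr(genome$seq, start, end)
  } else {
    if (genome$topology != "circular") {
      abort("origin-wrapping subsequence requested on a linear genome")
    }
    paste0(substr(genome$seq, start, L), substr(genome$seq, 1L, end))
  }
}

# Positions covered by a (possibly wrapping) span, in 5'->3' order.
span_positions <- function(start, end, genome_length) {
  if (end >= start) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' Feature sequence, strand-aware
#'
#' Extracts the span of one feature row; minus-strand features are
#' reverse-complemented so the result always reads 5' to 3' in the sense of
#' the encoded gene.
#'
#' @param feature One-row data frame with `start`, `end`, `strand`.
#' @param genome A [mito_genome()].
#' @return Nucleotide string.
#' @export
feature_seq <- function(feature, genome) {
  s <- subsequence(genome, feature$start[[1]], feature$end[[1]])
  if (identical(feature$strand[[1]], "-")) revcomp(s) else s
}

# ---- genetic code -----------------------------------------------------------

#' Mitochondrial genetic code
#'
#' Wraps an NCBI translation table (via Biostrings) together with the start-
#' and stop-codon sets used for mitochondrial gene verification. The default
#' is table 5, the invertebrate mitochondrial code, with the start-codon set
#' observed across chromadorean nematode mitogenomes.
#'
#' @param table_id NCBI genetic code table id (default `5`).
#' @param start_codons Codons accepted as initiation codons.
#' @return An object of class `mito_code`: list with `table_id`, `map`
#'   (named character of 64 codon -> one-letter amino acid, stops as `"*"`),
#'   `start_codons`, `stop_codons`.
#' @examples
#' code <- genetic_code()
#' code$map[["TGA"]]  # "W" under the invertebrate mitochondrial code
#' @export
genetic_code <- function(table_id = 5,
                         start_codons = c("ATT", "ATA", "ATG",
                                          "TTG", "TTA", "GTG")) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(map) == 64L)
  structure(
    list(table_id = table_id,
         map = map,
         start_codons = toupper(start_codons),
         stop_codons = names(map)[map == "*"]),
    class = "mito_code"
  )
}

#' @export
print.mito_code <- function(x, ...) {
  cat(sprintf("<mito_code> NCBI table %s; stops: %s; starts: %s\n",
              x$table_id, paste(x$stop_codons, collapse = "/"),
              paste(x$start_codons, collapse = "/")))
  invisible(x)
}

# Translate an in-frame nucleotide string; codons containing N translate to X.
translate_seq <- function(seq, code) {
  cods <- codons_of(toupper(seq))
  aa <- unname(code$map[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ---- canonical gene vocabulary ---------------------------------------------

#' Canonical mitochondrial gene names
#'
#' The 36-gene complement of chromadorean nematode mtDNA: 12 protein-coding
#' genes (no `atp8`), 22 tRNAs (leucine and serine isoacceptors
#' disambiguated as L1/L2 and S1/S2) and 2 rRNAs.
#'
#' @return Named character vector of gene name -> class.
#' @export
canonical_genes <- function() {
  pcg <- c("atp6", "cob", "cox1", "cox2", "cox3",
           "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
  trna <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                          "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
                          "T", "V", "W", "Y"))
  rrna <- c("rrnS", "rrnL")
  c(setNames(rep("PCG", 12), pcg),
    setNames(rep("tRNA", 22), trna),
    setNames(rep("rRNA", 2), rrna))
}

# Validate a feature table; returns the table (tibble) sorted by start.
# complete = TRUE additionally requires exactly the 36 canonical genes.
validate_features <- function(features, genome_length = NULL,
                              complete = FALSE) {
  features <- as_tibble(features)
  needed <- c("gene", "class", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(features$class %in% c("PCG", "tRNA", "rRNA", "NCR"))) {
    abort("feature class must be one of PCG, tRNA, rRNA, NCR")
  }
  if (!is.null(genome_length)) {
    if (any(features$start < 1L | features$start > genome_length |
              features$end < 1L | features$end > genome_length)) {
      abort("feature coordinates outside [1, genome length]")
    }
  }
  if (complete) {
    canon <- canonical_genes()
    genes <- features$gene[features$class != "NCR"]
    if (anyDuplicated(genes)) {
      abort(paste0("duplicated gene names: ",
                   paste(unique(genes[duplicated(genes)]), collapse = ", ")))
    }
    absent <- setdiff(names(canon), genes)
    if (length(absent) > 0) {
      abort(paste0("incomplete 36-gene table; missing: ",
                   paste(absent, collapse = ", ")))
    }
    extra <- setdiff(genes, names(canon))
    if (length(extra) > 0) {
      warn(paste0("unknown gene names retained: ",
                  paste(extra, collapse = ", ")))
    }
  }
  arrange(features, .data$start, .data$end)
}
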