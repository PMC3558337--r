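# Feature-table and sequence I/O.
#
# Two interchange formats are supported for annotations:
#   * a tab-separated dialect mirroring published mitogenome organization
#     tables: gene, class, start, end, strand, start_codon, stop_codon
#     (+ optional anticodon), 1-based inclusive coordinates;
#   * GFF3 (1-based inclusive per the standard) with gene_class, start_codon,
#     stop_codon and anticodon carried as attributes. GFF3 cannot represent
#     origin-wrapping spans (end < start); the TSV dialect can.

FEATURE_COLS <- c("gene", "class", "start", "end", "strand",
                  "start_codon", "stop_codon", "anticodon")

empty_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)

#' Read a feature table (TSV dialect)
#'
#' @param path Path to a tab-separated feature table with header columns
#'   `gene class start end strand [start_codon stop_codon [anticodon]]`.
#' @return A tibble with one row per feature, sorted by `start`.
#' @export
read_feature_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = c("NA", ""))
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  bad <- which(is.na(raw$start) | is.na(raw$end))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinates at line(s) ",
                 paste(bad + 1L, collapse = ", "), " of ", path))
  }
  out <- as_tibble(raw[FEATURE_COLS])
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$start_codon <- empty_to_na(toupper(out$start_codon))
  out$stop_codon <- empty_to_na(toupper(out$stop_codon))
  out$anticodon <- empty_to_na(toupper(out$anticodon))
  canon <- canonical_genes()
  unknown <- setdiff(out$gene[out$class != "NCR"], names(canon))
  if (length(unknown) > 0) {
    warn(paste0("unknown gene name(s) in ", basename(path), ": ",
                paste(unknown, collapse = ", ")))
  }
  validate_features(out)
}

#' Write a feature table (TSV dialect)
#'
#' @param features Feature tibble (see [read_feature_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  features <- validate_features(features)
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  utils::write.table(features[FEATURE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# ---- GFF3 dialect -----------------------------------------------------------

GFF3_TYPES <- c(PCG = "gene", tRNA = "tRNA", rRNA = "rRNA",
                NCR = "sequence_feature")

#' Write features as GFF3
#'
#' Coordinates are written 1-based inclusive per the GFF3 standard; the
#' feature class and any codon/anticodon annotations travel as attributes
#' (`gene_class`, `start_codon`, `stop_codon`, `anticodon`). Origin-wrapping
#' spans cannot be represented in GFF3 and raise an error; use the TSV
#' dialect for those.
#'
#' @param features Feature tibble.
#' @param path Output path.
#' @param genome_id Sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, genome_id = "genome") {
  features <- validate_features(features)
  if (any(features$end < features$start)) {
    abort("GFF3 cannot represent origin-wrapping features (end < start)")
  }
  attr_str <- pmap(features, function(gene, class, start, end, strand,
                                      start_codon = NA, stop_codon = NA,
                                      anticodon = NA, ...) {
    parts <- c(paste0("ID=", gene), paste0("Name=", gene),
               paste0("gene_class=", class))
    if (!is.na(start_codon)) parts <- c(parts, paste0("start_codon=", start_codon))
    if (!is.na(stop_codon)) parts <- c(parts, paste0("stop_codon=", stop_codon))
    if (!is.na(anticodon)) parts <- c(parts, paste0("anticodon=", anticodon))
    paste(parts, collapse = ";")
  })
  lines <- c("##gff-version 3",
             sprintf("%s\tmitocomp\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     genome_id, unname(GFF3_TYPES[features$class]),
                     features$start, features$end, features$strand,
                     unlist(attr_str)))
  writeLines(lines, path)
  invisible(path)
}

gff3_attr <- function(attrs, key) {
  hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  has <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
  out[has] <- sub(paste0("^;?", key, "="), "", unlist(hit))
  out
}

#' Read features from GFF3
#'
#' Counterpart of [write_features_gff3()]; accepts any GFF3 whose records
#' carry a `gene_class` (or recognisable `type`) and an `ID`/`Name`.
#'
#' @param path Path to a GFF3 file.
#' @return Feature tibble sorted by start.
#' @export
read_features_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(lengths(rows) != 9L)
  if (length(bad) > 0) {
    abort(paste0("malformed GFF3 record at line(s) ",
                 paste(lineno[bad], collapse = ", "), " of ", path))
  }
  m <- do.call(rbind, rows)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < 1L)
  if (length(bad) > 0) {
    abort(paste0("invalid GFF3 coordinates (must be positive integers) at line(s) ",
                 paste(lineno[bad], collapse = ", "), " of ", path))
  }
  attrs <- m[, 9]
  klass <- gff3_attr(attrs, "gene_class")
  type_fallback <- names(GFF3_TYPES)[match(m[, 3], GFF3_TYPES)]
  klass <- ifelse(is.na(klass), type_fallback, klass)
  if (anyNA(klass)) abort("GFF3 records missing gene_class attribute")
  gene <- gff3_attr(attrs, "ID")
  gene <- ifelse(is.na(gene), gff3_attr(attrs, "Name"), gene)
  out <- tibble(
    gene = gene, class = klass, start = start, end = end,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "+"),
    start_codon = gff3_attr(attrs, "start_codon"),
    stop_codon = gff3_attr(attrs, "stop_codon"),
    anticodon = gff3_attr(attrs, "anticodon")
  )
  canon <- canonical_genes()
  unknown <- setdiff(out$gene[out$class != "NCR"], names(canon))
  if (length(unknown) > 0) {
    warn(paste0("unknown gene name(s) in ", basename(path), ": ",
                paste(unknown, collapse = ", ")))
  }
  validate_features(out)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a single-record genome FASTA
#'
#' @param path Path to a FASTA file holding one nucleotide record.
#' @param topology Genome topology.
#' @return A [mito_genome()].
#' @export
read_genome_fasta <- function(path, topology = "circular") {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    abort(paste0("expected a single-record genome FASTA, found ",
                 length(set), " records"))
  }
  id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  mito_genome(id, as.character(set[[1]]), topology = topology)
}

#' Write a genome to FASTA
#'
#' @param genome A [mito_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "mito_genome"))
  set <- Biostrings::DNAStringSet(setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
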