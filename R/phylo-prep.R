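# Preparation of phylogenetic input matrices: PCG translation, protein
# alignment, back-translation to codon alignments, concatenation with
# per-gene partitions, and third-codon-position exclusion.

# Strip the terminal stop from a CDS: 1 or 2 trailing bases for incomplete
# stops (span not divisible by 3), 3 for a terminal complete stop codon.
strip_stop <- function(cds, code) {
  len <- nchar(cds)
  m <- len %% 3L
  if (m != 0L) return(substr(cds, 1L, len - m))
  last <- substr(cds, len - 2L, len)
  if (last %in% code$stop_codons) substr(cds, 1L, len - 3L) else cds
}

#' Translate a protein-coding gene feature
#'
#' Extracts the (strand-aware) coding span, removes the complete or
#' incomplete termination codon (incomplete stops contribute no residue),
#' and translates under the given code. Any internal stop raises an error.
#'
#' @param feature One-row PCG feature.
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Amino-acid string of length `(span - stop length) / 3`.
#' @export
translate_pcg <- function(feature, genome, code = genetic_code()) {
  stopifnot(identical(feature$class[[1]], "PCG"))
  cds <- strip_stop(feature_seq(feature, genome), code)
  aa <- translate_seq(cds, code)
  if (grepl("*", aa, fixed = TRUE)) {
    abort(paste0("internal stop codon in ", feature$gene[[1]]))
  }
  aa
}

#' Stop-stripped CDS and protein of every PCG
#'
#' @param features Feature tibble.
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Tibble `gene`, `cds` (stop-stripped), `protein`.
#' @export
pcg_sequences <- function(features, genome, code = genetic_code()) {
  pcgs <- filter(validate_features(features, genome$length),
                 .data$class == "PCG")
  if (nrow(pcgs) == 0L) abort("no PCG features in table")
  tibble(
    gene = pcgs$gene,
    cds = map_chr(seq_len(nrow(pcgs)), function(i)
      strip_stop(feature_seq(pcgs[i, ], genome), code)),
    protein = map_chr(seq_len(nrow(pcgs)), function(i)
      translate_pcg(pcgs[i, ], genome, code))
  )
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column becomes the residue's source codon; each gap becomes
#' `---`. The degapped protein rows must equal the translations of the
#' supplied coding sequences (terminal stops are stripped first).
#'
#' @param alignment A `mito_alignment` of type `"AA"` (from
#'   [align_proteins()] or imported).
#' @param cds Named character vector of coding sequences, one per taxon.
#' @param code A [genetic_code()].
#' @return A `mito_alignment` of type `"NT"` with 3x the columns.
#' @export
backtranslate <- function(alignment, cds, code = genetic_code()) {
  stopifnot(inherits(alignment, "mito_alignment"),
            identical(alignment$type, "AA"))
  cds <- unlist(cds)
  missing <- setdiff(alignment$taxa, names(cds))
  if (length(missing) > 0) {
    abort(paste0("no CDS for taxa: ", paste(missing, collapse = ", ")))
  }
  rows <- map_chr(alignment$taxa, function(tx) {
    row <- alignment$rows[[tx]]
    clean <- strip_stop(toupper(cds[[tx]]), code)
    if (!identical(translate_seq(clean, code), degap(row))) {
      abort(paste0("CDS translation does not match alignment row for ", tx))
    }
    cods <- codons_of(clean)
    chars <- seq_chars(row)
    out <- character(length(chars))
    ci <- 1L
    for (p in seq_along(chars)) {
      if (chars[p] == "-") {
        out[p] <- "---"
      } else {
        out[p] <- cods[ci]
        ci <- ci + 1L
      }
    }
    paste(out, collapse = "")
  })
  new_alignment(setNames(rows, alignment$taxa), type = "NT",
                gene = alignment$gene)
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Genes concatenate in canonical (alphabetical) order of their names; the
#' emitted partition table records the column span of each gene so the
#' concatenation order is immaterial downstream.
#'
#' @param alignments Named list of `mito_alignment`s (all the same type).
#' @param fill_missing Fill taxa absent from a gene with all-gap rows
#'   instead of erroring?
#' @return Object of class `mito_supermatrix`: list with `taxa`, `rows`,
#'   `partitions` (tibble `gene`, `start`, `end`), `type`.
#' @export
concatenate_alignments <- function(alignments, fill_missing = FALSE) {
  stopifnot(length(alignments) >= 1L)
  if (is.null(names(alignments))) {
    names(alignments) <- map_chr(alignments, function(a)
      a$gene %||% NA_character_)
  }
  alignments <- alignments[order(names(alignments))]
  types <- unique(map_chr(alignments, "type"))
  if (length(types) != 1L) abort("alignments mix NT and AA types")
  taxa <- sort(unique(unlist(map(alignments, "taxa"))))
  parts <- list()
  offset <- 0L
  rows <- setNames(rep("", length(taxa)), taxa)
  for (g in names(alignments)) {
    a <- alignments[[g]]
    w <- nchar(a$rows[[1]])
    absent <- setdiff(taxa, a$taxa)
    if (length(absent) > 0 && !fill_missing) {
      abort(paste0("gene ", g, " lacks taxa ",
                   paste(absent, collapse = ", "),
                   " (set fill_missing = TRUE to pad with gaps)"))
    }
    for (tx in taxa) {
      piece <- if (tx %in% a$taxa) a$rows[[tx]] else strrep("-", w)
      rows[[tx]] <- paste0(rows[[tx]], piece)
    }
    parts[[g]] <- tibble(gene = g, start = offset + 1L, end = offset + w)
    offset <- offset + w
  }
  structure(list(taxa = taxa, rows = rows, partitions = bind_rows(parts),
                 type = types),
            class = "mito_supermatrix")
}

#' @export
print.mito_supermatrix <- function(x, ...) {
  cat(sprintf("<mito_supermatrix> %s, %d taxa x %d columns, %d partitions\n",
              x$type, length(x$taxa), nchar(x$rows[[1]]),
              nrow(x$partitions)))
  invisible(x)
}

#' @method tidy mito_supermatrix
#' @export
tidy.mito_supermatrix <- function(x, ...) x$partitions

#' @method glance mito_supermatrix
#' @export
glance.mito_supermatrix <- function(x, ...) {
  tibble(type = x$type, n_taxa = length(x$taxa),
         n_columns = nchar(x$rows[[1]]), n_partitions = nrow(x$partitions))
}

#' Drop third codon positions from a codon supermatrix
#'
#' Retains positions 1-2 of every codon within every partition; the result
#' has exactly 2/3 of the input columns and an updated partition table.
#'
#' @param sm A `mito_supermatrix` of type `"NT"` whose partitions all have
#'   lengths divisible by 3.
#' @return A `mito_supermatrix`.
#' @export
exclude_third_positions <- function(sm) {
  stopifnot(inherits(sm, "mito_supermatrix"), identical(sm$type, "NT"))
  widths <- sm$partitions$end - sm$partitions$start + 1L
  if (any(widths %% 3L != 0L)) {
    abort("partition column counts not divisible by 3")
  }
  keep <- unlist(map2(sm$partitions$start, sm$partitions$end, function(s, e) {
    idx <- seq.int(s, e)
    idx[(idx - s) %% 3L != 2L]
  }))
  rows <- map_chr(sm$rows, function(r) {
    paste(seq_chars(r)[keep], collapse = "")
  })
  new_w <- widths / 3L * 2L
  ends <- cumsum(new_w)
  parts <- tibble(gene = sm$partitions$gene,
                  start = c(1L, utils::head(ends, -1L) + 1L), end = ends)
  structure(list(taxa = sm$taxa, rows = setNames(rows, sm$taxa),
                 partitions = parts, type = "NT"),
            class = "mito_supermatrix")
}

# ---- writers ----------------------------------------------------------------

#' Write an alignment or supermatrix to FASTA
#'
#' @param x A `mito_alignment` or `mito_supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(x, path) {
  writeLines(paste0(">", x$taxa, "\n", unname(x$rows[x$taxa])), path)
  invisible(path)
}

#' Read a FASTA alignment
#'
#' @param path Path to an aligned FASTA (equal-length gapped rows).
#' @param type `"AA"` or `"NT"`.
#' @param gene Optional gene label.
#' @return A `mito_alignment`.
#' @export
read_alignment_fasta <- function(path, type = c("AA", "NT"),
                                 gene = NA_character_) {
  type <- match.arg(type)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("not a FASTA file")
  idx <- cumsum(hdr)
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- vapply(strsplit(taxa, "\\s+"), `[[`, "", 1L)
  rows <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  rows <- toupper(gsub("\\s", "", rows))
  if (length(unique(nchar(rows))) != 1L) {
    abort("FASTA rows have unequal lengths; not an alignment")
  }
  new_alignment(setNames(unname(rows), taxa), type = type, gene = gene)
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' @param sm A `mito_supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  stopifnot(inherits(sm, "mito_supermatrix"))
  lines <- c(sprintf(" %d %d", length(sm$taxa), nchar(sm$rows[[1]])),
             paste0(format(sm$taxa, width = max(nchar(sm$taxa)) + 2L),
                    unname(sm$rows[sm$taxa])))
  writeLines(lines, path)
  invisible(path)
}

#' Write a supermatrix as NEXUS with charset blocks
#'
#' @param sm A `mito_supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(sm, path) {
  stopifnot(inherits(sm, "mito_supermatrix"))
  datatype <- if (identical(sm$type, "NT")) "DNA" else "PROTEIN"
  lines <- c(
    "#NEXUS", "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
            nchar(sm$rows[[1]])),
    sprintf("  FORMAT DATATYPE=%s GAP=- MISSING=?;", datatype),
    "  MATRIX",
    paste0("    ", format(sm$taxa, width = max(nchar(sm$taxa)) + 2L),
           unname(sm$rows[sm$taxa])),
    "  ;", "END;", "",
    "BEGIN SETS;",
    sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene,
            sm$partitions$start, sm$partitions$end),
    "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Write a RAxML-style plain-text partition file
#'
#' @param sm A `mito_supermatrix`.
#' @param path Output path.
#' @param model Substitution model label per partition line.
#' @return `path`, invisibly.
#' @export
write_raxml_partitions <- function(sm, path, model = NULL) {
  stopifnot(inherits(sm, "mito_supermatrix"))
  model <- model %||% if (identical(sm$type, "NT")) "DNA" else "LG"
  writeLines(sprintf("%s, %s = %d-%d", model, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}
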