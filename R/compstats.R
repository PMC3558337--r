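# Nucleotide composition and codon-usage statistics.

composition_row <- function(seq, partition = "sequence", digits = 1) {
  chars <- seq_chars(toupper(seq))
  chars <- chars[chars != "N"]
  n <- length(chars)
  if (n == 0L) abort("empty (or all-N) sequence")
  counts <- table(factor(chars, levels = BASES))
  pct <- as.numeric(counts) / n * 100
  names(pct) <- BASES
  tibble(partition = partition, length = nchar(seq),
         A = round_half_up(pct[["A"]], digits),
         C = round_half_up(pct[["C"]], digits),
         T = round_half_up(pct[["T"]], digits),
         G = round_half_up(pct[["G"]], digits),
         AT = round_half_up(pct[["A"]] + pct[["T"]], digits))
}

#' Base composition of a sequence
#'
#' Percentages are computed over non-N residues (N counts in the reported
#' length but in no numerator or denominator) and rounded half-up at
#' `digits` decimals. `AT` is rounded from the unrounded sum of A and T.
#'
#' @param seq Nucleotide string or a [mito_genome()].
#' @param partition Label for the output row.
#' @param digits Reporting precision (default 1 decimal).
#' @return One-row tibble of class `mito_composition`: `partition`,
#'   `length`, `A`, `C`, `T`, `G`, `AT` (percent).
#' @examples
#' base_composition("TTTT")$AT  # 100
#' @export
base_composition <- function(seq, partition = "sequence", digits = 1) {
  if (inherits(seq, "mito_genome")) seq <- seq$seq
  out <- composition_row(seq, partition, digits)
  class(out) <- c("mito_composition", class(out))
  out
}

# Concatenated coding sequence of all PCGs, termination codons excluded,
# in genome order. include_stops = TRUE retains complete stop codons
# (incomplete stops are never whole codons and are always dropped).
pcg_coding_concat <- function(features, genome, include_stops = FALSE) {
  pcgs <- filter(validate_features(features, genome$length),
                 .data$class == "PCG")
  if (nrow(pcgs) == 0L) abort("no PCG features in table")
  parts <- map_chr(seq_len(nrow(pcgs)), function(i) {
    s <- feature_seq(pcgs[i, ], genome)
    len <- nchar(s)
    drop <- stop_len_for_span(len)
    if (include_stops && drop == 3L) s else substr(s, 1L, len - drop)
  })
  paste(parts, collapse = "")
}

#' Partitioned nucleotide composition of a mitogenome
#'
#' Reproduces the standard composition table: the entire sequence; the
#' concatenated protein-coding sequence with termination codons excluded;
#' that same sequence split by codon position; concatenated rRNA;
#' concatenated tRNA; and the non-coding-region features. Overlapping
#' nucleotides count once per feature (each gene contributes its full
#' span), so per-class lengths may double-count shared bases; the genome
#' length reconciliation lives in [partition_report()] instead.
#'
#' @param features Complete feature tibble.
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @param digits Reporting precision.
#' @return Tibble of class `mito_composition`, one row per partition
#'   (`entire`, `pcg`, `pcg_pos1..3`, `rRNA`, `tRNA`, `NCR`).
#' @export
partitioned_composition <- function(features, genome, code = genetic_code(),
                                    digits = 1) {
  stopifnot(inherits(genome, "mito_genome"))
  features <- validate_features(features, genome$length)
  coding <- pcg_coding_concat(features, genome)
  chars <- seq_chars(coding)
  pos <- (seq_along(chars) - 1L) %% 3L + 1L
  class_concat <- function(klass) {
    rows <- filter(features, .data$class == klass)
    paste(map_chr(seq_len(nrow(rows)),
                  function(i) feature_seq(rows[i, ], genome)),
          collapse = "")
  }
  rows <- list(
    composition_row(genome$seq, "entire", digits),
    composition_row(coding, "pcg", digits),
    composition_row(paste(chars[pos == 1L], collapse = ""), "pcg_pos1", digits),
    composition_row(paste(chars[pos == 2L], collapse = ""), "pcg_pos2", digits),
    composition_row(paste(chars[pos == 3L], collapse = ""), "pcg_pos3", digits)
  )
  for (klass in c("rRNA", "tRNA", "NCR")) {
    s <- class_concat(klass)
    if (nchar(s) > 0) rows <- c(rows, list(composition_row(s, klass, digits)))
  }
  out <- bind_rows(rows)
  attr(out, "genome_id") <- genome$id
  class(out) <- c("mito_composition", class(out))
  out
}

#' Codon usage over the protein-coding genes
#'
#' Counts every codon of every PCG with termination codons excluded (the
#' convention under which coding length divided by 3 equals the codon
#' total). All 64 codons appear in the output; stop codons therefore have
#' count 0 unless `include_stops = TRUE`.
#'
#' @param features Feature tibble with 12 PCGs.
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @param include_stops Count complete termination codons too?
#' @param digits Reporting precision for the percent column (default 2).
#' @return Tibble of class `mito_codon_usage` with `codon`, `aa`, `count`,
#'   `percent`; attribute `total_codons`.
#' @export
codon_usage <- function(features, genome, code = genetic_code(),
                        include_stops = FALSE, digits = 2) {
  coding <- pcg_coding_concat(features, genome, include_stops = include_stops)
  if (nchar(coding) %% 3L != 0L) {
    abort("concatenated coding length not divisible by 3 after stop exclusion")
  }
  cods <- codons_of(coding)
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  counts <- table(factor(cods, levels = all_codons()))
  codon_usage_from_counts(
    tibble(codon = names(counts), count = as.integer(counts)),
    code = code, digits = digits)
}

#' Build a codon-usage table from raw counts
#'
#' Recomputes amino-acid assignments and percentages from a plain
#' codon/count table (for example a published codon-usage table).
#'
#' @param counts Data frame with columns `codon` and `count`.
#' @param code A [genetic_code()].
#' @param digits Reporting precision for `percent`.
#' @return Tibble of class `mito_codon_usage` (see [codon_usage()]).
#' @export
codon_usage_from_counts <- function(counts, code = genetic_code(),
                                    digits = 2) {
  counts <- as_tibble(counts)
  stopifnot(all(c("codon", "count") %in% names(counts)))
  full <- tibble(codon = all_codons()) |>
    left_join(select(counts, "codon", "count"), by = "codon") |>
    mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count)),
           aa = unname(genetic_code(code$table_id)$map[.data$codon]))
  total <- sum(full$count)
  out <- full |>
    mutate(percent = round_half_up(.data$count / total * 100, digits)) |>
    select("codon", "aa", "count", "percent")
  attr(out, "total_codons") <- total
  class(out) <- c("mito_codon_usage", class(out))
  out
}

#' Most frequently used codons
#'
#' @param usage A `mito_codon_usage` table.
#' @param k Number of codons to report.
#' @return Tibble of the `k` most frequent codons (ties broken by count,
#'   then alphabetically), columns `codon`, `aa`, `count`, `percent`;
#'   attribute `combined_percent` holds their summed unrounded frequency,
#'   rounded half-up at 1 decimal.
#' @export
top_codons <- function(usage, k = 3) {
  stopifnot(inherits(usage, "mito_codon_usage"), k >= 1)
  total <- attr(usage, "total_codons")
  top <- usage |>
    arrange(desc(.data$count), .data$codon) |>
    utils::head(k)
  attr(top, "combined_percent") <-
    round_half_up(sum(top$count) / total * 100, 1)
  top
}
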