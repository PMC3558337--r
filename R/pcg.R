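# Protein-coding gene verification and de novo ORF scanning under the
# invertebrate mitochondrial genetic code.

#' Verify start and stop codons of annotated protein-coding genes
#'
#' For each PCG feature the start codon is read off the first triplet of the
#' span and the termination is classified from the span length modulo 3:
#' a span divisible by 3 must end in a complete stop codon; remainder 1
#' requires a trailing `T` and remainder 2 a trailing `TA` (the incomplete
#' stop codons completed to `TAA` by polyadenylation of the transcript).
#' Internal stop codons, non-stop final triplets and non-`T`/`TA` trailing
#' bases are reported in the `violations` column rather than raised.
#'
#' @param features Feature tibble; only `class == "PCG"` rows are used.
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Tibble with one row per PCG: `gene`, `length`, `start_codon`,
#'   `stop_codon`, `stop_kind` (`complete`/`incomplete`), `start_known`
#'   (start codon in the configured start set), `spacing_next` (signed bp to
#'   the next ring feature; negative = overlap) and `violations`.
#' @export
infer_codons <- function(features, genome, code = genetic_code()) {
  stopifnot(inherits(genome, "mito_genome"))
  features <- validate_features(features, genome$length)
  pcgs <- filter(features, .data$class == "PCG")
  if (nrow(pcgs) == 0L) abort("no PCG features in table")

  spacing <- tryCatch({
    census <- gap_overlap_census(features, genome)
    setNames(census$length, census$left_gene)
  }, error = function(e) setNames(integer(0), character(0)))

  rows <- map(seq_len(nrow(pcgs)), function(i) {
    f <- pcgs[i, ]
    s <- feature_seq(f, genome)
    len <- nchar(s)
    m <- len %% 3L
    start_codon <- substr(s, 1L, 3L)
    violations <- character(0)
    if (m == 0L) {
      stop_codon <- substr(s, len - 2L, len)
      stop_kind <- "complete"
      if (!stop_codon %in% code$stop_codons) {
        violations <- c(violations,
                        paste0("final triplet ", stop_codon, " is not a stop codon"))
      }
      coding <- substr(s, 1L, len - 3L)
    } else if (m == 1L) {
      stop_codon <- substr(s, len, len)
      stop_kind <- "incomplete"
      if (stop_codon != "T") {
        violations <- c(violations,
                        paste0("trailing base ", stop_codon,
                               " cannot form an incomplete stop"))
      }
      coding <- substr(s, 1L, len - 1L)
    } else {
      stop_codon <- substr(s, len - 1L, len)
      stop_kind <- "incomplete"
      if (stop_codon != "TA") {
        violations <- c(violations,
                        paste0("trailing bases ", stop_codon,
                               " cannot form an incomplete stop"))
      }
      coding <- substr(s, 1L, len - 2L)
    }
    aa <- translate_seq(coding, code)
    n_internal <- sum(seq_chars(aa) == "*")
    if (n_internal > 0) {
      violations <- c(violations,
                      paste0(n_internal, " internal stop codon(s)"))
    }
    tibble(
      gene = f$gene, length = len,
      start_codon = start_codon, stop_codon = stop_codon,
      stop_kind = stop_kind,
      start_known = start_codon %in% code$start_codons,
      spacing_next = unname(spacing[f$gene])[1] %||% NA_integer_,
      violations = if (length(violations) == 0) NA_character_
                   else paste(violations, collapse = "; ")
    )
  })
  bind_rows(rows)
}

#' Start-codon usage histogram over the 12 protein-coding genes
#'
#' @inheritParams infer_codons
#' @return Tibble `start_codon`, `n`, `genes` sorted by decreasing count.
#' @export
start_codon_histogram <- function(features, genome, code = genetic_code()) {
  inf <- infer_codons(features, genome, code)
  inf |>
    group_by(.data$start_codon) |>
    summarise(n = n(), genes = paste(sort(.data$gene), collapse = ","),
              .groups = "drop") |>
    arrange(desc(.data$n), .data$start_codon)
}

#' Scan a genome for open reading frames
#'
#' Finds maximal reading frames on the given strand: within each frame,
#' stretches between stop codons are reported from their first codon drawn
#' from the configured start-codon set through the terminating stop. A frame
#' running off the end of the scanned sequence is reported only when the
#' trailing bases form a permitted incomplete stop (`T` or `TA`).
#'
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @param min_aa Minimum protein length (residues, stop excluded).
#' @param start_codons Start-codon set; defaults to the code's set.
#' @param both_strands Also scan the reverse complement?
#' @return Tibble of candidates sorted by `start`: `start`, `end`, `strand`,
#'   `frame` (0-2 relative to the scan origin), `start_codon`, `stop_kind`
#'   (`TAA`, `TAG`, `T`, `TA`), `aa_length`.
#' @export
scan_orfs <- function(genome, code = genetic_code(), min_aa = 50,
                      start_codons = NULL, both_strands = FALSE) {
  stopifnot(inherits(genome, "mito_genome"), min_aa >= 1)
  start_codons <- toupper(start_codons %||% code$start_codons)
  fwd <- scan_orfs_strand(genome$seq, code, min_aa, start_codons)
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (both_strands) {
    L <- genome$length
    rev <- scan_orfs_strand(revcomp(genome$seq), code, min_aa, start_codons)
    if (nrow(rev) > 0) {
      rev <- mutate(rev, strand = "-",
                    start0 = L - .data$end + 1L, end = L - .data$start + 1L,
                    start = .data$start0) |> select(-"start0")
      out <- bind_rows(fwd, rev)
    }
  }
  arrange(out, .data$start, .data$end)
}

scan_orfs_strand <- function(seq, code, min_aa, start_codons) {
  L <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 1L) next
    cods <- substring(seq, f + seq(1L, by = 3L, length.out = n_cod),
                      f + seq(3L, by = 3L, length.out = n_cod))
    leftover <- substr(seq, f + 3L * n_cod + 1L, L)
    is_stop <- cods %in% code$stop_codons
    seg_start <- c(1L, which(is_stop) + 1L)
    seg_stop <- c(which(is_stop), NA_integer_)  # codon index of terminator
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]
      term <- seg_stop[k]
      b <- if (is.na(term)) n_cod else term - 1L
      if (b < a) next
      idx <- which(cods[a:b] %in% start_codons)
      if (length(idx) == 0L) next
      first <- a + idx[1] - 1L
      aa_len <- b - first + 1L
      if (aa_len < min_aa) next
      if (!is.na(term)) {
        stop_kind <- cods[term]
        end_bp <- f + 3L * term
      } else if (leftover %in% c("T", "TA")) {
        stop_kind <- leftover
        end_bp <- L
      } else {
        next
      }
      out[[length(out) + 1L]] <- tibble(
        start = f + 3L * (first - 1L) + 1L, end = end_bp, frame = f,
        start_codon = cods[first], stop_kind = stop_kind, aa_length = aa_len)
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(0), end = integer(0), frame = integer(0),
                  start_codon = character(0), stop_kind = character(0),
                  aa_length = integer(0)))
  }
  bind_rows(out)
}
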