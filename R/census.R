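# Intergenic/overlap census and the partition accounting that reconciles a
# 36-gene feature table with the genome length.

# Stop-codon length implied by a PCG span: complete stops occupy 3 bp, the
# incomplete, polyadenylation-completed forms occupy 1 ("T") or 2 ("TA") bp.
stop_len_for_span <- function(span) {
  m <- span %% 3L
  ifelse(m == 0L, 3L, m)
}

#' Census of intergenic gaps and gene overlaps around the circle
#'
#' Walks consecutive pairs of the 36-gene ring (non-coding-region features
#' are excluded from the ring; their spans simply contribute to the flanking
#' intergenic interval) and reports the signed spacing between neighbours:
#' positive = intergenic sequence, negative = overlap, zero = abutting.
#' On circular genomes the junction between the last and first gene is
#' included.
#'
#' @param features Feature tibble (1-based inclusive coordinates).
#' @param genome A [mito_genome()] or genome length in bp.
#' @param circular Include the origin junction? Defaults to the genome
#'   topology.
#' @return Tibble with `left_gene`, `right_gene`, `length` (signed bp).
#' @examples
#' \dontrun{
#' census <- gap_overlap_census(bx_features, bx_genome)
#' sum(census$length[census$length > 0])  # total intergenic sequence
#' }
#' @export
gap_overlap_census <- function(features, genome, circular = NULL) {
  if (inherits(genome, "mito_genome")) {
    L <- genome$length
    circular <- circular %||% (genome$topology == "circular")
  } else {
    L <- as.integer(genome)
    circular <- circular %||% TRUE
  }
  ring <- validate_features(filter(features, .data$class != "NCR"), L)
  if (nrow(ring) == 0L) abort("no ring features for a census")
  if (nrow(ring) == 1L) {
    if (!circular) {
      return(tibble(left_gene = character(0), right_gene = character(0),
                    length = integer(0)))
    }
    span <- feature_length(ring$start, ring$end, L)
    return(tibble(left_gene = ring$gene, right_gene = ring$gene,
                  length = L - span))
  }
  if (anyDuplicated(ring[c("start", "end")])) {
    abort("duplicate feature coordinates in ring")
  }
  n <- nrow(ring)
  inner <- tibble(
    left_gene = ring$gene[-n],
    right_gene = ring$gene[-1],
    length = ring$start[-1] - ring$end[-n] - 1L
  )
  if (!circular) return(inner)
  last_end <- ring$end[n]
  junction <- if (last_end < ring$start[n]) {
    # last feature wraps the origin; spacing is purely linear
    ring$start[1] - last_end - 1L
  } else {
    (L - last_end) + (ring$start[1] - 1L)
  }
  bind_rows(inner, tibble(left_gene = ring$gene[n],
                          right_gene = ring$gene[1],
                          length = as.integer(junction)))
}

#' Partition length accounting for a complete mitogenome
#'
#' Reports the per-class partition lengths used in composition tables:
#' entire genome; protein-coding span total and coding total with
#' termination codons excluded (3 bp per complete stop, 1 or 2 bp per
#' incomplete stop); rRNA and tRNA totals; explicit non-coding-region
#' features; and total intergenic sequence (positive census entries, which
#' subsume the NCR spans). It also checks the reconciliation identity
#' `sum(gene spans) + sum(gaps) - sum(overlaps) = genome length`; failure is
#' reported as a diagnostic column in [glance()], never silently.
#'
#' @param features Complete 36-gene feature tibble.
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()] (currently used only for interface
#'   symmetry; stop lengths follow the span arithmetic).
#' @param complete Require the full 36-gene complement? Disable for partial
#'   or synthetic layouts; the reconciliation identity is checked either
#'   way.
#' @return A tibble of class `mito_partitions` with columns `partition`,
#'   `length`; attributes carry the reconciliation diagnostics (see
#'   [glance.mito_partitions()]).
#' @export
partition_report <- function(features, genome, code = genetic_code(),
                             complete = TRUE) {
  stopifnot(inherits(genome, "mito_genome"))
  L <- genome$length
  features <- validate_features(features, L, complete = complete)
  spans <- feature_length(features$start, features$end, L)
  by_class <- split(spans, features$class)
  pcg_span <- sum(by_class$PCG %||% 0L)
  pcg_coding <- sum((by_class$PCG %||% integer(0)) -
                      stop_len_for_span(by_class$PCG %||% integer(0)))
  census <- gap_overlap_census(features, genome)
  gaps <- sum(census$length[census$length > 0])
  overlaps <- -sum(census$length[census$length < 0])
  ring_total <- sum(spans[features$class != "NCR"])
  residual <- ring_total + gaps - overlaps - L
  out <- tibble(
    partition = c("entire", "pcg_span", "pcg_coding", "rRNA", "tRNA",
                  "NCR", "intergenic"),
    length = c(L, pcg_span, pcg_coding, sum(by_class$rRNA %||% 0L),
               sum(by_class$tRNA %||% 0L), sum(by_class$NCR %||% 0L), gaps)
  )
  attr(out, "genome_id") <- genome$id
  attr(out, "genome_length") <- L
  attr(out, "n_gaps") <- sum(census$length > 0)
  attr(out, "n_overlaps") <- sum(census$length < 0)
  attr(out, "overlap_bp") <- overlaps
  attr(out, "residual") <- residual
  attr(out, "reconciled") <- residual == 0L
  class(out) <- c("mito_partitions", class(out))
  if (residual != 0L) {
    warn(sprintf(
      "partition reconciliation failed for %s: spans + gaps - overlaps differ from genome length by %d bp",
      genome$id, residual))
  }
  out
}

#' @describeIn partition_report One-row summary with the reconciliation
#'   diagnostics: genome length, gap/overlap counts, residual and whether the
#'   identity holds exactly.
#' @param x A `mito_partitions` object.
#' @param ... Unused.
#' @method glance mito_partitions
#' @export
glance.mito_partitions <- function(x, ...) {
  tibble(
    genome_id = attr(x, "genome_id"),
    genome_length = attr(x, "genome_length"),
    n_gaps = attr(x, "n_gaps"),
    n_overlaps = attr(x, "n_overlaps"),
    overlap_bp = attr(x, "overlap_bp"),
    residual = attr(x, "residual"),
    reconciled = attr(x, "reconciled")
  )
}
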