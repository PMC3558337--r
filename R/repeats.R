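# Tandem-repeat discovery in non-coding (control) regions.
#
# Mitogenome-scale sequences (<= ~25 kb) need no suffix structures: for each
# candidate period the sequence is compared against itself at that lag
# (vectorised), and candidate anchors are extended window by window against
# a running consensus.

window_chars <- function(chars, start, p) chars[seq.int(start, start + p - 1L)]

# Majority consensus from a 4 x p count profile; ties keep the current
# consensus base (greedy, left-to-right update), making results
# deterministic.
profile_consensus <- function(profile, current) {
  for (j in seq_along(current)) {
    col <- profile[, j]
    best <- BASES[which.max(col)]
    if (col[[best]] > col[[current[j]]]) current[j] <- best
  }
  current
}

extend_array <- function(chars, i, p, L, max_mm) {
  profile <- matrix(0L, nrow = 4L, ncol = p,
                    dimnames = list(BASES, NULL))
  consensus <- window_chars(chars, i, p)
  keep <- consensus %in% BASES
  profile[cbind(match(consensus[keep], BASES), which(keep))] <- 1L
  copies <- 1L
  repeat {
    nxt <- i + copies * p
    if (nxt + p - 1L > L) break
    w <- window_chars(chars, nxt, p)
    mm <- sum(w != consensus)
    if (mm > max_mm) break
    keep <- w %in% BASES
    idx <- cbind(match(w[keep], BASES), which(keep))
    profile[idx] <- profile[idx] + 1L
    consensus <- profile_consensus(profile, consensus)
    copies <- copies + 1L
  }
  list(copies = copies, consensus = consensus)
}

#' Find tandemly repeated units in a sequence
#'
#' For each candidate period, successive period-length windows are compared
#' to a running majority consensus by Hamming distance; maximal runs with at
#' least `min_copies` copies, each within `max_mismatch_per_copy` of the
#' consensus, are reported. Reports contained inside a larger report of the
#' same (or a harmonically related) period are suppressed in favour of the
#' maximal one.
#'
#' @param seq Nucleotide string.
#' @param min_unit,max_unit Period range searched (bp); `max_unit` defaults
#'   to `floor(length/min_copies)`.
#' @param min_copies Minimum copy number (>= 2).
#' @param max_mismatch_per_copy Mismatch budget of each copy against the
#'   consensus.
#' @return Tibble ordered by `start` then descending `unit_length`:
#'   `start` (1-based within `seq`), `unit_length`, `copies`, `consensus`,
#'   `total_mismatches`, `per_copy_mismatches` (list-column).
#' @examples
#' unit <- strrep("ACGTT", 4)            # 20-bp unit
#' seq <- paste0("AAAA", strrep(unit, 3), "GGGG")
#' find_tandem_repeats(seq, min_unit = 10, min_copies = 3)
#' @export
find_tandem_repeats <- function(seq, min_unit = 20, max_unit = NULL,
                                min_copies = 2, max_mismatch_per_copy = 0) {
  seq <- toupper(seq)
  L <- nchar(seq)
  min_unit <- as.integer(min_unit)
  min_copies <- as.integer(min_copies)
  if (min_unit < 2L) abort("min_unit must be >= 2")
  if (min_copies < 2L) abort("min_copies must be >= 2")
  if (!is.null(max_unit) && max_unit < min_unit) {
    abort("degenerate period range: max_unit < min_unit")
  }
  max_unit <- as.integer(min(max_unit %||% Inf, L %/% min_copies))
  empty <- tibble(start = integer(0), unit_length = integer(0),
                  copies = integer(0), consensus = character(0),
                  total_mismatches = integer(0),
                  per_copy_mismatches = list())
  if (max_unit < min_unit) return(empty)
  chars <- seq_chars(seq)
  found <- list()
  for (p in seq.int(min_unit, max_unit)) {
    n_anchor <- L - 2L * p + 1L
    if (n_anchor < 1L) next
    eq <- chars[seq_len(L - p)] == chars[seq.int(p + 1L, L)]
    cs <- c(0L, cumsum(eq))
    # mismatches between window at i and the window one period later
    adj_mm <- p - (cs[seq.int(p + 1L, p + n_anchor)] - cs[seq_len(n_anchor)])
    anchors <- which(adj_mm <= 2L * max_mismatch_per_copy)
    claimed_until <- 0L
    k <- 1L
    while (k <= length(anchors)) {
      i <- anchors[k]
      if (i <= claimed_until) {
        k <- k + 1L
        next
      }
      # candidate phases: every anchor within one period of the first one;
      # keep the extension with most copies, then fewest mismatches, then
      # the leftmost start (guards against off-phase anchors that match by
      # chance just upstream of a planted array)
      phase <- anchors[anchors >= i & anchors < i + p]
      best <- NULL
      for (j in phase) {
        ext <- extend_array(chars, j, p, L, max_mismatch_per_copy)
        if (ext$copies < min_copies) next
        copy_starts <- j + p * (seq_len(ext$copies) - 1L)
        per_copy <- map_int(copy_starts, function(s) {
          sum(window_chars(chars, s, p) != ext$consensus)
        })
        cand <- list(start = j, copies = ext$copies,
                     consensus = ext$consensus, per_copy = per_copy,
                     total = sum(per_copy))
        if (is.null(best) || cand$copies > best$copies ||
              (cand$copies == best$copies && cand$total < best$total)) {
          best <- cand
        }
      }
      if (is.null(best)) {
        k <- k + 1L
        next
      }
      found[[length(found) + 1L]] <- tibble(
        start = best$start, unit_length = p, copies = best$copies,
        consensus = paste(best$consensus, collapse = ""),
        total_mismatches = best$total,
        per_copy_mismatches = list(best$per_copy))
      claimed_until <- best$start + best$copies * p - 1L
      k <- k + 1L
    }
  }
  if (length(found) == 0L) return(empty)
  reports <- bind_rows(found) |>
    mutate(end = .data$start + .data$copies * .data$unit_length - 1L,
           span = .data$copies * .data$unit_length)
  # maximal-first: longer array span, then smaller unit, then leftmost
  ord <- order(-reports$span, reports$unit_length, reports$start)
  reports <- reports[ord, ]
  keep <- rep(TRUE, nrow(reports))
  for (i in seq_len(nrow(reports))) {
    if (!keep[i]) next
    ri <- reports[i, ]
    for (j in seq_len(nrow(reports))) {
      if (j == i || !keep[j]) next
      rj <- reports[j, ]
      harmonic <- rj$unit_length %% ri$unit_length == 0L ||
        ri$unit_length %% rj$unit_length == 0L
      if (harmonic && rj$start >= ri$start && rj$end <= ri$end &&
            rj$span <= ri$span) {
        keep[j] <- FALSE
      }
    }
  }
  reports[keep, ] |>
    arrange(.data$start, desc(.data$unit_length)) |>
    select("start", "unit_length", "copies", "consensus",
           "total_mismatches", "per_copy_mismatches")
}

#' Tandem-repeat and composition report over non-coding intervals
#'
#' Enumerates every non-coding interval of the genome (positive entries of
#' [gap_overlap_census()], which subsume explicit NCR features) at least
#' `min_length` bp long, and runs [find_tandem_repeats()] plus an A+T
#' summary on each.
#'
#' @param features Feature tibble.
#' @param genome A [mito_genome()].
#' @param min_length Interval floor in bp (default 100).
#' @param ... Passed on to [find_tandem_repeats()].
#' @return Tibble with one row per interval: `left_gene`, `right_gene`,
#'   `start`, `end`, `length`, `AT` (percent), `n_repeats` and a `repeats`
#'   list-column of per-interval repeat tables.
#' @export
ncr_report <- function(features, genome, min_length = 100, ...) {
  stopifnot(inherits(genome, "mito_genome"))
  L <- genome$length
  ring <- validate_features(filter(features, .data$class != "NCR"), L)
  census <- gap_overlap_census(features, genome)
  rows <- list()
  for (k in seq_len(nrow(census))) {
    if (census$length[k] < min_length) next
    left <- census$left_gene[k]
    i <- match(left, ring$gene)
    gap_start <- ring$end[i] %% L + 1L
    gap_end <- (gap_start + census$length[k] - 2L) %% L + 1L
    s <- subsequence(genome, gap_start, gap_end)
    reps <- find_tandem_repeats(s, ...)
    rows[[length(rows) + 1L]] <- tibble(
      left_gene = left, right_gene = census$right_gene[k],
      start = gap_start, end = gap_end, length = census$length[k],
      AT = base_composition(s)$AT,
      n_repeats = nrow(reps), repeats = list(reps))
  }
  if (length(rows) == 0L) {
    return(tibble(left_gene = character(0), right_gene = character(0),
                  start = integer(0), end = integer(0), length = integer(0),
                  AT = numeric(0), n_repeats = integer(0), repeats = list()))
  }
  bind_rows(rows)
}
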