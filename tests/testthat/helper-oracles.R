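# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: alignments are scored by exhaustive
# enumeration, tandem arrays by brute-force scanning, and adjacency sets
# by a plain double loop.

# All global alignments of two character vectors, as pairs of gapped
# strings (exponential; for tiny inputs only).
enumerate_alignments <- function(xs, ys) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(list(list(ax = "", ay = "")))
    out <- list()
    if (i > 0 && j > 0) {
      for (al in rec(i - 1, j - 1)) {
        out[[length(out) + 1]] <- list(ax = paste0(al$ax, xs[i]),
                                       ay = paste0(al$ay, ys[j]))
      }
    }
    if (i > 0) {
      for (al in rec(i - 1, j)) {
        out[[length(out) + 1]] <- list(ax = paste0(al$ax, xs[i]),
                                       ay = paste0(al$ay, "-"))
      }
    }
    if (j > 0) {
      for (al in rec(i, j - 1)) {
        out[[length(out) + 1]] <- list(ax = paste0(al$ax, "-"),
                                       ay = paste0(al$ay, ys[j]))
      }
    }
    out
  }
  rec(length(xs), length(ys))
}

# Score a gapped alignment: substitutions column-wise; each maximal gap
# run costs gap_open + run_length * gap_extend.
score_gapped <- function(ax, ay, match, mismatch, gap_open, gap_extend) {
  a <- strsplit(ax, "")[[1]]
  b <- strsplit(ay, "")[[1]]
  sub_cols <- a != "-" & b != "-"
  s <- sum(ifelse(a[sub_cols] == b[sub_cols], match, mismatch))
  for (row in list(a, b)) {
    r <- rle(row == "-")
    runs <- r$lengths[r$values]
    s <- s + sum(gap_open + runs * gap_extend)
  }
  s
}

oracle_align_score <- function(x, y, match = 2, mismatch = -1,
                               gap_open = -4, gap_extend = -1) {
  als <- enumerate_alignments(strsplit(x, "")[[1]], strsplit(y, "")[[1]])
  max(vapply(als, function(al)
    score_gapped(al$ax, al$ay, match, mismatch, gap_open, gap_extend),
    numeric(1)))
}

# Does an exact tandem array (unit in [min_unit, max_unit], >= min_copies
# identical copies) exist anywhere in seq? Plain brute force.
brute_force_exact_tandem <- function(seq, min_unit, max_unit, min_copies) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  for (p in min_unit:min(max_unit, L %/% min_copies)) {
    lag_eq <- chars[seq_len(L - p)] == chars[seq.int(p + 1, L)]
    cs <- c(0, cumsum(lag_eq))
    need <- (min_copies - 1) * p
    for (i in seq_len(L - min_copies * p + 1)) {
      if (cs[i + need] - cs[i] == need) return(TRUE)
    }
  }
  FALSE
}

# Directed adjacency intersection of two circular orders, computed with a
# plain loop over positions.
oracle_shared_adjacencies <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- length(a)
  shared <- character(0)
  for (i in seq_len(n)) {
    x <- a[i]
    y <- a[if (i == n) 1 else i + 1]
    j <- which(b == x)
    succ <- b[if (j == length(b)) 1 else j + 1]
    if (identical(succ, y)) shared <- c(shared, paste(x, y))
  }
  shared
}

# The two published circular orders (non-coding regions dropped), and the
# adjacency intersection worked out by hand from the organization table
# before the comparison code was written.
BX_ORDER <- c("cox1", "trnC", "trnM", "trnD", "trnG", "cox2", "trnH",
              "rrnL", "nad3", "nad5", "trnA", "trnP", "trnV", "nad6",
              "nad4L", "trnW", "trnE", "rrnS", "trnS2", "trnY", "nad1",
              "atp6", "trnK", "trnL2", "trnS1", "nad2", "trnI", "trnR",
              "trnQ", "trnF", "cob", "trnL1", "cox3", "trnN", "trnT",
              "nad4")
PV_ORDER <- c("cox1", "trnH", "trnL1", "rrnL", "nad3", "cob", "rrnS",
              "trnY", "trnW", "nad1", "trnL2", "nad2", "trnI", "cox3",
              "trnN", "trnG", "trnK", "trnC", "trnF", "nad6", "nad4L",
              "cox2", "nad4", "trnD", "trnM", "trnT", "trnS1", "atp6",
              "nad5", "trnS2", "trnQ", "trnA", "trnP", "trnR", "trnV",
              "trnE")
BX_PV_SHARED <- c("rrnL nad3", "trnA trnP", "nad6 nad4L", "nad2 trnI",
                  "cox3 trnN")
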