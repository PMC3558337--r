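# Deterministic global alignment: Needleman-Wunsch with affine gaps
# (Gotoh) extended to multiple sequences by center-star progressive
# merging. Intentionally simple — it exists so that codon-alignment
# preparation is testable without an external aligner; externally produced
# FASTA alignments can be imported and are treated identically downstream.

#' Pairwise global alignment (affine gaps)
#'
#' A gap of length k costs `gap_open + k * gap_extend` (both negative).
#' Traceback ties resolve deterministically: diagonal, then gap in the
#' second sequence, then gap in the first.
#'
#' @param x,y Sequences (single strings, any residue alphabet).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List with `ax`, `ay` (gapped strings) and `score`.
#' @export
align_pairwise <- function(x, y, match = 2, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  if (nchar(x) == 0L || nchar(y) == 0L) abort("empty sequence")
  xs <- seq_chars(x)
  ys <- seq_chars(y)
  m <- length(xs)
  n <- length(ys)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, m + 1L, n + 1L)
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1L, 1L] <- gap_open + i * gap_extend
  for (j in seq_len(n)) Y[1L, j + 1L] <- gap_open + j * gap_extend
  for (i in seq_len(m)) {
    sub <- ifelse(xs[i] == ys, match, mismatch)
    for (j in seq_len(n)) {
      best_prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- best_prev + sub[j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open + gap_extend,
                               X[i, j + 1L] + gap_extend,
                               Y[i, j + 1L] + gap_open + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open + gap_extend,
                               Y[i + 1L, j] + gap_extend,
                               X[i + 1L, j] + gap_open + gap_extend)
    }
  }
  score <- max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])
  # traceback
  ax <- ay <- character(0)
  i <- m; j <- n
  state <- which.max(c(M[m + 1L, n + 1L], X[m + 1L, n + 1L],
                       Y[m + 1L, n + 1L]))
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == 1L) {  # M: consumed xs[i], ys[j]
      ax <- c(xs[i], ax); ay <- c(ys[j], ay)
      s <- ifelse(xs[i] == ys[j], match, mismatch)
      prev <- M[i + 1L, j + 1L] - s
      i <- i - 1L; j <- j - 1L
      state <- if (abs(M[i + 1L, j + 1L] - prev) < tol) 1L
               else if (abs(X[i + 1L, j + 1L] - prev) < tol) 2L else 3L
    } else if (state == 2L) {  # X: xs[i] over gap
      ax <- c(xs[i], ax); ay <- c("-", ay)
      v <- X[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (abs(X[i + 1L, j + 1L] + gap_extend - v) < tol) 2L
               else if (abs(M[i + 1L, j + 1L] + gap_open + gap_extend - v) < tol) 1L
               else 3L
    } else {  # Y: gap over ys[j]
      ax <- c("-", ax); ay <- c(ys[j], ay)
      v <- Y[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (abs(Y[i + 1L, j + 1L] + gap_extend - v) < tol) 3L
               else if (abs(M[i + 1L, j + 1L] + gap_open + gap_extend - v) < tol) 1L
               else 2L
    }
  }
  list(ax = paste(ax, collapse = ""), ay = paste(ay, collapse = ""),
       score = score)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

new_alignment <- function(rows, type = c("AA", "NT"), gene = NA_character_) {
  type <- match.arg(type)
  widths <- nchar(rows)
  stopifnot(length(unique(widths)) == 1L)
  structure(list(taxa = names(rows), rows = rows, type = type, gene = gene),
            class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat(sprintf("<mito_alignment> %s, %d taxa x %d columns%s\n", x$type,
              length(x$rows), nchar(x$rows[[1]]),
              if (is.na(x$gene)) "" else paste0(" (", x$gene, ")")))
  invisible(x)
}

#' @method tidy mito_alignment
#' @export
tidy.mito_alignment <- function(x, ...) {
  tibble(taxon = x$taxa, sequence = unname(x$rows))
}

#' @method glance mito_alignment
#' @export
glance.mito_alignment <- function(x, ...) {
  tibble(type = x$type, gene = x$gene, n_taxa = length(x$rows),
         n_columns = nchar(x$rows[[1]]))
}

#' Multiple protein alignment by center-star progressive merging
#'
#' The center sequence is the one with the maximal summed pairwise
#' alignment score against all others (ties: first in input order); each
#' remaining sequence is aligned to the center and merged under the
#' "once a gap, always a gap" rule. Deterministic throughout.
#'
#' @param seqs Named character vector/list of >= 2 ungapped sequences.
#' @param ... Scoring parameters for [align_pairwise()].
#' @return A `mito_alignment` (type `"AA"`); every row degaps to its input.
#' @export
align_proteins <- function(seqs, ...) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) < 2L) abort("need at least two sequences")
  if (any(nchar(seqs) == 0L)) abort("empty sequence")
  k <- length(seqs)
  if (k == 2L) {
    pw <- align_pairwise(seqs[[1]], seqs[[2]], ...)
    return(new_alignment(setNames(c(pw$ax, pw$ay), names(seqs))))
  }
  scores <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      scores[i, j] <- scores[j, i] <- align_pairwise(seqs[[i]], seqs[[j]], ...)$score
    }
  }
  center <- which.max(rowSums(scores))
  master <- matrix(seq_chars(seqs[[center]]), nrow = 1)
  rownames(master) <- names(seqs)[center]
  for (idx in setdiff(seq_len(k), center)) {
    pw <- align_pairwise(seqs[[center]], seqs[[idx]], ...)
    master <- merge_into_master(master, seq_chars(pw$ax), seq_chars(pw$ay),
                                names(seqs)[idx])
  }
  rows <- apply(master, 1, paste, collapse = "")
  new_alignment(rows[names(seqs)])
}

# Merge a (center, new) pairwise alignment into the master alignment whose
# first row is the (gapped) center. Columns where only one side has a
# center gap get gap columns inserted on the other side.
merge_into_master <- function(master, ac, as_new, new_name) {
  mc <- master[1, ]  # center row of master, with gaps
  out_master <- list()
  out_new <- character(0)
  i <- 1L; j <- 1L
  nm <- length(mc); np <- length(ac)
  gap_col <- rep("-", nrow(master))
  while (i <= nm || j <= np) {
    if (i <= nm && mc[i] == "-" && (j > np || ac[j] != "-")) {
      out_master[[length(out_master) + 1L]] <- master[, i]
      out_new <- c(out_new, "-")
      i <- i + 1L
    } else if (j <= np && ac[j] == "-" && (i > nm || mc[i] != "-")) {
      out_master[[length(out_master) + 1L]] <- gap_col
      out_new <- c(out_new, as_new[j])
      j <- j + 1L
    } else {
      # both sides consume the same center residue (or both are gaps)
      out_master[[length(out_master) + 1L]] <- master[, i]
      out_new <- c(out_new, as_new[j])
      i <- i + 1L
      j <- j + 1L
    }
  }
  m <- do.call(cbind, out_master)
  m <- rbind(m, out_new)
  rownames(m) <- c(rownames(master), new_name)
  m
}
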