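# Secondary-structure folding of nematode mitochondrial tRNAs.
#
# The structural model is the one shared by almost all chromadorean
# mitochondrial tRNAs: an acceptor stem of 7 pairs, a DHU stem of 4 pairs
# with its loop, an anticodon stem of 5 pairs with a 7-nt loop, and a TV
# replacement loop standing in for the TPsiC arm + variable loop. The two
# serine isoacceptors instead lack the DHU arm (an unpaired replacement
# loop) but carry a TPsiC stem-loop. Pairing is Watson-Crick plus G.U;
# scoring is by paired-base count (no thermodynamic energies) because at
# these lengths (<= 75 nt) exhaustive placement search is trivial.

#' Nematode mitochondrial tRNA structural model
#'
#' Ranges not fixed by the structural description (loop sizes) default to
#' standard conventions and are overridable here.
#'
#' @param acceptor_pairs,dhu_pairs,ac_pairs Stem sizes in nucleotide pairs.
#' @param dhu_loop,tv_loop,tpsic_loop,dhu_replacement Loop length ranges
#'   (nt), each `c(min, max)`.
#' @param ac_loop Anticodon loop length (nt); the anticodon is its central
#'   triplet.
#' @param tpsic_pairs TPsiC stem size range (pairs) for the serine variant.
#' @param max_mismatch_per_stem Mismatch budget per stem.
#' @param allow_gu Count G.U as a valid pair?
#' @return An object of class `mito_trna_model`.
#' @export
trna_model <- function(acceptor_pairs = 7L, dhu_pairs = 4L,
                       dhu_loop = c(4L, 9L), ac_pairs = 5L, ac_loop = 7L,
                       tv_loop = c(4L, 12L), tpsic_pairs = c(3L, 5L),
                       tpsic_loop = c(3L, 8L), dhu_replacement = c(2L, 12L),
                       max_mismatch_per_stem = 1L, allow_gu = TRUE) {
  stopifnot(ac_loop >= 3L, dhu_loop[1] <= dhu_loop[2],
            tv_loop[1] <= tv_loop[2], tpsic_loop[1] <= tpsic_loop[2])
  structure(
    list(acceptor_pairs = as.integer(acceptor_pairs),
         dhu_pairs = as.integer(dhu_pairs),
         dhu_loop = as.integer(dhu_loop),
         ac_pairs = as.integer(ac_pairs),
         ac_loop = as.integer(ac_loop),
         tv_loop = as.integer(tv_loop),
         tpsic_pairs = as.integer(tpsic_pairs),
         tpsic_loop = as.integer(tpsic_loop),
         dhu_replacement = as.integer(dhu_replacement),
         max_mismatch_per_stem = as.integer(max_mismatch_per_stem),
         allow_gu = isTRUE(allow_gu)),
    class = "mito_trna_model")
}

default_trna_model <- function() trna_model()

# Arm layout of the TV-replacement-loop variant for loop sizes (d, t);
# total length L = 14 + 8 + d + 10 + ac_loop + t with default stem sizes.
layout_tv <- function(L, d, t, model) {
  a <- model$acceptor_pairs; dh <- model$dhu_pairs
  ac <- model$ac_pairs; al <- model$ac_loop
  acc5 <- c(1L, a)
  dhu5 <- c(a + 1L, a + dh)
  dloop <- c(a + dh + 1L, a + dh + d)
  dhu3 <- c(dloop[2] + 1L, dloop[2] + dh)
  acs5 <- c(dhu3[2] + 1L, dhu3[2] + ac)
  aloop <- c(acs5[2] + 1L, acs5[2] + al)
  acs3 <- c(aloop[2] + 1L, aloop[2] + ac)
  tv <- c(acs3[2] + 1L, acs3[2] + t)
  acc3 <- c(tv[2] + 1L, tv[2] + a)
  stopifnot(acc3[2] == L)
  mid <- (al - 3L) %/% 2L
  list(variant = "TV",
       arms = tibble(
         arm = c("acceptor5", "dhu5", "dhu_loop", "dhu3", "ac_stem5",
                 "ac_loop", "ac_stem3", "tv_loop", "acceptor3"),
         start = c(acc5[1], dhu5[1], dloop[1], dhu3[1], acs5[1], aloop[1],
                   acs3[1], tv[1], acc3[1]),
         end = c(acc5[2], dhu5[2], dloop[2], dhu3[2], acs5[2], aloop[2],
                 acs3[2], tv[2], acc3[2])),
       pairs = rbind(
         cbind(seq.int(acc5[1], acc5[2]), seq.int(L, acc3[1]), 1L),
         cbind(seq.int(dhu5[1], dhu5[2]), seq.int(dhu3[2], dhu3[1]), 2L),
         cbind(seq.int(acs5[1], acs5[2]), seq.int(acs3[2], acs3[1]), 3L)),
       stems = c("acceptor", "dhu", "anticodon"),
       anticodon_pos = seq.int(aloop[1] + mid + 1L, aloop[1] + mid + 3L),
       d = d, tie = c(t, d))
}

# Arm layout of the DHU-less serine variant with TPsiC stem-loop:
# L = 2*a + r + 2*ac + ac_loop + 2*s + l.
layout_ser <- function(L, r, s, l, model) {
  a <- model$acceptor_pairs; ac <- model$ac_pairs; al <- model$ac_loop
  acc5 <- c(1L, a)
  drep <- c(a + 1L, a + r)
  acs5 <- c(drep[2] + 1L, drep[2] + ac)
  aloop <- c(acs5[2] + 1L, acs5[2] + al)
  acs3 <- c(aloop[2] + 1L, aloop[2] + ac)
  tp5 <- c(acs3[2] + 1L, acs3[2] + s)
  tloop <- c(tp5[2] + 1L, tp5[2] + l)
  tp3 <- c(tloop[2] + 1L, tloop[2] + s)
  acc3 <- c(tp3[2] + 1L, tp3[2] + a)
  stopifnot(acc3[2] == L)
  mid <- (al - 3L) %/% 2L
  list(variant = "TPsiC",
       arms = tibble(
         arm = c("acceptor5", "dhu_replacement", "ac_stem5", "ac_loop",
                 "ac_stem3", "tpsic5", "tpsic_loop", "tpsic3", "acceptor3"),
         start = c(acc5[1], drep[1], acs5[1], aloop[1], acs3[1], tp5[1],
                   tloop[1], tp3[1], acc3[1]),
         end = c(acc5[2], drep[2], acs5[2], aloop[2], acs3[2], tp5[2],
                 tloop[2], tp3[2], acc3[2])),
       pairs = rbind(
         cbind(seq.int(acc5[1], acc5[2]), seq.int(L, acc3[1]), 1L),
         cbind(seq.int(acs5[1], acs5[2]), seq.int(acs3[2], acs3[1]), 2L),
         cbind(seq.int(tp5[1], tp5[2]), seq.int(tp3[2], tp3[1]), 3L)),
       stems = c("acceptor", "anticodon", "tpsic"),
       anticodon_pos = seq.int(aloop[1] + mid + 1L, aloop[1] + mid + 3L),
       tie = c(l, r))
}

# All placements consistent with the model for a sequence of length L.
enumerate_layouts <- function(L, model) {
  out <- list()
  base_tv <- 2L * model$acceptor_pairs + 2L * model$dhu_pairs +
    2L * model$ac_pairs + model$ac_loop
  for (d in seq.int(model$dhu_loop[1], model$dhu_loop[2])) {
    t <- L - base_tv - d
    if (t >= model$tv_loop[1] && t <= model$tv_loop[2]) {
      out[[length(out) + 1L]] <- layout_tv(L, d, t, model)
    }
  }
  base_ser <- 2L * model$acceptor_pairs + 2L * model$ac_pairs + model$ac_loop
  for (s in seq.int(model$tpsic_pairs[1], model$tpsic_pairs[2])) {
    for (l in seq.int(model$tpsic_loop[1], model$tpsic_loop[2])) {
      r <- L - base_ser - 2L * s - l
      if (r >= model$dhu_replacement[1] && r <= model$dhu_replacement[2]) {
        out[[length(out) + 1L]] <- layout_ser(L, r, s, l, model)
      }
    }
  }
  out
}

score_layout <- function(chars, layout, model) {
  p5 <- chars[layout$pairs[, 1]]
  p3 <- chars[layout$pairs[, 2]]
  ok <- if (model$allow_gu) is_stem_pair(p5, p3) else is_wc_pair(p5, p3)
  mm_by_stem <- tapply(!ok, layout$pairs[, 3], sum)
  list(ok = ok, mismatches = sum(!ok), mm_by_stem = mm_by_stem,
       feasible = all(mm_by_stem <= model$max_mismatch_per_stem),
       score = sum(ok) - sum(!ok))
}

#' Fold a candidate tRNA sequence
#'
#' Exhaustively enumerates every arm placement consistent with the model's
#' loop-length ranges (both the TV-replacement-loop variant and the DHU-less
#' serine variant), scores each as paired bases minus mismatches, and
#' returns the best placement whose per-stem mismatch count stays within
#' budget. Ties break deterministically: higher score, then fewer
#' mismatches, then TV variant before serine, then smaller TV (or TPsiC)
#' loop, then leftmost DHU (or smaller replacement) loop.
#'
#' @param seq Nucleotide string, 45-75 nt.
#' @param model A [trna_model()].
#' @return An object of class `mito_trna` (see [tidy.mito_trna()] /
#'   [glance.mito_trna()]), or `NULL` when no placement satisfies the
#'   mismatch budget.
#' @export
fold_trna <- function(seq, model = trna_model()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 45L || L > 75L) {
    abort(sprintf("tRNA sequence length %d outside [45, 75]", L))
  }
  chars <- seq_chars(seq)
  bad <- setdiff(unique(chars), c(BASES, "N"))
  if (length(bad) > 0) {
    abort(paste0("non-nucleotide characters: ", paste(bad, collapse = ", ")))
  }
  layouts <- enumerate_layouts(L, model)
  if (length(layouts) == 0L) return(NULL)
  scored <- map(layouts, function(lay) c(lay, score_layout(chars, lay, model)))
  scored <- scored[map_lgl(scored, "feasible")]
  if (length(scored) == 0L) return(NULL)
  ord <- order(-map_dbl(scored, "score"),
               map_dbl(scored, "mismatches"),
               map_chr(scored, "variant") != "TV",
               map_dbl(scored, ~ .x$tie[1]),
               map_dbl(scored, ~ .x$tie[2]))
  best <- scored[[ord[1]]]
  structure(
    list(seq = seq, length = L, variant = best$variant,
         score = best$score, mismatches = best$mismatches,
         arms = best$arms,
         pairs = tibble(pos5 = best$pairs[, 1], pos3 = best$pairs[, 2],
                        stem = best$stems[best$pairs[, 3]],
                        paired = best$ok),
         anticodon_pos = best$anticodon_pos,
         anticodon = paste(chars[best$anticodon_pos], collapse = "")),
    class = "mito_trna")
}

#' @export
print.mito_trna <- function(x, ...) {
  cat(sprintf("<mito_trna> %d nt, %s variant, anticodon %s, score %d (%d mismatch%s)\n",
              x$length, x$variant, x$anticodon, x$score, x$mismatches,
              if (x$mismatches == 1) "" else "es"))
  cat(" ", dot_bracket(x), "\n ", x$seq, "\n")
  invisible(x)
}

#' Dot-bracket string of a folded tRNA
#'
#' @param structure A `mito_trna` from [fold_trna()].
#' @return Single string; `(`/`)` mark paired positions, `.` unpaired.
#' @export
dot_bracket <- function(structure) {
  stopifnot(inherits(structure, "mito_trna"))
  db <- rep(".", structure$length)
  ok <- structure$pairs$paired
  db[structure$pairs$pos5[ok]] <- "("
  db[structure$pairs$pos3[ok]] <- ")"
  paste(db, collapse = "")
}

#' @describeIn fold_trna Base-pair table of the folded structure.
#' @param x A `mito_trna`.
#' @param ... Unused.
#' @method tidy mito_trna
#' @export
tidy.mito_trna <- function(x, ...) x$pairs

#' @describeIn fold_trna One-row structure summary.
#' @method glance mito_trna
#' @export
glance.mito_trna <- function(x, ...) {
  tibble(length = x$length, variant = x$variant, anticodon = x$anticodon,
         score = x$score, mismatches = x$mismatches)
}

# ---- classification ---------------------------------------------------------

# Canonical anticodons (DNA alphabet) for the 22 mitochondrial tRNA genes.
TRNA_ANTICODONS <- c(
  trnA = "TGC", trnC = "GCA", trnD = "GTC", trnE = "TTC", trnF = "GAA",
  trnG = "TCC", trnH = "GTG", trnI = "GAT", trnK = "TTT", trnL1 = "TAG",
  trnL2 = "TAA", trnM = "CAT", trnN = "GTT", trnP = "TGG", trnQ = "TTG",
  trnR = "TCG", trnS1 = "TCT", trnS2 = "TGA", trnT = "TGT", trnV = "TAC",
  trnW = "TCA", trnY = "GTA")

AA_TO_LABEL <- c(A = "trnA", C = "trnC", D = "trnD", E = "trnE", F = "trnF",
                 G = "trnG", H = "trnH", I = "trnI", K = "trnK", M = "trnM",
                 N = "trnN", P = "trnP", Q = "trnQ", R = "trnR", T = "trnT",
                 V = "trnV", W = "trnW", Y = "trnY")

#' Gene label implied by a tRNA anticodon
#'
#' The decoded amino acid is the translation of the reverse-complemented
#' anticodon read 5' to 3'. Leucine and serine isoacceptors are
#' disambiguated by codon family: `CUN` -> `trnL1`, `UUR` -> `trnL2`,
#' `AGN` -> `trnS1`, `UCN` -> `trnS2`.
#'
#' @param anticodon Anticodon triplet (DNA or RNA alphabet).
#' @param code A [genetic_code()].
#' @return Gene label, e.g. `"trnL2"`.
#' @examples
#' classify_anticodon("TAA")  # trnL2
#' classify_anticodon("TCT")  # trnS1
#' @export
classify_anticodon <- function(anticodon, code = genetic_code()) {
  anticodon <- chartr("Uu", "Tt", toupper(anticodon))
  if (nchar(anticodon) != 3L) abort("anticodon must be a triplet")
  codon <- revcomp(anticodon)
  aa <- unname(code$map[codon])
  if (is.na(aa)) abort(paste0("unknown codon ", codon))
  if (aa == "*") {
    abort(paste0("anticodon ", anticodon, " decodes to a stop codon"))
  }
  if (aa == "L") {
    if (substr(codon, 1, 2) == "CT") return("trnL1") else return("trnL2")
  }
  if (aa == "S") {
    if (substr(codon, 1, 2) == "AG") return("trnS1") else return("trnS2")
  }
  unname(AA_TO_LABEL[aa])
}

#' Fold and validate every annotated tRNA of a genome
#'
#' @param features Feature tibble; `class == "tRNA"` rows are used.
#' @param genome A [mito_genome()].
#' @param model A [trna_model()].
#' @param code A [genetic_code()].
#' @return Tibble with one row per tRNA: `gene`, `length`, `folded`,
#'   `variant`, `score`, `mismatches`, `anticodon`, `label` (classification
#'   from the recovered anticodon) and `agrees` (label matches the annotated
#'   gene name). Attributes `length_range` summarises observed lengths.
#' @export
validate_trnas <- function(features, genome, model = trna_model(),
                           code = genetic_code()) {
  stopifnot(inherits(genome, "mito_genome"))
  trnas <- filter(validate_features(features, genome$length),
                  .data$class == "tRNA")
  if (nrow(trnas) == 0L) abort("no tRNA features in table")
  rows <- map(seq_len(nrow(trnas)), function(i) {
    f <- trnas[i, ]
    s <- feature_seq(f, genome)
    st <- fold_trna(s, model)
    if (is.null(st)) {
      return(tibble(gene = f$gene, length = nchar(s), folded = FALSE,
                    variant = NA_character_, score = NA_integer_,
                    mismatches = NA_integer_, anticodon = NA_character_,
                    label = NA_character_, agrees = FALSE))
    }
    label <- tryCatch(classify_anticodon(st$anticodon, code),
                      error = function(e) NA_character_)
    tibble(gene = f$gene, length = nchar(s), folded = TRUE,
           variant = st$variant, score = st$score,
           mismatches = st$mismatches, anticodon = st$anticodon,
           label = label, agrees = identical(label, f$gene))
  })
  out <- bind_rows(rows)
  attr(out, "length_range") <- range(out$length)
  out
}
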