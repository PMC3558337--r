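# Synthetic mitogenome generation.
#
# A genome spec fixes everything the analysis pipeline assumes: the gene
# layout (coordinates, start/stop codons, overlaps), the codon distribution
# of protein-coding genes, per-class base compositions, tandem-repeat plans
# for non-coding regions, and the tRNA structural model. Generation is
# deterministic given a seed, so every pipeline stage can be tested against
# planted truth without downloading any real sequence.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

sample_bases <- function(n, freq) {
  if (n <= 0L) return(character(0))
  sample(BASES, n, replace = TRUE, prob = freq)
}

#' Specification of a synthetic mitogenome
#'
#' @param layout Feature tibble giving the gene plan: `gene`, `class`,
#'   `start`, `end`, `strand`, and for PCGs `start_codon`/`stop_codon`
#'   (stop may be the incomplete `T`/`TA`). Coordinates are 1-based
#'   inclusive; overlaps between neighbours are realised by constrained
#'   sequence sharing.
#' @param genome_length Total genome length (bp); defaults to the maximum
#'   layout end.
#' @param genome_id Identifier for the generated genome.
#' @param codon_distribution Named 64-entry frequency vector over codons
#'   (stop entries must be zero); protein-coding genes are drawn
#'   codon-by-codon from it. Normalised internally.
#' @param base_freq Named list of per-class base frequency vectors
#'   (`A`,`C`,`G`,`T` order) for `rRNA`, `tRNA` (stems and loops), `NCR`
#'   and `intergenic` background.
#' @param repeat_plans Named list (by NCR feature name) of data frames with
#'   `unit_length`, `copies`, `mismatches`: tandem arrays planted
#'   contiguously at the 5' end of that NCR, mismatches injected into the
#'   first copy.
#' @param trna_model A [trna_model()]; default model when `NULL`.
#' @return Object of class `mito_spec`.
#' @export
genome_spec <- function(layout, genome_length = NULL, genome_id = "synthetic",
                        codon_distribution = NULL, base_freq = NULL,
                        repeat_plans = list(), trna_model = NULL) {
  trna_model <- trna_model %||% default_trna_model()
  layout <- validate_features(layout)
  genome_length <- as.integer(genome_length %||% max(layout$end))
  if (is.null(codon_distribution)) {
    code <- genetic_code()
    codon_distribution <- setNames(rep(1, 64), all_codons())
    codon_distribution[code$stop_codons] <- 0
  }
  stopifnot(length(codon_distribution) == 64L,
            !is.null(names(codon_distribution)))
  codon_distribution <- codon_distribution[all_codons()]
  codon_distribution <- codon_distribution / sum(codon_distribution)
  default_freq <- c(A = 0.35, C = 0.08, G = 0.12, T = 0.45)
  base_freq <- utils::modifyList(
    list(rRNA = default_freq, tRNA = default_freq, NCR = default_freq,
         intergenic = default_freq),
    base_freq %||% list())
  base_freq <- map(base_freq, function(f) f[BASES] / sum(f[BASES]))
  # layout must reconcile with the declared genome length
  census <- gap_overlap_census(layout, genome_length)
  ring <- filter(layout, .data$class != "NCR")
  spans <- feature_length(ring$start, ring$end, genome_length)
  residual <- sum(spans) + sum(census$length[census$length > 0]) +
    sum(census$length[census$length < 0]) - genome_length
  if (residual != 0L) {
    abort(sprintf("layout spans + gaps - overlaps differ from genome length by %d bp",
                  residual))
  }
  structure(
    list(genome_id = genome_id, genome_length = genome_length,
         layout = layout, codon_distribution = codon_distribution,
         base_freq = base_freq, repeat_plans = repeat_plans,
         trna_model = trna_model),
    class = "mito_spec")
}

#' @export
print.mito_spec <- function(x, ...) {
  cat(sprintf("<mito_spec> %s: %d bp, %d features, %d repeat plan(s)\n",
              x$genome_id, x$genome_length, nrow(x$layout),
              length(x$repeat_plans)))
  invisible(x)
}

# ---- tRNA generation --------------------------------------------------------

sample_layout_sizes <- function(label, length, model) {
  serine <- label %in% c("trnS1", "trnS2")
  combos <- list()
  if (serine) {
    base <- 2L * model$acceptor_pairs + 2L * model$ac_pairs + model$ac_loop
    for (s in seq.int(model$tpsic_pairs[1], model$tpsic_pairs[2])) {
      for (l in seq.int(model$tpsic_loop[1], model$tpsic_loop[2])) {
        r <- length - base - 2L * s - l
        if (r >= model$dhu_replacement[1] && r <= model$dhu_replacement[2]) {
          combos[[length(combos) + 1L]] <- list(serine = TRUE, r = r, s = s, l = l)
        }
      }
    }
  } else {
    base <- 2L * model$acceptor_pairs + 2L * model$dhu_pairs +
      2L * model$ac_pairs + model$ac_loop
    for (d in seq.int(model$dhu_loop[1], model$dhu_loop[2])) {
      t <- length - base - d
      if (t >= model$tv_loop[1] && t <= model$tv_loop[2]) {
        combos[[length(combos) + 1L]] <- list(serine = FALSE, d = d, t = t)
      }
    }
  }
  if (length(combos) == 0L) {
    abort(sprintf("no %s arm layout fits a %d nt tRNA under this model",
                  if (serine) "TPsiC-variant" else "TV-loop", length))
  }
  combos[[sample.int(length(combos), 1L)]]
}

generate_trna_once <- function(label, model, length, fixed, anticodon, freq) {
  sizes <- sample_layout_sizes(label, length, model)
  layout <- if (sizes$serine) {
    layout_ser(length, sizes$r, sizes$s, sizes$l, model)
  } else {
    layout_tv(length, sizes$d, sizes$t, model)
  }
  chars <- rep(NA_character_, length)
  chars[layout$anticodon_pos] <- seq_chars(anticodon)
  if (!is.null(fixed) && length(fixed) > 0) {
    pos <- as.integer(names(fixed))
    conflict <- !is.na(chars[pos]) & chars[pos] != unname(fixed)
    if (any(conflict)) {
      abort("infeasible overlap constraints: fixed bases conflict with the planted anticodon")
    }
    chars[pos] <- unname(fixed)
  }
  for (k in seq_len(nrow(layout$pairs))) {
    i <- layout$pairs[k, 1]
    j <- layout$pairs[k, 2]
    if (!is.na(chars[i]) && !is.na(chars[j])) {
      if (!is_wc_pair(chars[i], chars[j])) {
        abort("infeasible overlap constraints: both stem partners fixed and non-complementary")
      }
    } else if (!is.na(chars[i])) {
      chars[j] <- unname(COMPLEMENT[chars[i]])
    } else if (!is.na(chars[j])) {
      chars[i] <- unname(COMPLEMENT[chars[j]])
    } else {
      b <- sample_bases(1L, freq)
      chars[i] <- b
      chars[j] <- unname(COMPLEMENT[b])
    }
  }
  free <- is.na(chars)
  chars[free] <- sample_bases(sum(free), freq)
  paste(chars, collapse = "")
}

#' Generate a synthetic mitochondrial tRNA gene
#'
#' Produces a sequence whose planned arms pair perfectly under the model,
#' with the anticodon implied by the gene label (serine labels use the
#' DHU-less TPsiC variant). Each candidate is verified to fold back to the
#' planted variant and anticodon as the unique best structure; ambiguous
#' draws are rejected and redrawn, so the generator/folder round trip is
#' exact by construction.
#'
#' @param label Gene label from the canonical 22-tRNA vocabulary.
#' @param model A [trna_model()].
#' @param seed Optional seed (omit to draw from the current RNG stream).
#' @param length Sequence length (nt); default drawn from 52-60.
#' @param fixed Optional named character vector of constrained bases
#'   (position -> base) imposed by overlapping neighbours; stem partners of
#'   constrained positions are set to their complements.
#' @param freq Base frequencies for unconstrained positions.
#' @return Nucleotide string of the requested length.
#' @export
generate_trna <- function(label, model = trna_model(), seed = NULL,
                          length = NULL, fixed = NULL,
                          freq = c(A = 0.39, C = 0.05, G = 0.105, T = 0.455)) {
  if (!label %in% names(TRNA_ANTICODONS)) {
    abort(paste0("unknown tRNA label: ", label))
  }
  anticodon <- TRNA_ANTICODONS[[label]]
  freq <- freq[BASES] / sum(freq[BASES])
  with_local_seed(seed, {
    length <- as.integer(length %||% sample(52:60, 1L))
    want_variant <- if (label %in% c("trnS1", "trnS2")) "TPsiC" else "TV"
    for (attempt in seq_len(50L)) {
      s <- generate_trna_once(label, model, length, fixed, anticodon, freq)
      st <- fold_trna(s, model)
      if (!is.null(st) && st$mismatches == 0L &&
            identical(st$variant, want_variant) &&
            identical(st$anticodon, anticodon)) {
        return(s)
      }
    }
    abort(paste0("could not generate an unambiguously folding ", label,
                 " of length ", length))
  })
}

# ---- NCR / repeat generation ------------------------------------------------

generate_ncr_seq <- function(len, plan, freq) {
  out <- character(0)
  if (!is.null(plan) && nrow(plan) > 0) {
    for (k in seq_len(nrow(plan))) {
      p <- as.integer(plan$unit_length[k])
      cp <- as.integer(plan$copies[k])
      mm <- as.integer(plan$mismatches[k])
      unit <- sample_bases(p, freq)
      copies <- rep(list(unit), cp)
      if (mm > 0L) {
        pos <- sample.int(p, mm)
        for (q in pos) {
          copies[[1]][q] <- sample(setdiff(BASES, unit[q]), 1L)
        }
      }
      out <- c(out, unlist(copies))
    }
    if (length(out) > len) {
      abort("repeat plan exceeds the non-coding region length")
    }
  }
  c(out, sample_bases(len - length(out), freq))
}

# ---- genome generation ------------------------------------------------------

sample_codons <- function(n, dist, constraints = NULL) {
  codons <- names(dist)
  if (is.null(constraints)) {
    return(sample(codons, n, replace = TRUE, prob = dist))
  }
  out <- character(n)
  free <- map_lgl(constraints, function(cc) all(is.na(cc)))
  out[free] <- sample(codons, sum(free), replace = TRUE, prob = dist)
  for (i in which(!free)) {
    cc <- constraints[[i]]
    keep <- rep(TRUE, length(codons))
    for (o in 1:3) {
      if (!is.na(cc[o])) keep <- keep & substr(codons, o, o) == cc[o]
    }
    support <- codons[keep & dist > 0]
    if (length(support) == 0L) {
      abort("infeasible overlap constraints: no codon with positive probability matches the shared bases")
    }
    out[i] <- sample(support, 1L, prob = dist[support])
  }
  out
}

#' Generate a synthetic mitogenome from a specification
#'
#' Protein-coding genes are drawn codon-by-codon from the spec's codon
#' distribution, opened by the planned start codon and closed by the
#' planned (complete or incomplete) stop; tRNAs come from
#' [generate_trna()]; rRNA and non-coding background are i.i.d. draws from
#' the per-class base frequencies; tandem-repeat plans are embedded at the
#' 5' ends of their non-coding regions. Overlaps between neighbouring genes
#' are realised by constrained sequence sharing: bases already written by
#' an upstream feature constrain the downstream draw (codon support is
#' restricted, stem partners are complemented), and plans whose shared
#' bases cannot satisfy both neighbours fail loudly.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; generation is deterministic given
#'   (spec, seed).
#' @return List with `genome` (a [mito_genome()]) and `features` (the
#'   realised feature tibble, with tRNA anticodons filled in).
#' @export
generate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mito_spec"))
  with_local_seed(seed, {
    L <- spec$genome_length
    residues <- rep(NA_character_, L)
    feats <- spec$layout
    # Pre-seed every planned codon base (PCG starts and stops) so that
    # overlapping neighbours are generated conditional on each other's
    # hard requirements; conflicting plans fail before any sampling.
    for (i in which(feats$class == "PCG")) {
      f <- feats[i, ]
      if (is.na(f$start_codon) || is.na(f$stop_codon)) next
      pos <- span_positions(f$start, f$end, L)
      plan_pos <- c(pos[1:3],
                    pos[seq.int(length(pos) - nchar(f$stop_codon) + 1L,
                                length(pos))])
      plan_chars <- c(seq_chars(f$start_codon), seq_chars(f$stop_codon))
      if (f$strand == "-") {
        plan_pos <- rev(pos)[c(1:3, seq.int(
          length(pos) - nchar(f$stop_codon) + 1L, length(pos)))]
        plan_chars <- unname(COMPLEMENT[plan_chars])
      }
      clash <- !is.na(residues[plan_pos]) & residues[plan_pos] != plan_chars
      if (any(clash)) {
        abort(paste0("infeasible overlap constraints: planned codons of ",
                     f$gene, " conflict with a neighbouring plan"))
      }
      residues[plan_pos] <- plan_chars
    }
    feats$anticodon <- feats$anticodon %||% rep(NA_character_, nrow(feats))
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      pos <- span_positions(f$start, f$end, L)
      len <- length(pos)
      existing <- residues[pos]
      klass <- f$class
      if (klass == "PCG") {
        if (is.na(f$start_codon) || is.na(f$stop_codon)) {
          abort(paste0("PCG ", f$gene, " needs start_codon and stop_codon in the layout"))
        }
        stop_len <- nchar(f$stop_codon)
        if ((len - stop_len) %% 3L != 0L) {
          abort(paste0("PCG ", f$gene,
                       " span minus stop length is not divisible by 3"))
        }
        n_cod <- (len - stop_len) %/% 3L
        planned <- c(seq_chars(f$start_codon), rep(NA, 3L * (n_cod - 1L)),
                     seq_chars(f$stop_codon))
        conflict <- !is.na(existing) & !is.na(planned) & existing != planned
        if (any(conflict)) {
          abort(paste0("infeasible overlap constraints: shared bases of ",
                       f$gene, " conflict with its planned codons"))
        }
        constraints <- map(seq_len(n_cod - 1L), function(k) {
          existing[(3L * k + 1L):(3L * k + 3L)]
        })
        if (all(map_lgl(constraints, function(cc) all(is.na(cc))))) {
          constraints <- NULL
        }
        internal <- if (n_cod > 1L) {
          sample_codons(n_cod - 1L, spec$codon_distribution, constraints)
        } else character(0)
        chars <- c(seq_chars(f$start_codon),
                   unlist(strsplit(internal, "", fixed = TRUE)),
                   seq_chars(f$stop_codon))
      } else if (klass == "tRNA") {
        fixed_idx <- which(!is.na(existing))
        fixed <- if (length(fixed_idx) > 0) {
          setNames(existing[fixed_idx], fixed_idx)
        } else NULL
        s <- generate_trna(f$gene, spec$trna_model, seed = NULL,
                           length = len, fixed = fixed,
                           freq = spec$base_freq$tRNA)
        chars <- seq_chars(s)
        feats$anticodon[i] <- TRNA_ANTICODONS[[f$gene]]
      } else if (klass == "rRNA") {
        chars <- sample_bases(len, spec$base_freq$rRNA)
        chars[!is.na(existing)] <- existing[!is.na(existing)]
      } else {  # NCR
        chars <- generate_ncr_seq(len, spec$repeat_plans[[f$gene]],
                                  spec$base_freq$NCR)
        chars[!is.na(existing)] <- existing[!is.na(existing)]
      }
      if (f$strand == "-") {
        chars <- rev(unname(COMPLEMENT[chars]))
      }
      residues[pos] <- chars
    }
    free <- is.na(residues)
    residues[free] <- sample_bases(sum(free), spec$base_freq$intergenic)
    list(genome = mito_genome(spec$genome_id, paste(residues, collapse = "")),
         features = feats)
  })
}

# ---- templates from the packaged organization tables ------------------------

mitocomp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mitocomp")
  if (path == "") abort(paste0("packaged fixture not found: ", file))
  path
}

template_spec <- function(table1_file, count_col, genome_id, genome_length,
                          base_freq, repeat_plans) {
  layout <- read_feature_tsv(mitocomp_extdata(table1_file))
  t3 <- utils::read.delim(mitocomp_extdata("codon_usage_table3.tsv"))
  dist <- setNames(t3[[count_col]], t3$codon)
  genome_spec(layout, genome_length = genome_length, genome_id = genome_id,
              codon_distribution = dist, base_freq = base_freq,
              repeat_plans = repeat_plans)
}

#' Template spec: the 14.8-kb pine wood nematode mitogenome layout
#'
#' Gene coordinates, start/stop codons and overlaps come from the packaged
#' organization-table transcription; the codon distribution comes from the
#' packaged codon-usage counts; per-class base frequencies target the
#' published partition compositions; the control-region repeat plan plants
#' four 147-nt, four 101-nt and three 56-nt tandem units (one mismatch in
#' the first 56-nt copy).
#'
#' @return A [genome_spec()].
#' @export
bx_genome_spec <- function() {
  template_spec(
    "bxylophilus_table1.tsv", "count_bx", "Bxylophilus_synthetic", 14778L,
    base_freq = list(
      rRNA = c(A = 0.391, C = 0.050, G = 0.097, T = 0.462),
      tRNA = c(A = 0.391, C = 0.049, G = 0.105, T = 0.456),
      NCR = c(A = 0.477, C = 0.007, G = 0.007, T = 0.510),
      intergenic = c(A = 0.477, C = 0.007, G = 0.007, T = 0.510)),
    repeat_plans = list(
      NCR = tibble(unit_length = c(147L, 101L, 56L),
                   copies = c(4L, 4L, 3L),
                   mismatches = c(0L, 0L, 1L))))
}

#' Template spec: the 21.7-kb walnut root-lesion nematode mitogenome layout
#'
#' As [bx_genome_spec()], for the second genome: two large non-coding
#' regions, with three 494-bp tandem units (two mismatches, both in the
#' first copy) planted at the 5' end of the larger one.
#'
#' @return A [genome_spec()].
#' @export
pv_genome_spec <- function() {
  template_spec(
    "pvulnus_table1.tsv", "count_pv", "Pvulnus_synthetic", 21656L,
    base_freq = list(
      rRNA = c(A = 0.302, C = 0.115, G = 0.191, T = 0.392),
      tRNA = c(A = 0.350, C = 0.069, G = 0.160, T = 0.422),
      NCR = c(A = 0.374, C = 0.113, G = 0.158, T = 0.355),
      intergenic = c(A = 0.374, C = 0.113, G = 0.158, T = 0.355)),
    repeat_plans = list(
      NCR1 = tibble(unit_length = 494L, copies = 3L, mismatches = 2L)))
}

#' Random small genome specification
#'
#' Draws a compact but structurally complete layout (a handful of PCGs,
#' tRNAs, one rRNA, optionally an NCR with a planted tandem array) with
#' random intergenic gaps — a quick source of varied inputs for
#' property-style checks.
#'
#' @param seed Integer seed.
#' @param n_pcg,n_trna Gene counts.
#' @param with_ncr Include a non-coding region with a repeat plan?
#' @return A [genome_spec()].
#' @export
random_genome_spec <- function(seed, n_pcg = 3L, n_trna = 4L,
                               with_ncr = TRUE) {
  with_local_seed(seed, {
    code <- genetic_code()
    pcg_names <- sample(c("cox1", "cox2", "cox3", "nad1", "nad2", "cob",
                          "atp6", "nad4"), n_pcg)
    trna_names <- sample(names(TRNA_ANTICODONS), n_trna)
    rows <- list()
    cursor <- 1L
    add <- function(gene, klass, len, start_codon = NA, stop_codon = NA) {
      gap <- sample(0:15, 1L)
      start <- cursor + gap
      rows[[length(rows) + 1L]] <<- tibble(
        gene = gene, class = klass, start = start,
        end = start + len - 1L, strand = "+",
        start_codon = start_codon, stop_codon = stop_codon,
        anticodon = NA_character_)
      cursor <<- start + len
    }
    for (g in pcg_names) {
      stop_codon <- sample(c("TAA", "TAG", "T", "TA"), 1L)
      n_aa <- sample(25:60, 1L)
      add(g, "PCG", 3L * n_aa + nchar(stop_codon),
          start_codon = sample(code$start_codons, 1L), stop_codon = stop_codon)
    }
    for (g in trna_names) add(g, "tRNA", sample(52:60, 1L))
    add("rrnS", "rRNA", sample(120:300, 1L))
    plans <- list()
    if (with_ncr) {
      unit <- sample(15:40, 1L)
      copies <- sample(2:4, 1L)
      len <- unit * copies + sample(30:80, 1L)
      add("NCR", "NCR", len)
      plans$NCR <- tibble(unit_length = unit, copies = copies,
                          mismatches = sample(0:1, 1L))
    }
    layout <- bind_rows(rows)
    genome_spec(layout, genome_length = cursor - 1L + sample(0:20, 1L),
                genome_id = paste0("random_", seed),
                repeat_plans = plans)
  })
}

# ---- gene-order perturbation ------------------------------------------------

#' Apply random single-gene translocations to a gene order
#'
#' @param order A [gene_order()].
#' @param n_moves Number of single-gene moves (>= 0).
#' @param seed Integer seed.
#' @return List with `order` (the perturbed [gene_order()]) and `moves`
#'   (tibble `gene`, `from`, `to`: ground-truth move list, positions in the
#'   pre-move linearisation).
#' @export
perturb_gene_order <- function(order, n_moves, seed = 1L) {
  stopifnot(n_moves >= 0L)
  genes <- as.character(order)
  with_local_seed(seed, {
    moves <- list()
    circ_neighbours <- function(g, pos) {
      n <- length(g)
      c(g[(pos - 2L) %% n + 1L], g[pos %% n + 1L])
    }
    for (k in seq_len(n_moves)) {
      n <- length(genes)
      repeat {
        from <- sample.int(n, 1L)
        gene <- genes[from]
        old_nb <- circ_neighbours(genes, from)
        rest <- genes[-from]
        to <- sample(setdiff(seq_len(n), from), 1L)
        cand <- append(rest, gene, after = to - 1L)
        # a reinsertion between the same circular neighbours is a rotation,
        # not a translocation; redraw
        if (!identical(circ_neighbours(cand, to), old_nb)) break
      }
      genes <- cand
      moves[[k]] <- tibble(gene = gene, from = from, to = to)
    }
    anchor <- attr(order, "anchor")
    if (!anchor %in% genes) anchor <- genes[1]
    list(order = gene_order(genes,
                            genome_id = paste0(attr(order, "genome_id"),
                                               "_perturbed"),
                            anchor = anchor),
         moves = if (length(moves) > 0) bind_rows(moves) else
           tibble(gene = character(0), from = integer(0), to = integer(0)))
  })
}
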