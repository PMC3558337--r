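# Internal helpers shared across modules.

# Round half away from zero (the convention of the printed tables;
# base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", U = "A")

revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(COMPLEMENT)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in sequence: ",
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

codons_of <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) abort("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# All 64 codons in a fixed lexicographic order (A < C < G < T).
all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# Watson-Crick pair (strict)?
is_wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# Valid tRNA stem pair: Watson-Crick or G.U wobble; N never pairs.
is_stem_pair <- function(a, b) {
  is_wc_pair(a, b) | (a == "G" & b == "T") | (a == "T" & b == "G")
}

`%||%` <- rlang::`%||%`
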