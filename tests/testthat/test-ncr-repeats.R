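planted_array <- function(unit_len, copies, background = 200, seed = 1,
                          mismatches = 0) {
  set.seed(seed)
  unit <- strsplit(random_dna(unit_len), "")[[1]]
  copy_list <- rep(list(unit), copies)
  for (q in seq_len(mismatches)) {
    pos <- sample(unit_len, 1)
    copy_list[[1]][pos] <- setdiff(c("A", "C", "G", "T"), unit[pos])[1]
  }
  left <- random_dna(background)
  right <- random_dna(background)
  list(seq = paste0(left, paste(unlist(copy_list), collapse = ""), right),
       start = background + 1L)
}

test_that("a planted perfect array is recovered exactly once", {
  pl <- planted_array(147, 4, seed = 2)
  reps <- find_tandem_repeats(pl$seq, min_unit = 100, max_unit = 200,
                              min_copies = 3)
  expect_equal(nrow(reps), 1)
  expect_lt(abs(reps$start - pl$start), 147)  # phase ambiguity at boundaries
  expect_equal(reps$unit_length, 147L)
  expect_equal(reps$copies, 4L)
  expect_equal(reps$total_mismatches, 0L)
})

test_that("a first-copy mismatch is attributed to the first copy", {
  pl <- planted_array(56, 3, seed = 3, mismatches = 1)
  reps <- find_tandem_repeats(pl$seq, min_unit = 40, max_unit = 80,
                              min_copies = 3, max_mismatch_per_copy = 1)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$copies, 3L)
  expect_equal(reps$total_mismatches, 1L)
  expect_equal(reps$per_copy_mismatches[[1]], c(1L, 0L, 0L))
})

test_that("random sequence carries no long perfect array (vs brute force)", {
  set.seed(17)
  s <- random_dna(1650, freq = c(A = 0.477, C = 0.007, G = 0.007, T = 0.51))
  expect_false(brute_force_exact_tandem(s, 40, 1650 %/% 3, 3))
  reps <- find_tandem_repeats(s, min_unit = 40, min_copies = 3,
                              max_mismatch_per_copy = 0)
  expect_equal(nrow(reps), 0)
})

test_that("every planted perfect array within range is detected", {
  for (seed in 1:20) {
    set.seed(seed)
    unit_len <- sample(20:60, 1)
    copies <- sample(2:4, 1)
    pl <- planted_array(unit_len, copies, background = 120, seed = seed + 100)
    reps <- find_tandem_repeats(pl$seq, min_unit = 15, max_unit = 70,
                                min_copies = copies)
    hit <- reps[reps$unit_length == unit_len, ]
    expect_gte(nrow(hit), 1)
    # the phase is ambiguous by up to one unit when flanking background
    # happens to extend the periodicity; unit, copies and mismatches are
    # the planted truth
    expect_true(any(abs(hit$start - pl$start) < unit_len &
                      hit$copies == copies & hit$total_mismatches == 0))
  }
})

test_that("no report strictly contains another of the same period", {
  pl <- planted_array(30, 5, seed = 9)
  reps <- find_tandem_repeats(pl$seq, min_unit = 10, max_unit = 80,
                              min_copies = 2)
  expect_gte(nrow(reps), 1)
  ends <- reps$start + reps$copies * reps$unit_length - 1L
  for (i in seq_len(nrow(reps))) {
    for (j in seq_len(nrow(reps))) {
      if (i == j || reps$unit_length[i] != reps$unit_length[j]) next
      strictly_inside <- reps$start[j] >= reps$start[i] &&
        ends[j] <= ends[i] && !(reps$start[j] == reps$start[i] &&
                                  ends[j] == ends[i])
      expect_false(strictly_inside)
    }
  }
})

test_that("repeat discovery is reverse-complement symmetric", {
  for (seed in c(5, 6)) {
    pl <- planted_array(40, 3, seed = seed)
    fwd <- find_tandem_repeats(pl$seq, min_unit = 30, max_unit = 60,
                               min_copies = 3)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", pl$seq), "")[[1]]),
                collapse = "")
    bwd <- find_tandem_repeats(rc, min_unit = 30, max_unit = 60,
                               min_copies = 3)
    expect_equal(nrow(fwd), nrow(bwd))
    expect_equal(sort(fwd$unit_length), sort(bwd$unit_length))
    expect_equal(sort(fwd$copies), sort(bwd$copies))
    expect_equal(sort(fwd$total_mismatches), sort(bwd$total_mismatches))
  }
})

test_that("the template control regions yield their planted repeat families", {
  rep_bx <- ncr_report(bx_sim$features, bx_sim$genome, min_unit = 40,
                       min_copies = 3, max_mismatch_per_copy = 1)
  ncr <- rep_bx[rep_bx$left_gene == "nad4", ]
  expect_equal(ncr$length, 1650L)
  fams <- ncr$repeats[[1]]
  expect_equal(fams$unit_length, c(147L, 101L, 56L))
  expect_equal(fams$copies, c(4L, 4L, 3L))
  expect_equal(fams$total_mismatches, c(0L, 0L, 1L))
  expect_lt(abs(ncr$AT - 98.7), 1)

  rep_pv <- ncr_report(pv_sim$features, pv_sim$genome, min_unit = 400,
                       min_copies = 3, max_mismatch_per_copy = 2)
  big <- rep_pv[rep_pv$left_gene == "cox1", ]
  expect_equal(big$length, 6847L)
  expect_equal(big$repeats[[1]]$unit_length, 494L)
  expect_equal(big$repeats[[1]]$copies, 3L)
  expect_equal(big$repeats[[1]]$total_mismatches, 2L)
})

test_that("genomes without long non-coding intervals report nothing", {
  spec <- random_genome_spec(12, with_ncr = FALSE)
  sim <- generate_genome(spec, seed = 12)
  rep <- ncr_report(sim$features, sim$genome, min_length = 100)
  expect_equal(nrow(rep), 0)
})

test_that("degenerate parameter ranges are rejected", {
  expect_error(find_tandem_repeats("ACGTACGT", min_unit = 1), "min_unit")
  expect_error(find_tandem_repeats("ACGTACGT", min_unit = 4, max_unit = 2),
               "degenerate")
  expect_error(find_tandem_repeats("ACGT", min_unit = 2, min_copies = 1),
               "min_copies")
})
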