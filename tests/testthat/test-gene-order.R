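bx_order <- gene_order(bx_features, "Bx")
pv_order <- gene_order(pv_features, "Pv")

test_that("gene orders are extracted, anchored and rotation-invariant", {
  expect_length(bx_order, 36)
  expect_equal(as.character(bx_order)[1:6],
               c("cox1", "trnC", "trnM", "trnD", "trnG", "cox2"))
  expect_equal(as.character(pv_order)[1:5],
               c("cox1", "trnH", "trnL1", "rrnL", "nad3"))
  expect_equal(as.character(bx_order), BX_ORDER)
  expect_equal(as.character(pv_order), PV_ORDER)

  rotated <- gene_order(c(BX_ORDER[10:36], BX_ORDER[1:9]), "rot")
  expect_equal(as.character(rotated), BX_ORDER)
})

test_that("incomplete or duplicated tables are rejected", {
  expect_error(gene_order(bx_features[-1, ]), "missing")
  dup <- dplyr::bind_rows(bx_features, bx_features[2, ])
  expect_error(gene_order(dup), "duplicated")
})

test_that("shared adjacencies match the published blocks and a hand oracle", {
  self <- shared_adjacencies(bx_order, bx_order)
  expect_equal(nrow(self), 36)

  shared <- shared_adjacencies(bx_order, pv_order)
  keys <- paste(shared$from, shared$to)
  # the published two-gene blocks shared between the two genomes
  expect_true(all(c("nad6 nad4L", "nad2 trnI", "cox3 trnN", "rrnL nad3")
                  %in% keys))
  expect_setequal(keys, BX_PV_SHARED)
  expect_setequal(keys, oracle_shared_adjacencies(BX_ORDER, PV_ORDER))
})

test_that("breakpoint distances follow single-move arithmetic", {
  expect_equal(breakpoint_distance(bx_order, bx_order), 0)
  expect_equal(breakpoint_distance(bx_order, pv_order), 36 - 5)

  # move one gene far away by hand
  moved <- setdiff(BX_ORDER, "trnN")
  moved <- append(moved, "trnN", after = 10)
  moved_order <- gene_order(moved, "moved")
  expect_equal(nrow(shared_adjacencies(bx_order, moved_order)), 33)
  expect_equal(breakpoint_distance(bx_order, moved_order), 3)
})

test_that("translocation reports pinpoint moved genes and their contexts", {
  expect_equal(nrow(translocation_report(bx_order, bx_order)), 0)

  moved <- setdiff(BX_ORDER, "trnN")
  moved <- append(moved, "trnN", after = 10)
  rep1 <- translocation_report(bx_order, gene_order(moved, "m"))
  expect_true("trnN" %in% rep1$gene)
  row <- rep1[rep1$gene == "trnN", ]
  expect_equal(c(row$pred_a, row$succ_a), c("cox3", "trnT"))
  # every flagged gene lies in the disturbed neighbourhoods
  affected <- c("trnN", "cox3", "trnT", moved[10], moved[12])
  expect_true(all(rep1$gene %in% affected))

  # two far-apart moves
  two <- perturb_gene_order(bx_order, 2, seed = 6)
  rep2 <- translocation_report(bx_order, two$order)
  expect_true(all(two$moves$gene %in% rep2$gene))
})

test_that("breakpoint distance is a metric on random circular orders", {
  set.seed(30)
  orders <- purrr::map(1:20, function(i) {
    gene_order(sample(BX_ORDER), paste0("r", i), anchor = "cox1")
  })
  for (k in 1:50) {
    i <- sample(20, 1)
    j <- sample(20, 1)
    dij <- breakpoint_distance(orders[[i]], orders[[j]])
    expect_gte(dij, 0)
    expect_equal(dij, breakpoint_distance(orders[[j]], orders[[i]]))
    if (i == j) expect_equal(dij, 0)
  }
  for (k in 1:20) {
    idx <- sample(20, 3)
    d12 <- breakpoint_distance(orders[[idx[1]]], orders[[idx[2]]])
    d23 <- breakpoint_distance(orders[[idx[2]]], orders[[idx[3]]])
    d13 <- breakpoint_distance(orders[[idx[1]]], orders[[idx[3]]])
    expect_lte(d13, d12 + d23)
  }
  expect_error(breakpoint_distance(bx_order,
                                   gene_order(BX_ORDER[1:35], anchor = "cox1")),
               "universe")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 4, 6,
                4, 0, 8,
                6, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- gene_order_tree(d)
  # x_a = (d_ab + d_ac - d_bc)/2 = 1; x_b = 3; x_c = 5
  tip_edges <- tree$edge.length[match(1:3, tree$edge[, 2])]
  expect_equal(sort(tip_edges), c(1, 3, 5))
})

test_that("NJ recovers additive five-taxon trees exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    true <- ape::rtree(5, rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.5, 3)
    d <- ape::cophenetic.phylo(true)
    est <- gene_order_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(true), est)[[1]], 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("a zero matrix gives zero branch lengths and Newick output", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  path <- withr::local_tempfile(fileext = ".nwk")
  tree <- gene_order_tree(d, newick = path)
  expect_true(all(tree$edge.length == 0))
  expect_s3_class(ape::read.tree(path), "phylo")
  bad <- d
  bad[1, 2] <- 5
  expect_error(gene_order_tree(bad), "symmetric")
})

test_that("gene-order files round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_orders(list(Bx = bx_order, Pv = pv_order), path)
  back <- read_gene_orders(path)
  expect_equal(as.character(back$Bx), BX_ORDER)
  expect_equal(as.character(back$Pv), PV_ORDER)
  m <- breakpoint_matrix(back)
  expect_equal(m["Bx", "Pv"], 31)
  expect_equal(diag(m), c(Bx = 0, Pv = 0))
})
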