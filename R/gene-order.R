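# Circular gene-order comparison: adjacencies, breakpoint distances,
# translocation reports, and a neighbor-joining tree over a distance matrix.
#
# Adjacencies are directed: in these genomes all 36 genes are transcribed in
# the same direction, so the ordered neighbour pair carries the signal. A
# circular order of n genes has exactly n directed adjacencies.

#' Circular gene order of a feature table
#'
#' Sorts the 36 canonical genes by start coordinate, drops non-coding
#' regions, and anchors the circle by rotating the chosen gene to front
#' (comparisons themselves are rotation-invariant; anchoring only
#' normalises printing).
#'
#' @param features Complete feature tibble, or a character vector already
#'   giving the circular order.
#' @param genome_id Identifier carried on the result.
#' @param anchor Gene rotated to the first position (default `cox1`).
#' @return Object of class `mito_gene_order` (character vector of gene
#'   labels with attributes).
#' @export
gene_order <- function(features, genome_id = "genome", anchor = "cox1") {
  if (is.character(features)) {
    genes <- features
  } else {
    features <- validate_features(features, complete = TRUE)
    genes <- features$gene[features$class != "NCR"]
  }
  if (anyDuplicated(genes)) abort("duplicate genes in order")
  if (!anchor %in% genes) abort(paste0("anchor gene ", anchor, " not in order"))
  i <- match(anchor, genes)
  genes <- c(genes[i:length(genes)], genes[seq_len(i - 1L)])
  structure(genes, class = "mito_gene_order", genome_id = genome_id,
            anchor = anchor)
}

#' @export
print.mito_gene_order <- function(x, ...) {
  cat(sprintf("<mito_gene_order> %s (%d genes, anchored at %s)\n",
              attr(x, "genome_id"), length(x), attr(x, "anchor")))
  cat(" ", paste(unclass(x), collapse = " > "), "\n")
  invisible(x)
}

#' Directed adjacency set of a circular gene order
#'
#' @param order A [gene_order()] (or character vector).
#' @return Tibble `from`, `to` with one row per adjacency (n rows for n
#'   genes, including the wrap-around pair).
#' @export
adjacencies <- function(order) {
  genes <- as.character(order)
  n <- length(genes)
  tibble(from = genes, to = genes[c(2:n, 1L)])
}

order_universe_check <- function(orders) {
  sets <- map(orders, function(o) sort(as.character(o)))
  if (!all(map_lgl(sets[-1], identical, sets[[1]]))) {
    abort("gene orders are over different gene universes")
  }
  invisible(sets[[1]])
}

#' Adjacencies shared by two or more gene orders
#'
#' @param ... Two or more [gene_order()] objects (or a single list of them).
#' @return Tibble `from`, `to`: the intersection of the directed adjacency
#'   sets, in the order of the first input.
#' @export
shared_adjacencies <- function(...) {
  orders <- list(...)
  if (length(orders) == 1L && is.list(orders[[1]]) &&
        !inherits(orders[[1]], "mito_gene_order")) {
    orders <- orders[[1]]
  }
  if (length(orders) < 2L) abort("need at least two gene orders")
  order_universe_check(orders)
  keys <- map(orders, function(o) {
    adj <- adjacencies(o)
    paste(adj$from, adj$to, sep = "\r")
  })
  shared <- Reduce(intersect, keys)
  adj1 <- adjacencies(orders[[1]])
  adj1[paste(adj1$from, adj1$to, sep = "\r") %in% shared, ]
}

#' Breakpoint distance between two circular gene orders
#'
#' The number of adjacencies of one order absent from the other:
#' `n - |shared adjacencies|`. Symmetric, non-negative, zero iff the two
#' circular orders are identical up to rotation, and satisfies the triangle
#' inequality.
#'
#' @param a,b [gene_order()] objects over the same gene universe.
#' @return Integer distance.
#' @export
breakpoint_distance <- function(a, b) {
  length(as.character(a)) - nrow(shared_adjacencies(a, b))
}

#' Pairwise breakpoint distance matrix
#'
#' @param orders Named list of [gene_order()] objects.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
breakpoint_matrix <- function(orders) {
  ids <- names(orders) %||% map_chr(orders, attr, "genome_id")
  n <- length(orders)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- breakpoint_distance(orders[[i]], orders[[j]])
    }
  }
  m
}

#' Genes whose neighbourhood differs between two orders
#'
#' @param a,b [gene_order()] objects over the same universe.
#' @return Tibble with one row per gene whose (predecessor, successor) pair
#'   differs: `gene`, `pred_a`, `succ_a`, `pred_b`, `succ_b`.
#' @export
translocation_report <- function(a, b) {
  order_universe_check(list(a, b))
  ctx <- function(o) {
    genes <- as.character(o)
    n <- length(genes)
    tibble(gene = genes, pred = genes[c(n, seq_len(n - 1L))],
           succ = genes[c(2:n, 1L)])
  }
  ca <- ctx(a)
  cb <- ctx(b)
  cb <- cb[match(ca$gene, cb$gene), ]
  moved <- ca$pred != cb$pred | ca$succ != cb$succ
  tibble(gene = ca$gene[moved],
         pred_a = ca$pred[moved], succ_a = ca$succ[moved],
         pred_b = cb$pred[moved], succ_b = cb$succ[moved])
}

#' Neighbor-joining tree from a breakpoint distance matrix
#'
#' Standard neighbor-joining (via \pkg{ape}) with negative branch lengths
#' clamped to zero.
#'
#' @param d Symmetric zero-diagonal distance matrix (or `dist`), >= 3 taxa.
#' @param newick Optional path; when given the tree is also written as
#'   Newick.
#' @return An \pkg{ape} `phylo` tree.
#' @export
gene_order_tree <- function(d, newick = NULL) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) abort("need at least three taxa")
  if (!isTRUE(all.equal(m, t(m)))) abort("distance matrix is not symmetric")
  if (any(diag(m) != 0)) abort("distance matrix diagonal must be zero")
  tree <- ape::nj(stats::as.dist(m))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(newick)) ape::write.tree(tree, file = newick)
  tree
}

#' Read gene orders from a tab-separated file
#'
#' One genome per line: `genome_id<TAB>comma-separated gene labels`.
#'
#' @param path Input path.
#' @param anchor Anchor gene for all orders.
#' @return Named list of [gene_order()] objects.
#' @export
read_gene_orders <- function(path, anchor = "cox1") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(paste0("malformed gene-order line(s) ", paste(bad, collapse = ", ")))
  }
  out <- map(parts, function(p) {
    gene_order(trimws(strsplit(p[2], ",", fixed = TRUE)[[1]]),
               genome_id = p[1], anchor = anchor)
  })
  setNames(out, map_chr(parts, 1))
}

#' Write gene orders to a tab-separated file
#'
#' @param orders Named list of [gene_order()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  ids <- names(orders) %||% map_chr(orders, attr, "genome_id")
  writeLines(paste0(ids, "\t",
                    map_chr(orders, function(o)
                      paste(as.character(o), collapse = ","))), path)
  invisible(path)
}
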