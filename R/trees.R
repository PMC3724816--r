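#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou--Nei agglomeration. On an additive matrix the generating
#' topology and branch lengths are recovered exactly. Negative branch-length
#' estimates (possible on non-additive input) are clamped to zero and the
#' deficit moved to the adjacent parent edge, with a warning.
#'
#' @param d Symmetric numeric matrix, zero diagonal, taxon dimnames,
#'   at least 2 taxa.
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  if (any(d < 0)) stop("negative entries in distance matrix")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must have taxon names")
  if (nrow(d) == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to zero")
    for (pass in 1:5) {
      neg <- which(tr$edge.length < 0)
      if (!length(neg)) break
      for (e in neg) {
        deficit <- tr$edge.length[e]
        tr$edge.length[e] <- 0
        parent <- which(tr$edge[, 2L] == tr$edge[e, 1L])
        if (length(parent) == 1L)
          tr$edge.length[parent] <- tr$edge.length[parent] + deficit
      }
    }
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# pairwise comparable columns (both sequences unambiguous ACGT) and
# mismatch proportion; shared by the JC distance and Eq.-5-style rates
.pairwise_p <- function(chm, valid, i, j) {
  ok <- valid[i, ] & valid[j, ]
  n <- sum(ok)
  if (n == 0L) return(c(p = NA_real_, n = 0))
  c(p = sum(chm[i, ok] != chm[j, ok]) / n, n = n)
}

#' Jukes--Cantor distance matrix from an alignment
#'
#' For each pair of sequences, columns with a gap or ambiguity code in
#' either sequence are excluded, p is the mismatch proportion over the
#' compared columns, and d = -(3/4) ln(1 - (4/3) p).
#'
#' @param alignment Named character vector of equal-length aligned
#'   nucleotide sequences (as from [read_alignment()]).
#' @return Symmetric distance matrix.
#' @export
jukes_cantor_distance <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 2L)
  if (is.null(names(alignment))) stop("alignment must be named")
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences must have equal length")
  chm <- do.call(rbind, lapply(alignment, .clean_seq))
  valid <- matrix(chm %in% c("A", "C", "G", "T"), nrow = nrow(chm))
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pn <- .pairwise_p(chm, valid, i, j)
    if (pn[["n"]] == 0L)
      stop("no comparable columns between ", names(alignment)[i],
           " and ", names(alignment)[j])
    p <- pn[["p"]]
    if (p >= 0.75)
      stop("JC distance undefined (saturation) for pair ",
           names(alignment)[i], " / ", names(alignment)[j],
           ": p = ", format(p))
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}

.check_same_leaves <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (k in seq_along(trees)) {
    if (!identical(sort(trees[[k]]$tip.label), ref))
      stop("tree ", k, " has a different leaf set")
  }
  invisible(ref)
}

#' Majority-rule consensus with support counts
#'
#' Retains bipartitions present in strictly more than half of the input
#' trees (a 50/50 split is excluded); the result may be multifurcating.
#' Supports are occurrence counts out of the number of trees, stored as
#' internal node labels; percentages are available via [support_table()].
#'
#' @param trees List of `phylo` trees on the same leaf set.
#' @return Consensus `phylo` with `node.label` = occurrence counts and
#'   attribute `n_trees`.
#' @export
majority_consensus <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  .check_same_leaves(trees)
  class(trees) <- "multiPhylo"
  ct <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(ct, trees, rooted = FALSE)
  counts[is.na(counts)] <- length(trees)  # the trivial all-taxa partition
  ct$node.label <- as.character(counts)
  attr(ct, "n_trees") <- length(trees)
  ct
}

#' Tabulate consensus supports as counts and percentages
#'
#' @param tree Consensus tree from [majority_consensus()] (or
#'   [bootstrap_trees()]).
#' @param n_trees Total tree count; defaults to the tree's `n_trees`
#'   attribute.
#' @return data.frame with `node`, `count`, `percent`.
#' @export
support_table <- function(tree, n_trees = attr(tree, "n_trees")) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$node.label))
  counts <- suppressWarnings(as.numeric(tree$node.label))
  data.frame(node = length(tree$tip.label) + seq_along(counts),
             count = counts,
             percent = if (is.null(n_trees)) NA_real_
                       else 100 * counts / n_trees)
}

#' Robinson--Foulds symmetric difference between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the
#' two trees.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @return Integer count.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  .check_same_leaves(list(t1, t2))
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

# resample k points with replacement from each ordered pair's point set and
# recompute tan(theta); returns the per-pair F table for one replicate
.resample_ftab <- function(pts_list, model, k, cutoff) {
  rows <- lapply(pts_list, function(p) {
    if (is.null(p$pts)) {         # no comparable points: ceiling fallback
      tt <- 1
    } else {
      idx <- sample.int(p$pts$n, k, replace = TRUE)
      m <- slope_m(mean(p$pts$x[idx]), mean(p$pts$y[idx]), cutoff)
      tt <- tan_theta(m, model$convention)
    }
    data.frame(query_taxon = p$query, subject_taxon = p$subject,
               tan_theta = tt, stringsAsFactors = FALSE)
  })
  sims <- do.call(rbind, rows)
  attr(sims, "convention") <- model$convention
  sims$AvE_X <- sims$AvE_Y <- NA_real_; sims$n <- k; sims$m <- NA_real_
  f_index_table(sims, model)
}

.pair_points_list <- function(tables, taxa, cutoff) {
  out <- list()
  for (x in taxa) for (y in taxa) {
    if (x == y) next
    self_tb <- tables[[.table_key(x, x)]]
    cross_tb <- tables[[.table_key(x, y)]]
    if (is.null(self_tb) || is.null(cross_tb))
      stop("missing best-match table for ordered pair ", x, " vs ", y)
    pts <- tryCatch(pair_points(self_tb, cross_tb), error = function(e) {
      if (grepl("no comparable points", conditionMessage(e))) {
        warning("pair ", x, " vs ", y,
                " has no comparable points; bootstrap uses tan(theta) = 1")
        NULL
      } else stop(e)
    })
    out[[length(out) + 1L]] <- list(query = x, subject = y, pts = pts)
  }
  out
}

#' Bootstrap by resampling best-matched protein pairs
#'
#' For each of B replicates and each ordered genome pair, k best-matched
#' (gene, E-value) points are drawn with replacement from the pair's point
#' set; tan(theta), the calibrated F values, the distance matrix and the
#' NJ tree are recomputed. Resampling is per ordered pair, so every matrix
#' entry stays defined in every replicate. Replicate r uses seed
#' `seed + r`, making individual replicates reproducible.
#'
#' @param tables List of best-match tables over the taxon set.
#' @param model An `ave_calibration` model.
#' @param B Number of replicates (default 100).
#' @param k Points resampled per ordered pair per replicate (default 1000).
#' @param index F index for the distance matrices (default `"F_AV"`).
#' @param seed Base random seed.
#' @inheritParams slope_m
#' @return List with `trees` (multiPhylo of B trees) and `consensus`
#'   (majority-rule tree with supports out of B).
#' @export
bootstrap_trees <- function(tables, model, B = 100, k = 1000,
                            index = "F_AV", seed = 1, cutoff = 1) {
  stopifnot(B >= 1, k >= 1)
  tables <- .index_tables(tables)
  taxa <- .taxa_of(tables)
  pts_list <- .pair_points_list(tables, taxa, cutoff)
  trees <- vector("list", B)
  for (r in seq_len(B)) {
    set.seed(seed + r)
    ftab <- .resample_ftab(pts_list, model, k, cutoff)
    trees[[r]] <- neighbor_joining(build_distance_matrix(ftab, index))
  }
  class(trees) <- "multiPhylo"
  list(trees = trees, consensus = majority_consensus(trees))
}

#' Gene-content reduction experiment
#'
#' Emulates rebuilding one genome's database from a random subsample of its
#' genes: in each of R replicates, `floor(fraction * N)` of the target
#' taxon's genes are drawn without replacement; every best-match table in
#' which the target is the query keeps only records for sampled query
#' genes, and every table in which it is the subject keeps only records
#' whose best match is a sampled gene. Trees are re-inferred for each
#' requested F index and summarised by a majority consensus whose supports
#' count identical branching patterns out of R.
#'
#' @param tables List of best-match tables.
#' @param target_taxon Taxon whose gene content is reduced.
#' @param fraction Fraction of genes kept, in (0, 1].
#' @param R Number of replicates (default 10).
#' @param model An `ave_calibration` model.
#' @param indices F indices to rebuild trees for (default all five).
#' @param seed Base random seed; replicate j uses `seed + j`.
#' @inheritParams slope_m
#' @return Named list per index: list with `trees` (R trees) and
#'   `consensus` (agreement counts out of R as node labels).
#' @export
gene_reduction_experiment <- function(tables, target_taxon, fraction,
                                      R = 10, model,
                                      indices = c("F_AV", "F_XY", "F_YX",
                                                  "F_H", "F_L"),
                                      seed = 1, cutoff = 1) {
  stopifnot(fraction > 0, fraction <= 1, R >= 1)
  tables <- .index_tables(tables)
  self_key <- .table_key(target_taxon, target_taxon)
  if (is.null(tables[[self_key]]))
    stop("no self table for target taxon ", target_taxon)
  genes <- tables[[self_key]]$records$query_gene
  keep_n <- floor(fraction * length(genes))
  if (keep_n < 10L)
    stop("subsample of ", keep_n, " genes is too small (need >= 10)")
  per_index_trees <- stats::setNames(
    lapply(indices, function(i) vector("list", R)), indices)
  for (j in seq_len(R)) {
    set.seed(seed + j)
    kept <- sample(genes, keep_n, replace = FALSE)
    reduced <- lapply(tables, function(tb) {
      rec <- tb$records
      if (tb$query_taxon == target_taxon)
        rec <- rec[rec$query_gene %in% kept, , drop = FALSE]
      if (tb$subject_taxon == target_taxon)
        rec <- rec[rec$subject_gene %in% kept, , drop = FALSE]
      best_match_table(tb$query_taxon, tb$subject_taxon,
                       rec$query_gene, rec$subject_gene, rec$logE)
    })
    sims <- tantheta_safe(reduced, cutoff = cutoff,
                          convention = model$convention)
    ftab <- f_index_table(sims, model)
    for (ix in indices) {
      per_index_trees[[ix]][[j]] <-
        neighbor_joining(build_distance_matrix(ftab, ix))
    }
  }
  lapply(per_index_trees, function(trs) {
    class(trs) <- "multiPhylo"
    list(trees = trs, consensus = majority_consensus(trs))
  })
}

#' Root a tree at a declared out-group
#'
#' Tree construction in this package is unrooted; rooting is a display
#' step applied afterwards.
#'
#' @param tree `phylo` tree.
#' @param outgroup Tip label to root on.
#' @return Rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("out-group '", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
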