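test_that("NJ solves the three-taxon closed form", {
  nm <- c("A", "B", "C")
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3, dimnames = list(nm, nm))
  tr <- neighbor_joining(d)
  pend <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(pend[["A"]], 1)
  expect_equal(pend[["B"]], 3)
  expect_equal(pend[["C"]], 5)
})

test_that("NJ recovers the generating 4-taxon tree and internal edge", {
  # additive matrix of ((A:1,B:2):1,(C:3,D:4))
  truth <- parse_newick("((A:1,B:2):1,(C:3,D:4));")
  d <- gen_additive_matrix(truth)
  expect_equal(d["A", "B"], 3); expect_equal(d["A", "C"], 5)
  expect_equal(d["A", "D"], 6); expect_equal(d["B", "C"], 6)
  expect_equal(d["B", "D"], 7); expect_equal(d["C", "D"], 7)
  tr <- neighbor_joining(d)
  expect_equal(rf_distance(tr, truth), 0L)  # split AB|CD
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_equal(tr$edge.length[internal], 1)
})

test_that("NJ handles two taxa and rejects bad input", {
  nm <- c("A", "B")
  d <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(nm, nm))
  tr <- neighbor_joining(d)
  expect_equal(sum(tr$edge.length), 7)
  expect_equal(sort(tr$tip.label), nm)

  bad <- matrix(c(0, NaN, NaN, 0), 2, 2, dimnames = list(nm, nm))
  expect_error(neighbor_joining(bad), "non-finite")
  neg <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(nm, nm))
  expect_error(neighbor_joining(neg), "negative")
})

test_that("Jukes-Cantor distances match the closed form and saturate", {
  mk <- function(n_diff, n = 100) {
    a <- strrep("A", n)
    b <- paste0(strrep("C", n_diff), strrep("A", n - n_diff))
    c(s1 = a, s2 = b)
  }
  expect_equal(jukes_cantor_distance(mk(0))["s1", "s2"], 0)
  expect_equal(jukes_cantor_distance(mk(10))["s1", "s2"],
               -0.75 * log(1 - 4 * 0.1 / 3))  # = 0.107326 at 6 digits
  expect_equal(jukes_cantor_distance(mk(10))["s1", "s2"], 0.107326,
               tolerance = 1e-5)
  expect_true(is.finite(jukes_cantor_distance(mk(74))["s1", "s2"]))
  expect_error(jukes_cantor_distance(mk(75)), "saturation")
  expect_error(jukes_cantor_distance(mk(80)), "s1")
})

test_that("JC distances agree with the reference implementation", {
  tr <- rand_tree(5, seed = 17, min_br = 0.02, max_br = 0.2)
  aln <- evolve_sequences(tr, length = 500, seed = 3)
  ours <- jukes_cantor_distance(aln)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(ours, ref[rownames(ours), colnames(ours)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("majority consensus keeps strict-majority bipartitions", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  t2 <- parse_newick("((A,C),(B,D),E);")

  all_same <- rep(list(t1), 100)
  cons <- majority_consensus(all_same)
  expect_equal(rf_distance(cons, t1), 0L)
  expect_true(all(as.numeric(cons$node.label) == 100))

  mixed <- c(rep(list(t1), 60), rep(list(t2), 40))
  cons2 <- majority_consensus(mixed)
  expect_equal(rf_distance(cons2, t1), 0L)  # AB|CD retained
  counts <- as.numeric(cons2$node.label)
  expect_true(60 %in% counts)

  tied <- c(rep(list(t1), 50), rep(list(t2), 50))
  cons3 <- majority_consensus(tied)
  expect_equal(cons3$Nnode, 1L)  # 50/50 bipartitions excluded -> star

  t3 <- parse_newick("((A,B),(C,F),E);")
  expect_error(majority_consensus(list(t1, t3)), "different leaf set")
})

test_that("Robinson-Foulds distance is a symmetric bipartition count", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  expect_equal(rf_distance(t1, t1), 0L)
  t2 <- parse_newick("((A,C),(B,D),E);")
  expect_equal(rf_distance(t1, t2), 4L)  # both non-trivial splits differ
  # 4-leaf case: one resolution vs the alternative differs by 2
  q1 <- parse_newick("((A,B),(C,D));")
  q2 <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(q1, q2), 2L)
  set.seed(19)
  for (i in 1:5) {
    a <- rand_tree(7); b <- rand_tree(7)
    b$tip.label <- sample(a$tip.label)
    expect_equal(rf_distance(a, b), rf_distance(b, a))
  }
})

test_that("bootstrap replicates are seeded and order-invariant", {
  fx <- fixture8()
  b1 <- bootstrap_trees(fx$tables, fx$model, B = 5, k = 50, seed = 42)
  b2 <- bootstrap_trees(fx$tables, fx$model, B = 5, k = 50, seed = 42)
  expect_identical(lapply(b1$trees, write_newick),
                   lapply(b2$trees, write_newick))
  b3 <- bootstrap_trees(fx$tables, fx$model, B = 5, k = 50, seed = 43)
  expect_false(identical(lapply(b1$trees, write_newick),
                         lapply(b3$trees, write_newick)))
})

test_that("degenerate point sets give the point-estimate tree everywhere", {
  # every pair's points are identical, so any resample is the same
  taxa <- c("A", "B", "C", "D")
  consts <- c(A = -40, B = -60, C = -80, D = -100)
  cross_y <- function(x, m) 1 + m * (x - 1)
  m_tab <- matrix(0.5, 4, 4, dimnames = list(taxa, taxa))
  m_tab["A", "B"] <- m_tab["B", "A"] <- 0.9
  tables <- list()
  for (x in taxa) {
    g <- paste0(x, 1:20)
    tables <- c(tables, list(bmt(x, x, g, rep(consts[[x]], 20))))
    for (y in setdiff(taxa, x)) {
      tables <- c(tables, list(
        bmt(x, y, g, rep(cross_y(consts[[x]], m_tab[x, y]), 20),
            subj = paste0(y, 1:20))))
    }
  }
  model <- calibration_preset()
  point <- neighbor_joining(genome_distance_matrix(tables, model))
  boot <- bootstrap_trees(tables, model, B = 20, k = 15, seed = 3)
  for (tr in boot$trees) expect_equal(rf_distance(tr, point), 0L)
  expect_true(all(as.numeric(boot$consensus$node.label) == 20))
})

test_that("gene reduction at fraction 1 reproduces the full-data trees", {
  fx <- fixture8()
  full <- neighbor_joining(genome_distance_matrix(fx$tables, fx$model))
  target <- fx$tree$tip.label[1]
  res <- gene_reduction_experiment(fx$tables, target, fraction = 1,
                                   R = 3, model = fx$model, seed = 5)
  for (tr in res$F_AV$trees) expect_equal(rf_distance(tr, full), 0L)
  expect_true(all(as.numeric(res$F_AV$consensus$node.label) == 3))
})

test_that("gene reduction refuses a statistically meaningless subsample", {
  tables <- gen_best_hit_tables(c("A", "B"), gene_count = 50,
                                target_m = 0.5, seed = 1)
  expect_error(
    gene_reduction_experiment(tables, "A", fraction = 0.1, R = 2,
                              model = calibration_preset()),
    "too small")
})

test_that("rooting at the out-group is a display step", {
  tr <- rand_tree(6, seed = 23)
  rooted <- root_at_outgroup(tr, tr$tip.label[1])
  expect_true(ape::is.rooted(rooted))
  expect_equal(rf_distance(ape::unroot(rooted), tr), 0L)
  expect_error(root_at_outgroup(tr, "nope"), "not a leaf")
})
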