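# Fixtures are built in code at test time; nothing is stored on disk.

# hand-built best-match table
bmt <- function(q, s, genes, logE, subj = genes) {
  best_match_table(q, s, genes, subj, logE)
}

# random unrooted tree with branch lengths inside the calibration range
rand_tree <- function(n, seed = NULL, min_br = 0.5, max_br = 2.5) {
  if (!is.null(seed)) set.seed(seed)
  ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, min_br, max_br)))
}

# the 8-taxon reference fixture used by the end-to-end and gene-reduction
# checks: noiseless tables whose F_AV distances equal the tree's path
# lengths
fixture8 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- calibration_preset()
      tree <- rand_tree(8, seed = 101)
      tables <- gen_tables_from_tree(tree, model, gene_count = 300,
                                     noise_sd = 0, seed = 7)
      cache <<- list(tree = tree, tables = tables, model = model)
    }
    cache
  }
})

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
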