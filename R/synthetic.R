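#' Invert the tan(theta) convention back to the slope m
#'
#' @param tan_theta Values in `[0, 1]`.
#' @param convention `"angle"` or `"complement"`.
#' @return Slope m in `[0, 1]`.
#' @export
m_from_tantheta <- function(tan_theta, convention = c("angle", "complement")) {
  convention <- match.arg(convention)
  if (any(tan_theta < 0 | tan_theta > 1)) stop("tan_theta outside [0, 1]")
  if (convention == "angle") (1 - tan_theta) / (1 + tan_theta)
  else 1 - tan_theta
}

#' Generate synthetic best-match tables with controlled slope
#'
#' Synthesises the E-value geometry of a genome comparison directly,
#' without emulating a search engine. Self tables draw log10 E-values
#' uniformly in `[-180, -5]` (mimicking the length-driven spread of
#' self-match E-values); the cross-table point for gene i is
#' `y_i = C_OV + m * (x_i - C_OV) + noise`, clipped to `[-180, C_OV]`, so
#' with zero noise the recomputed slope equals the target m exactly.
#' Cross-table best-match partners are drawn uniformly from the subject
#' taxon's genes.
#'
#' @param taxa Character vector of taxon labels.
#' @param gene_count Genes per taxon: scalar or named vector.
#' @param target_m Target slope(s): scalar, or a matrix with taxa dimnames
#'   where `target_m[X, Y]` is the slope for X queried against Y.
#' @param noise_sd Gaussian spread of the cross log E-value around its
#'   conditional mean (log10 units; default 0).
#' @param cutoff C_OV on the log10 scale (default 1).
#' @param seed Random seed.
#' @return Named list of `best_match_table` objects covering every self
#'   and ordered cross comparison.
#' @export
gen_best_hit_tables <- function(taxa, gene_count, target_m, noise_sd = 0,
                                cutoff = 1, seed = 1) {
  stopifnot(length(taxa) >= 2L, !anyDuplicated(taxa))
  if (length(gene_count) == 1L)
    gene_count <- stats::setNames(rep(gene_count, length(taxa)), taxa)
  stopifnot(all(taxa %in% names(gene_count)), all(gene_count >= 1))
  m_of <- function(x, y) {
    m <- if (is.matrix(target_m)) target_m[x, y] else target_m
    if (m < 0 || m > 1) stop("target_m outside [0, 1] for pair ",
                             x, " vs ", y)
    m
  }
  set.seed(seed)
  taxa <- sort(taxa)
  genes <- lapply(stats::setNames(taxa, taxa), function(tx)
    paste0(tx, "_g", seq_len(gene_count[[tx]])))
  selfE <- lapply(stats::setNames(taxa, taxa), function(tx)
    stats::runif(gene_count[[tx]], -180, -5))
  tables <- list()
  for (x in taxa) {
    tables[[length(tables) + 1L]] <-
      best_match_table(x, x, genes[[x]], genes[[x]], selfE[[x]])
  }
  for (x in taxa) for (y in taxa) {
    if (x == y) next
    m <- m_of(x, y)
    xs <- selfE[[x]]
    ys <- cutoff + m * (xs - cutoff)
    if (noise_sd > 0) ys <- ys + stats::rnorm(length(ys), 0, noise_sd)
    ys <- pmin(pmax(ys, -180), cutoff)
    partners <- sample(genes[[y]], length(xs), replace = TRUE)
    tables[[length(tables) + 1L]] <-
      best_match_table(x, y, genes[[x]], partners, ys)
  }
  .index_tables(tables)
}

#' Best-match tables whose distances realise a given tree
#'
#' Derives the per-pair target slope from the tree's path-length distances
#' through the inverse calibration, then generates tables with
#' [gen_best_hit_tables()]. With zero noise, the pipeline
#' tan(theta) -> F -> distance matrix reproduces the tree's distances and
#' NJ recovers its topology exactly.
#'
#' @param tree `phylo` tree with branch lengths on the
#'   percent-substitution (S) scale; all pairwise path lengths must stay
#'   inside the calibration's range.
#' @param model An `ave_calibration` model.
#' @inheritParams gen_best_hit_tables
#' @return Named list of `best_match_table` objects.
#' @export
gen_tables_from_tree <- function(tree, model, gene_count, noise_sd = 0,
                                 cutoff = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "ave_calibration"))
  d <- gen_additive_matrix(tree)
  tt <- S_to_tantheta(model, d)
  m <- m_from_tantheta(pmin(pmax(tt, 0), 1), model$convention)
  diag(m) <- 1
  gen_best_hit_tables(rownames(d), gene_count, target_m = m,
                      noise_sd = noise_sd, cutoff = cutoff, seed = seed)
}

#' Generate calibration pairs with known constants
#'
#' tan(theta) is uniform on `[0, 1]`; S follows the exponential
#' calibration with optional multiplicative Gaussian noise, floored at 0.
#'
#' @param n Number of pairs.
#' @param const1,const2 Generating constants (defaults are the published
#'   values 5.0112 and 2.2223).
#' @param noise_fraction Standard deviation of the multiplicative noise
#'   (e.g. 0.10 for 10 percent).
#' @param seed Random seed.
#' @param form Calibration form, as in [fit_calibration()].
#' @return data.frame with columns `tan_theta`, `S`.
#' @export
gen_calibration_pairs <- function(n, const1 = 5.0112, const2 = 2.2223,
                                  noise_fraction = 0, seed = 1,
                                  form = c("exp_minus_one", "exp")) {
  form <- match.arg(form)
  stopifnot(n >= 1)
  set.seed(seed)
  t <- stats::runif(n)
  S <- .calib_fun(form)(t, const1, const2)
  if (noise_fraction > 0)
    S <- S * (1 + stats::rnorm(n, 0, noise_fraction))
  data.frame(tan_theta = t, S = pmax(S, 0))
}

#' Additive distance matrix of a tree
#'
#' Entry (i, j) is the path length between leaves i and j; the oracle for
#' NJ-recovery and additivity tests.
#'
#' @param tree `phylo` with branch lengths.
#' @return Symmetric matrix with leaf dimnames.
#' @export
gen_additive_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  internal <- tree$edge[, 2L] > length(tree$tip.label)
  # an absent root-edge length (rooted Newick) is not a zero-length branch
  has_len <- internal & !is.na(tree$edge.length)
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length[has_len] <= 0))
    warning("non-positive internal branch length; matrix may not identify ",
            "the topology")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Evolve sequences along a tree under the Jukes--Cantor model
#'
#' The root sequence is uniform over ACGT; substitutions accumulate along
#' each branch at the branch's length in expected substitutions per site.
#' The output is a gapless alignment.
#'
#' @param tree `phylo` with branch lengths in expected substitutions per
#'   site.
#' @param length Sequence length (>= 1).
#' @param seed Random seed.
#' @return Named character vector of aligned sequences, one per leaf.
#' @export
evolve_sequences <- function(tree, length, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (length < 1) stop("sequence length must be >= 1")
  set.seed(seed)
  sim <- phangorn::simSeq(tree, l = length, type = "DNA")
  chm <- toupper(as.character(sim))
  out <- apply(chm, 1L, paste, collapse = "")
  out[tree$tip.label]
}

#' Write a proteome-like FASTA file
#'
#' Small helper so synthetic fixtures can exercise the real parsers.
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}
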