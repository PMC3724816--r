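.F_INDICES <- c("F_AV", "F_XY", "F_YX", "F_H", "F_L")

#' Combine the two orientations of a calibrated genome distance
#'
#' For one genome pair, F_XY (X queried against Y) and F_YX generally
#' differ. The indices are: F_AV the mean of the two, F_H the higher,
#' F_L the lower, and F_XY / F_YX the named orientation passed through.
#'
#' @param F_XY,F_YX Calibrated distances for the two orientations
#'   (vectors of equal length are accepted).
#' @param index One of `"F_AV"`, `"F_XY"`, `"F_YX"`, `"F_H"`, `"F_L"`.
#' @return Numeric distance value(s).
#' @export
combine_F <- function(F_XY, F_YX, index = "F_AV") {
  if (!index %in% .F_INDICES)
    stop("unknown index '", index, "'; must be one of ",
         paste(.F_INDICES, collapse = ", "))
  if (any(F_XY < 0) || any(F_YX < 0)) stop("F values must be non-negative")
  switch(index,
         F_AV = (F_XY + F_YX) / 2,
         F_XY = F_XY,
         F_YX = F_YX,
         F_H  = pmax(F_XY, F_YX),
         F_L  = pmin(F_XY, F_YX))
}

#' Per-pair F values from tan(theta) statistics
#'
#' Applies the calibration to each ordered pair's tan(theta) and tabulates
#' the two orientations side by side.
#'
#' @param sims data.frame from [tantheta_matrix()].
#' @param model An `ave_calibration` model; its convention must match the
#'   one the statistics were computed under.
#' @return data.frame with one row per unordered pair: `taxon_x`,
#'   `taxon_y` (x sorts before y), `F_XY`, `F_YX`, `F_AV`, `F_H`, `F_L`.
#' @export
f_index_table <- function(sims, model) {
  stopifnot(inherits(model, "ave_calibration"))
  conv <- attr(sims, "convention")
  if (!is.null(conv) && !identical(conv, model$convention))
    stop("tan(theta) convention mismatch: statistics are '", conv,
         "', model is '", model$convention, "'")
  Fv <- predict(model, sims$tan_theta)
  taxa <- sort(unique(c(sims$query_taxon, sims$subject_taxon)))
  rows <- list()
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i >= j) next
    x <- taxa[i]; y <- taxa[j]
    ixy <- which(sims$query_taxon == x & sims$subject_taxon == y)
    iyx <- which(sims$query_taxon == y & sims$subject_taxon == x)
    if (length(ixy) != 1L || length(iyx) != 1L)
      stop("missing ordered pair ", x, " vs ", y, " in similarity table")
    fxy <- Fv[ixy]; fyx <- Fv[iyx]
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_x = x, taxon_y = y, F_XY = fxy, F_YX = fyx,
      F_AV = combine_F(fxy, fyx, "F_AV"),
      F_H = combine_F(fxy, fyx, "F_H"),
      F_L = combine_F(fxy, fyx, "F_L"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assemble a symmetric distance matrix for a chosen F index
#'
#' Diagonal is zero. For F_AV / F_H / F_L the matrix is symmetric by
#' construction. For the oriented indices F_XY / F_YX, which a
#' distance-based tree program still needs as a symmetric matrix, the
#' orientation is fixed by label order: for the pair (x, y) with x sorting
#' before y, F_XY uses x as the query and F_YX uses y as the query, and
#' the single value fills both cells.
#'
#' @param ftab data.frame from [f_index_table()].
#' @param index One of `"F_AV"`, `"F_XY"`, `"F_YX"`, `"F_H"`, `"F_L"`.
#' @return Symmetric numeric matrix with taxon dimnames and attribute
#'   `index`.
#' @export
build_distance_matrix <- function(ftab, index = "F_AV") {
  if (!index %in% .F_INDICES)
    stop("unknown index '", index, "'")
  taxa <- sort(unique(c(ftab$taxon_x, ftab$taxon_y)))
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (k in seq_len(nrow(ftab))) {
    i <- match(ftab$taxon_x[k], taxa)
    j <- match(ftab$taxon_y[k], taxa)
    v <- combine_F(ftab$F_XY[k], ftab$F_YX[k], index)
    d[i, j] <- v
    d[j, i] <- v
  }
  found <- ftab[, c("taxon_x", "taxon_y")]
  want <- t(utils::combn(taxa, 2L))
  have <- paste(found$taxon_x, found$taxon_y)
  need <- paste(want[, 1L], want[, 2L])
  if (any(!need %in% have))
    stop("missing pair(s): ", paste(need[!need %in% have], collapse = "; "))
  attr(d, "index") <- index
  d
}

#' Genome distance matrix straight from best-match tables
#'
#' Runs the full similarity -> calibration -> F-index chain. A pair with
#' zero shared points (no gene of one genome has any admissible best match
#' in the other) is assigned the calibration's value at tan(theta) = 1 --
#' the no-similarity ceiling -- with a warning, instead of aborting the
#' whole matrix.
#'
#' @param tables List of best-match tables (self tables for every taxon,
#'   cross tables for every ordered pair).
#' @param model An `ave_calibration` model.
#' @param index F index for the matrix (default `"F_AV"`).
#' @inheritParams slope_m
#' @return Symmetric numeric matrix; attribute `f_table` holds the per-pair
#'   F values.
#' @export
genome_distance_matrix <- function(tables, model, index = "F_AV",
                                   cutoff = 1) {
  sims <- tantheta_safe(tables, cutoff = cutoff,
                        convention = model$convention)
  ftab <- f_index_table(sims, model)
  d <- build_distance_matrix(ftab, index)
  attr(d, "f_table") <- ftab
  d
}

# tantheta_matrix with the zero-shared-points fallback: tan(theta) = 1
tantheta_safe <- function(tables, cutoff = 1, convention = "angle") {
  tables <- .index_tables(tables)
  taxa <- .taxa_of(tables)
  rows <- list()
  for (x in taxa) for (y in taxa) {
    if (x == y) next
    self_tb <- tables[[.table_key(x, x)]]
    cross_tb <- tables[[.table_key(x, y)]]
    if (is.null(self_tb) || is.null(cross_tb))
      stop("missing best-match table for ordered pair ", x, " vs ", y)
    sim <- tryCatch(
      pair_similarity(self_tb, cross_tb, cutoff = cutoff,
                      convention = convention),
      error = function(e) {
        if (grepl("no comparable points", conditionMessage(e))) {
          warning("pair ", x, " vs ", y,
                  " has no comparable points; using tan(theta) = 1")
          list(query_taxon = x, subject_taxon = y, AvE_X = NA_real_,
               AvE_Y = NA_real_, n = 0L, m = 0, tan_theta = 1,
               convention = convention)
        } else stop(e)
      })
    rows[[length(rows) + 1L]] <-
      data.frame(query_taxon = x, subject_taxon = y, AvE_X = sim$AvE_X,
                 AvE_Y = sim$AvE_Y, n = sim$n, m = sim$m,
                 tan_theta = sim$tan_theta, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "convention") <- convention
  attr(out, "cutoff") <- cutoff
  out
}

#' Write the per-pair similarity diagnostics as TSV
#'
#' @param sims data.frame from [tantheta_matrix()] or [f_index_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sims, path) {
  utils::write.table(sims, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
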