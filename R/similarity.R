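#' Two-dimensional point set for an ordered genome pair
#'
#' Joins a taxon's self best-match table (query X vs database X; the x
#' coordinates) with its cross table against another genome (query X vs
#' database Y; the y coordinates). One point per query gene present in both
#' tables: genes without a cross-genome best match below the cut-off
#' contribute no point, since a point needs both coordinates.
#'
#' @param self_table Best-match table of taxon X against itself.
#' @param cross_table Best-match table of taxon X against taxon Y.
#' @return An object of class `pair_points`: list with `query_taxon`,
#'   `subject_taxon`, `genes`, `x`, `y`, `n`.
#' @export
pair_points <- function(self_table, cross_table) {
  stopifnot(inherits(self_table, "best_match_table"),
            inherits(cross_table, "best_match_table"))
  if (self_table$query_taxon != self_table$subject_taxon)
    stop("self_table is not a self-comparison: ",
         self_table$query_taxon, " vs ", self_table$subject_taxon)
  if (cross_table$query_taxon != self_table$query_taxon)
    stop("taxon mismatch: self table is for ", self_table$query_taxon,
         ", cross table queries ", cross_table$query_taxon)
  idx <- match(self_table$records$query_gene, cross_table$records$query_gene)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no comparable points between ", cross_table$query_taxon,
         " and ", cross_table$subject_taxon)
  structure(list(query_taxon = cross_table$query_taxon,
                 subject_taxon = cross_table$subject_taxon,
                 genes = self_table$records$query_gene[keep],
                 x = self_table$records$logE[keep],
                 y = cross_table$records$logE[idx[keep]],
                 n = sum(keep)),
            class = "pair_points")
}

#' Averaged coordinates of a pair point set
#'
#' The arithmetic means of the x (self) and y (cross) log10 E-values over
#' the n plotted points.
#'
#' @param points A [pair_points()] object.
#' @return Named numeric vector `c(AvE_X, AvE_Y)`.
#' @export
average_coordinates <- function(points) {
  stopifnot(inherits(points, "pair_points"))
  if (points$n < 1L) stop("no points to average")
  c(AvE_X = mean(points$x), AvE_Y = mean(points$y))
}

#' Genome-pair similarity slope m
#'
#' The slope of the line through the shifted origin: the cut-off value
#' C_OV (on the log10 scale) is subtracted from both averaged coordinates
#' so that the no-similarity corner of the scatter plot becomes the origin,
#' and m = (AvE_Y - C_OV) / (AvE_X - C_OV). m = 1 for identical genomes
#' and m = 0 when every cross best match sits at the cut-off. Values
#' pushed marginally outside [0, 1] by sampling noise are clamped, with a
#' warning if the excursion exceeds 1e-9.
#'
#' @param AvE_X,AvE_Y Averaged self and cross log10 E-values.
#' @param cutoff C_OV on the log10 scale (default 1, i.e. raw E-value 10).
#' @return Slope m in `[0, 1]`.
#' @export
slope_m <- function(AvE_X, AvE_Y, cutoff = 1) {
  if (AvE_X == cutoff)
    stop("degenerate self-comparison: AvE_X equals the cut-off")
  if (AvE_X > cutoff) stop("AvE_X above the cut-off")
  m <- (AvE_Y - cutoff) / (AvE_X - cutoff)
  if (m < -1e-9 || m > 1 + 1e-9)
    warning("slope m = ", format(m), " outside [0,1]; clamped")
  min(max(m, 0), 1) + 0  # "+ 0" normalises IEEE negative zero
}

#' Dissimilarity statistic tan(theta) from the slope m
#'
#' theta is the angle between the pair's regression line (slope m through
#' the shifted origin) and the identity diagonal (slope 1). Two conventions
#' are supported: `"angle"` (default) is the exact tangent of that angle,
#' (1 - m)/(1 + m); `"complement"` is the simple difference 1 - m. Both
#' equal 0 at m = 1 (identical genomes) and 1 at m = 0 (no similarity).
#'
#' @param m Slope in `[0, 1]`.
#' @param convention `"angle"` or `"complement"`.
#' @return tan(theta) in `[0, 1]`.
#' @export
tan_theta <- function(m, convention = c("angle", "complement")) {
  convention <- match.arg(convention)
  if (any(m < 0) || any(m > 1)) stop("m must lie in [0, 1]")
  if (convention == "angle") (1 - m) / (1 + m) else 1 - m
}

#' Similarity statistics for one ordered genome pair
#'
#' Convenience wrapper: joins the self and cross tables, averages the
#' coordinates, and computes m and tan(theta).
#'
#' @inheritParams pair_points
#' @inheritParams slope_m
#' @inheritParams tan_theta
#' @return List with `query_taxon`, `subject_taxon`, `AvE_X`, `AvE_Y`,
#'   `n`, `m`, `tan_theta`, `convention`.
#' @export
pair_similarity <- function(self_table, cross_table, cutoff = 1,
                            convention = c("angle", "complement")) {
  convention <- match.arg(convention)
  pts <- pair_points(self_table, cross_table)
  av <- average_coordinates(pts)
  m <- slope_m(av[["AvE_X"]], av[["AvE_Y"]], cutoff)
  list(query_taxon = pts$query_taxon, subject_taxon = pts$subject_taxon,
       AvE_X = av[["AvE_X"]], AvE_Y = av[["AvE_Y"]], n = pts$n,
       m = m, tan_theta = tan_theta(m, convention), convention = convention)
}

.table_key <- function(q, s) paste(q, s, sep = "\r")

.index_tables <- function(tables) {
  stopifnot(is.list(tables),
            all(vapply(tables, inherits, TRUE, "best_match_table")))
  keys <- vapply(tables, function(tb) .table_key(tb$query_taxon,
                                                 tb$subject_taxon), "")
  if (anyDuplicated(keys)) stop("duplicate table for an ordered taxon pair")
  names(tables) <- keys
  tables
}

.taxa_of <- function(tables) {
  sort(unique(unlist(lapply(tables, function(tb)
    c(tb$query_taxon, tb$subject_taxon)))))
}

#' tan(theta) for every ordered pair of taxa
#'
#' Computes the similarity statistics for all ordered pairs (X, Y), X != Y.
#' Both orientations are reported: the two statistics of a pair generally
#' differ because the underlying search results are asymmetric, and no
#' averaging happens at this stage.
#'
#' @param tables List of best-match tables containing a self table for
#'   every taxon and a cross table for every ordered pair.
#' @inheritParams slope_m
#' @inheritParams tan_theta
#' @return data.frame with one row per ordered pair: `query_taxon`,
#'   `subject_taxon`, `AvE_X`, `AvE_Y`, `n`, `m`, `tan_theta`.
#' @export
tantheta_matrix <- function(tables, cutoff = 1,
                            convention = c("angle", "complement")) {
  convention <- match.arg(convention)
  tables <- .index_tables(tables)
  taxa <- .taxa_of(tables)
  missing <- character(0)
  for (x in taxa) {
    if (is.null(tables[[.table_key(x, x)]]))
      missing <- c(missing, paste(x, "vs", x))
  }
  for (x in taxa) for (y in taxa) {
    if (x != y && is.null(tables[[.table_key(x, y)]]))
      missing <- c(missing, paste(x, "vs", y))
  }
  if (length(missing))
    stop("missing best-match table(s): ", paste(missing, collapse = "; "))
  rows <- list()
  for (x in taxa) for (y in taxa) {
    if (x == y) next
    sim <- pair_similarity(tables[[.table_key(x, x)]],
                           tables[[.table_key(x, y)]],
                           cutoff = cutoff, convention = convention)
    rows[[length(rows) + 1L]] <-
      data.frame(query_taxon = x, subject_taxon = y,
                 AvE_X = sim$AvE_X, AvE_Y = sim$AvE_Y, n = sim$n,
                 m = sim$m, tan_theta = sim$tan_theta,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "convention") <- convention
  attr(out, "cutoff") <- cutoff
  out
}

#' Restrict two best-match tables to reciprocal best hits
#'
#' Given the two orientations of one genome pair, keeps a record g -> h in
#' the X-vs-Y table only if the Y-vs-X table maps h back to g, and
#' symmetrically.
#'
#' @param xy Best-match table of X queried against Y.
#' @param yx Best-match table of Y queried against X.
#' @return List with filtered tables `xy` and `yx`.
#' @export
reciprocal_best_hits <- function(xy, yx) {
  stopifnot(inherits(xy, "best_match_table"),
            inherits(yx, "best_match_table"))
  if (xy$query_taxon != yx$subject_taxon ||
      xy$subject_taxon != yx$query_taxon)
    stop("tables are not the two orientations of one genome pair")
  back <- yx$records$subject_gene[match(xy$records$subject_gene,
                                        yx$records$query_gene)]
  keep_xy <- !is.na(back) & back == xy$records$query_gene
  fwd <- xy$records$subject_gene[match(yx$records$subject_gene,
                                       xy$records$query_gene)]
  keep_yx <- !is.na(fwd) & fwd == yx$records$query_gene
  list(
    xy = best_match_table(xy$query_taxon, xy$subject_taxon,
                          xy$records$query_gene[keep_xy],
                          xy$records$subject_gene[keep_xy],
                          xy$records$logE[keep_xy]),
    yx = best_match_table(yx$query_taxon, yx$subject_taxon,
                          yx$records$query_gene[keep_yx],
                          yx$records$subject_gene[keep_yx],
                          yx$records$logE[keep_yx])
  )
}

#' Apply the reciprocal-best-hit filter to a full table set
#'
#' Filters every cross-table pair of orientations to reciprocal best hits;
#' self tables are left untouched.
#'
#' @param tables List of best-match tables.
#' @return List of filtered tables, same layout.
#' @export
rbh_filter_tables <- function(tables) {
  tables <- .index_tables(tables)
  taxa <- .taxa_of(tables)
  out <- tables
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i >= j) next
    x <- taxa[i]; y <- taxa[j]
    kxy <- .table_key(x, y); kyx <- .table_key(y, x)
    if (is.null(tables[[kxy]]) || is.null(tables[[kyx]])) next
    filt <- reciprocal_best_hits(tables[[kxy]], tables[[kyx]])
    out[[kxy]] <- filt$xy
    out[[kyx]] <- filt$yx
  }
  out
}
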