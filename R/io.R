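#' Read a proteome from a FASTA file
#'
#' Reads amino-acid FASTA into a proteome set. The gene identifier is the
#' header token before the first whitespace; multi-line sequences are
#' concatenated.
#'
#' @param path Path to a FASTA file.
#' @param taxon Taxon label; defaults to the file name without extension.
#' @return An object of class `proteome` : a list with `taxon` and
#'   `sequences` (named character vector, names are gene ids).
#' @export
read_proteome <- function(path, taxon = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated gene id(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  res <- as.character(seqs)
  names(res) <- ids
  if (any(nchar(res) == 0L)) {
    stop("empty sequence for gene id(s): ",
         paste(ids[nchar(res) == 0L], collapse = ", "))
  }
  if (is.null(taxon)) taxon <- sub("\\.[^.]*$", "", basename(path))
  structure(list(taxon = taxon, sequences = res), class = "proteome")
}

#' Read an aligned nucleotide FASTA
#'
#' For pairwise or multiple alignments of 16S rDNA. All sequences must have
#' equal length (gap characters included).
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(out))) != 1L)
    stop("aligned sequences must have equal length")
  out
}

#' Common-log transform of E-values with the zero sentinel
#'
#' Similarity-search E-values are converted to common (base-10) logarithms;
#' an E-value of exactly zero, which the search program reports when the
#' score underflows, is mapped to the sentinel -180. Results are floored at
#' -180 so no value is more extreme than the sentinel.
#'
#' @param evalue Numeric vector of raw E-values (>= 0).
#' @return Numeric vector of log10 E-values in `[-180, Inf)`.
#' @export
log_evalue <- function(evalue) {
  if (!is.numeric(evalue)) stop("evalue must be numeric")
  if (any(is.na(evalue))) stop("evalue contains NA")
  if (any(evalue < 0)) stop("negative E-value: ", min(evalue))
  out <- ifelse(evalue == 0, -180, log10(evalue))
  pmax(out, -180)
}

#' Construct a best-match table
#'
#' One record per query gene giving the best-matched (lowest E-value)
#' subject gene and its log10 E-value.
#'
#' @param query_taxon,subject_taxon Taxon labels of the ordered pair.
#' @param query_gene,subject_gene,logE Parallel vectors: query gene id,
#'   best-matched subject gene id, log10 E-value of the best match.
#' @return An object of class `best_match_table`.
#' @export
best_match_table <- function(query_taxon, subject_taxon,
                             query_gene, subject_gene, logE) {
  stopifnot(length(query_gene) == length(subject_gene),
            length(query_gene) == length(logE))
  query_gene <- as.character(query_gene)
  subject_gene <- as.character(subject_gene)
  if (anyDuplicated(query_gene))
    stop("duplicated query gene in best-match table: ",
         query_gene[duplicated(query_gene)][1L])
  if (length(logE) && any(logE < -180))
    stop("logE below the -180 sentinel")
  structure(list(query_taxon = query_taxon, subject_taxon = subject_taxon,
                 records = data.frame(query_gene = query_gene,
                                      subject_gene = subject_gene,
                                      logE = as.numeric(logE),
                                      stringsAsFactors = FALSE)),
            class = "best_match_table")
}

#' @export
print.best_match_table <- function(x, ...) {
  cat("Best-match table: ", x$query_taxon, " (query) vs ",
      x$subject_taxon, " (subject), ", nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Read tabular similarity-search output
#'
#' Parses the standard 12-column tabular hit format (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score). Only the query, subject and
#' E-value columns are interpreted; the rest are carried opaquely.
#'
#' @param path Path to a tabular hit file.
#' @return data.frame with columns `query`, `subject`, `evalue` plus the
#'   remaining columns as character.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed hit row (fewer than 11 columns) at line ",
         which(nf < 11L)[1L])
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (anyNA(ev))
    stop("non-numeric E-value at line ", which(is.na(ev))[1L])
  data.frame(query = vapply(fields, `[[`, "", 1L),
             subject = vapply(fields, `[[`, "", 2L),
             evalue = ev, stringsAsFactors = FALSE)
}

#' Extract best-matched hits per query gene
#'
#' Keeps, for each query gene, the hit with the lowest raw E-value among
#' rows at or below the cut-off; rows above the cut-off are discarded first,
#' so the cut-off acts as an admission filter. Ties at the minimum keep the
#' first row in input order. Queries with no admissible row are absent from
#' the result.
#'
#' @param hits data.frame with columns `query`, `subject`, `evalue`
#'   (e.g. from [read_hit_table()]).
#' @param query_taxon,subject_taxon Taxon labels of the ordered pair.
#' @param cutoff Raw E-value cut-off (default 10).
#' @return A [best_match_table()].
#' @export
parse_best_hits <- function(hits, query_taxon, subject_taxon, cutoff = 10) {
  stopifnot(all(c("query", "subject", "evalue") %in% names(hits)))
  if (any(hits$evalue < 0)) stop("negative E-value in hit table")
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(hits)) {
    # order() is stable: ties on evalue keep input order, giving the
    # deterministic first-row tie rule
    o <- order(hits$query, hits$evalue)
    hits <- hits[o, , drop = FALSE]
    hits <- hits[!duplicated(hits$query), , drop = FALSE]
  }
  best_match_table(query_taxon, subject_taxon,
                   hits$query, hits$subject, log_evalue(hits$evalue))
}

.phylip_name <- function(labels) {
  short <- substr(labels, 1L, 10L)
  if (anyDuplicated(short))
    stop("taxon names collide after truncation to 10 characters: ",
         paste(unique(short[duplicated(short)]), collapse = ", "))
  formatC(short, width = 10L, flag = "-")
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each subsequent row is the taxon name
#' padded to 10 characters followed by the full row of distances. Names
#' longer than 10 characters are truncated (with a collision check) and a
#' sidecar `<path>.labels` file mapping truncated to full names is written.
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("matrix must have taxon names")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  labs <- rownames(d)
  padded <- .phylip_name(labs)
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste0(padded[i], "  ",
           paste(formatC(d[i, ], format = "g", digits = 10), collapse = "  "))
  }, "")
  writeLines(c(as.character(nrow(d)), rows), path)
  if (any(nchar(labs) > 10L)) {
    writeLines(paste(trimws(padded), labs, sep = "\t"),
               paste0(path, ".labels"))
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Counterpart of [write_distance_matrix()]. If a sidecar `<path>.labels`
#' file exists, truncated names are restored to the full names recorded
#' there.
#'
#' @param path Path to a PHYLIP square matrix file.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 2L) stop("invalid taxon count on first line")
  if (length(lines) < n + 1L) stop("expected ", n, " matrix rows")
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    line <- lines[i + 1L]
    labs[i] <- trimws(substr(line, 1L, 10L))
    vals <- scan(text = substring(line, 11L), quiet = TRUE)
    if (length(vals) != n)
      stop("row ", i, " has ", length(vals), " values, expected ", n)
    d[i, ] <- vals
  }
  sidecar <- paste0(path, ".labels")
  if (file.exists(sidecar)) {
    map <- utils::read.table(sidecar, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    idx <- match(labs, map[[1L]])
    labs[!is.na(idx)] <- map[[2L]][idx[!is.na(idx)]]
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' Parse a Newick string into a tree
#'
#' Wraps the standard Newick parser with a balance pre-check that reports
#' the character position of the first unmatched parenthesis. Internal node
#' labels (e.g. bootstrap supports) are preserved.
#'
#' @param text Newick string.
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' : ", depth, " unclosed at end of string")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  tr
}

#' Serialize a tree as a Newick string
#'
#' @param tree A `phylo` object; supports, if present, are written as
#'   internal node labels.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(!is.finite(tree$edge.length)))
    stop("non-finite branch lengths")
  ape::write.tree(tree)
}

#' Run a local blastp search and return its tabular hits
#'
#' Optional convenience wrapper around a locally installed BLAST+
#' (`makeblastdb` + `blastp`); the package never requires it -- the
#' pipeline consumes tabular hit files from any source. Defaults follow
#' the method's search settings: BLOSUM62, low-complexity filtering,
#' E-value cut-off 10.
#'
#' @param query_fasta,subject_fasta Paths to protein FASTA files.
#' @param evalue E-value cut-off passed to blastp (default 10).
#' @param threads Number of search threads.
#' @return data.frame of hits as from [read_hit_table()].
#' @export
run_blastp <- function(query_fasta, subject_fasta, evalue = 10,
                       threads = 1L) {
  for (exe in c("makeblastdb", "blastp")) {
    if (Sys.which(exe) == "")
      stop("'", exe, "' not found on PATH; install BLAST+ or supply ",
           "tabular hit files directly")
  }
  db <- tempfile("blastdb")
  st <- system2("makeblastdb",
                c("-in", shQuote(subject_fasta), "-dbtype", "prot",
                  "-out", shQuote(db)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed on ", subject_fasta)
  out <- tempfile(fileext = ".tsv")
  st <- system2("blastp",
                c("-query", shQuote(query_fasta), "-db", shQuote(db),
                  "-evalue", format(evalue), "-outfmt", "6",
                  "-matrix", "BLOSUM62", "-seg", "yes",
                  "-num_threads", threads, "-out", shQuote(out)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("blastp failed")
  read_hit_table(out)
}
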