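#' Write / read a best-match table as TSV
#'
#' Three columns (`query_gene`, `subject_gene`, `logE`) preceded by two
#' comment lines recording the taxa of the ordered pair.
#'
#' @param table A `best_match_table`.
#' @param path File path.
#' @return `write_best_match_table` returns `path` invisibly;
#'   `read_best_match_table` returns a `best_match_table`.
#' @export
write_best_match_table <- function(table, path) {
  stopifnot(inherits(table, "best_match_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# query_taxon\t", table$query_taxon),
               paste0("# subject_taxon\t", table$subject_taxon)), con)
  utils::write.table(table$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_best_match_table
#' @export
read_best_match_table <- function(path) {
  lines <- readLines(path, n = 2L)
  hdr <- strsplit(lines, "\t", fixed = TRUE)
  if (length(hdr) < 2L || !grepl("^# query_taxon", lines[1L]))
    stop("not a best-match table file: ", path)
  rec <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric"))
  best_match_table(hdr[[1L]][2L], hdr[[2L]][2L],
                   rec$query_gene, rec$subject_gene, rec$logE)
}

.bmt_filename <- function(tb) paste0(tb$query_taxon, "__",
                                     tb$subject_taxon, ".bmt.tsv")

#' Write or load a directory of best-match tables
#'
#' Files are named `<query>__<subject>.bmt.tsv`.
#'
#' @param tables Named list of `best_match_table` objects.
#' @param dir Directory.
#' @return `write_table_dir` returns `dir` invisibly; `read_table_dir`
#'   returns the list of tables.
#' @export
write_table_dir <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in tables) write_best_match_table(tb, file.path(dir,
                                                          .bmt_filename(tb)))
  invisible(dir)
}

#' @rdname write_table_dir
#' @export
read_table_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bmt\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no .bmt.tsv files in ", dir)
  .index_tables(lapply(files, read_best_match_table))
}

#' Parse a flat key = value configuration file
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
parse_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
}

.default_config <- function() {
  list(cutoff = 10, convention = "angle", calibration = "satoh2013",
       index = "F_AV", bootstrap = 100, resample = 1000,
       outgroup = NA_character_, seed = 1, rbh = FALSE)
}

.load_model <- function(calibration) {
  if (inherits(calibration, "ave_calibration")) return(calibration)
  if (identical(calibration, "satoh2013")) return(calibration_preset())
  read_calibration(calibration)
}

#' Prepare best-match tables from raw tabular hit files
#'
#' Reads every `<query>__<subject>.tsv` hit file in `hits_dir`, extracts
#' best hits under the cut-off, and writes best-match tables to `out_dir`.
#'
#' @param hits_dir Directory of 12-column tabular hit files.
#' @param out_dir Output directory for `.bmt.tsv` files.
#' @param cutoff Raw E-value cut-off (default 10).
#' @return `out_dir`, invisibly.
#' @export
stage_prep <- function(hits_dir, out_dir, cutoff = 10) {
  files <- sort(list.files(hits_dir, pattern = "__.*\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no <query>__<subject>.tsv files in ", hits_dir)
  tables <- lapply(files, function(f) {
    taxa <- strsplit(sub("\\.tsv$", "", basename(f)), "__",
                     fixed = TRUE)[[1L]]
    if (length(taxa) != 2L)
      stop("hit file name must be <query>__<subject>.tsv: ", basename(f))
    parse_best_hits(read_hit_table(f), taxa[1L], taxa[2L], cutoff = cutoff)
  })
  write_table_dir(tables, out_dir)
}

#' Run the whole pipeline
#'
#' Orchestrates table loading (with optional reciprocal-best-hit
#' filtering), similarity statistics, calibration, the distance matrix,
#' the NJ tree, and the best-hit-resampling bootstrap. All artifacts are
#' written under `out_dir`; the effective configuration and seed are
#' echoed to `run.log` for provenance. A rerun with the same configuration
#' is bit-identical.
#'
#' @param config Named list (or path to a key = value file) with entries:
#'   `tables_dir` (directory of `.bmt.tsv` files) or `hits_dir` (raw hit
#'   files, prepared first); `out_dir`; `cutoff` (raw E-value, default
#'   10); `convention` (`"angle"`/`"complement"`); `calibration`
#'   (`"satoh2013"`, a model file path, or an `ave_calibration`); `index`
#'   (default `"F_AV"`); `bootstrap` (B, default 100); `resample` (k,
#'   default 1000); `outgroup` (optional tip label); `seed`; `rbh`
#'   (restrict to reciprocal best hits, default FALSE).
#' @return Invisibly, a list with the similarity table, distance matrix,
#'   tree, bootstrap result and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- parse_config(config)
  cfg <- utils::modifyList(.default_config(), as.list(config))
  for (k in c("cutoff", "bootstrap", "resample", "seed"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$rbh <- isTRUE(cfg$rbh) || identical(cfg$rbh, "TRUE") ||
    identical(cfg$rbh, "true")
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  if (is.null(cfg$tables_dir)) {
    if (is.null(cfg$hits_dir)) stop("config must set tables_dir or hits_dir")
    cfg$tables_dir <- file.path(cfg$out_dir, "tables")
    stage_prep(cfg$hits_dir, cfg$tables_dir, cutoff = cfg$cutoff)
  }
  tables <- read_table_dir(cfg$tables_dir)
  if (cfg$rbh) tables <- rbh_filter_tables(tables)
  model <- .load_model(cfg$calibration)
  if (!identical(model$convention, cfg$convention))
    stop("calibration model convention '", model$convention,
         "' does not match configured convention '", cfg$convention, "'")
  log_cut <- log10(cfg$cutoff)
  sims <- tantheta_safe(tables, cutoff = log_cut,
                        convention = cfg$convention)
  sim_path <- file.path(cfg$out_dir, "similarity.tsv")
  write_similarity_tsv(sims, sim_path)
  ftab <- f_index_table(sims, model)
  write_similarity_tsv(ftab, file.path(cfg$out_dir, "f_indices.tsv"))
  d <- build_distance_matrix(ftab, cfg$index)
  mat_path <- file.path(cfg$out_dir, "distmat.phy")
  write_distance_matrix(d, mat_path)
  tree <- neighbor_joining(d)
  if (!is.na(cfg$outgroup) && nzchar(cfg$outgroup))
    tree <- root_at_outgroup(tree, cfg$outgroup)
  tree_path <- file.path(cfg$out_dir, "tree.nwk")
  writeLines(write_newick(tree), tree_path)
  boot <- bootstrap_trees(tables, model, B = cfg$bootstrap,
                          k = cfg$resample, index = cfg$index,
                          seed = cfg$seed, cutoff = log_cut)
  cons_path <- file.path(cfg$out_dir, "consensus.nwk")
  writeLines(write_newick(boot$consensus), cons_path)
  supp_path <- file.path(cfg$out_dir, "supports.tsv")
  utils::write.table(support_table(boot$consensus), supp_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_flat <- cfg[!vapply(cfg, inherits, TRUE, "ave_calibration")]
  writeLines(c("# effective configuration",
               paste(names(cfg_flat),
                     vapply(cfg_flat, function(v) paste(format(v),
                                                        collapse = ","), ""),
                     sep = " = ")),
             file.path(cfg$out_dir, "run.log"))
  invisible(list(similarity = sims, f_table = ftab, distance_matrix = d,
                 tree = tree, bootstrap = boot,
                 paths = c(similarity = sim_path, distmat = mat_path,
                           tree = tree_path, consensus = cons_path,
                           supports = supp_path)))
}
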