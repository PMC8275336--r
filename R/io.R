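# Readers/writers for the stratified feature-table dialect, metadata,
# truth and result tables, and run configuration.

#' Parse stratified feature identifiers
#'
#' Feature ids follow the stratified convention of community functional
#' profilers: `"family|taxon"` for classified features, bare `"family"`
#' for unclassified ones.  `"|"` is forbidden inside components.
#'
#' @param ids character vector of feature ids.
#' @return data.frame with `feature_id`, `gene_family`, `taxon` (`NA` for
#'   unclassified features).
#' @export
parse_stratified_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  np <- lengths(parts)
  if (any(np > 2))
    stop("malformed feature id(s): ",
         paste(utils::head(ids[np > 2], 3), collapse = ", "))
  data.frame(
    feature_id = ids,
    gene_family = vapply(parts, `[`, "", 1),
    taxon = vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Serialize stratified feature identifiers
#'
#' @param gene_family,taxon character vectors; `taxon` may contain `NA` for
#'   unclassified features.
#' @return character vector of ids; inverse of [parse_stratified_ids()].
#' @export
make_stratified_ids <- function(gene_family, taxon = NULL) {
  if (any(grepl("|", gene_family, fixed = TRUE)))
    stop("'|' is forbidden inside gene family names")
  if (is.null(taxon)) return(gene_family)
  if (any(grepl("|", taxon[!is.na(taxon)], fixed = TRUE)))
    stop("'|' is forbidden inside taxon names")
  ifelse(is.na(taxon), gene_family, paste(gene_family, taxon, sep = "|"))
}

#' Read a tab-separated feature table
#'
#' First column holds feature ids (header cell `feature_id`), remaining
#' columns one sample each.  `#` comment lines are allowed.  Taxonomy is
#' extracted from stratified ids; integer tables become [mtx_counts()],
#' real-valued tables a plain numeric matrix.
#'
#' @param path file path.
#' @param modality `"RNA"` or `"DNA"` tag for count tables.
#' @return an [mtx_counts()] (integer input) or numeric matrix (real input).
#' @export
read_feature_table <- function(path, modality = "RNA") {
  tab <- read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("feature table needs an id column plus samples: ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (is.null(dim(bad)) || nrow(bad) == 0)
      stop("non-numeric data in ", path)
    stop("non-numeric cell in ", path, " at data row ", bad[1, 1],
         ", column ", colnames(m)[bad[1, 2]])
  }
  rownames(m) <- ids
  parsed <- parse_stratified_ids(ids)
  is_int <- all(m == round(m))
  if (is_int) {
    mtx_counts(m, modality = modality,
               feature_taxon = if (!all(is.na(parsed$taxon)))
                 setNames(parsed$taxon, ids))
  } else {
    m
  }
}

#' Write a feature table
#'
#' @param x an [mtx_counts()], [mtx_abund()] or matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(x, path) {
  m <- if (inherits(x, "mtx_counts")) x$counts
       else if (inherits(x, "mtx_abund")) x$values
       else x
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a `sample_id` column and a binary `phenotype` column;
#' additional columns are carried through as covariates.  Samples are
#' aligned to the supplied feature-table column order; mismatches are
#' errors listing the offending samples.  Rows with missing covariate
#' values are dropped with a warning (listwise deletion).
#'
#' @param path file path.
#' @param sample_ids character vector of expected sample ids, in feature
#'   table column order; NULL skips alignment.
#' @return data.frame of per-sample metadata.
#' @export
read_metadata <- function(path, sample_ids = NULL) {
  meta <- read.delim(path, check.names = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(meta)))
    stop("metadata needs 'sample_id' and 'phenotype' columns: ", path)
  lv <- unique(meta$phenotype[!is.na(meta$phenotype)])
  if (length(lv) != 2)
    stop("phenotype must have exactly two levels, found ", length(lv),
         " (", paste(utils::head(lv, 4), collapse = ", "), ")")
  if (!is.numeric(meta$phenotype))
    meta$phenotype <- as.integer(factor(meta$phenotype, levels = sort(lv))) - 1L
  incomplete <- !stats::complete.cases(meta)
  if (any(incomplete)) {
    warning(sum(incomplete), " metadata row(s) with missing values dropped")
    meta <- meta[!incomplete, , drop = FALSE]
  }
  if (!is.null(sample_ids)) {
    missing_meta <- setdiff(sample_ids, meta$sample_id)
    extra_meta <- setdiff(meta$sample_id, sample_ids)
    if (length(missing_meta) || length(extra_meta))
      stop("sample mismatch between tables; missing from metadata: [",
           paste(missing_meta, collapse = ", "), "]; not in feature table: [",
           paste(extra_meta, collapse = ", "), "]")
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Write a simulated dataset to a directory
#'
#' Emits `rna.tsv` and `dna.tsv` (stratified feature x sample count
#' tables), `metadata.tsv` (sample, phenotype, depths) and `truth.tsv`
#' (feature, label, spike type, target and attained rho).
#'
#' @param dataset an `mtx_dataset`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rna = file.path(outdir, "rna.tsv"),
             dna = file.path(outdir, "dna.tsv"),
             metadata = file.path(outdir, "metadata.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_feature_table(dataset$rna, paths["rna"])
  if (!is.null(dataset$dna)) write_feature_table(dataset$dna, paths["dna"])
  write.table(dataset$metadata, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing `rna.tsv`, optional `dna.tsv`,
#'   `metadata.tsv` and optional `truth.tsv`.
#' @return an `mtx_dataset`.
#' @export
read_dataset <- function(dir) {
  rna <- read_feature_table(file.path(dir, "rna.tsv"), "RNA")
  dna_path <- file.path(dir, "dna.tsv")
  dna <- if (file.exists(dna_path)) read_feature_table(dna_path, "DNA")
  meta <- read_metadata(file.path(dir, "metadata.tsv"),
                        colnames(rna$counts))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read.delim(truth_path, stringsAsFactors = FALSE)
  tax <- rna$feature_taxon
  structure(list(rna = rna, dna = dna, metadata = meta, truth = truth,
                 spikes = NULL,
                 taxonomy_known = !is.null(tax) && !anyNA(tax),
                 preset = "file", seed = NA_integer_, params = list()),
            class = "mtx_dataset")
}

#' Write / read DE results
#'
#' Tab-separated table with columns feature, coef, stderr, pval, qval,
#' n_used, status, reason.
#'
#' @param results an `mtx_de_result` from [run_de()].
#' @param path file path.
#' @return the results (reader) or `path`, invisibly (writer).
#' @export
write_de_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Persist / restore a run configuration
#'
#' JSON round-trip of the list describing a run (preset or input paths,
#' model spec fields, seeds, output paths), so any run is reconstructible
#' from its persisted configuration.
#'
#' @param config named list.
#' @param path JSON file path.
#' @return the configuration list (reader) or `path`, invisibly (writer).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
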