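#' Parametric species templates for a gut-like community
#'
#' Builds the table of per-species parameters driving community simulation:
#' a prevalence (probability a species occurs in a sample) and the
#' parameters of a log-normal abundance distribution used when it does.
#' The defaults describe a panel of prevalent human-gut-like species whose
#' prevalences span roughly 0.1--1 and whose natural-log mean abundances
#' span several log units, mimicking the strong rank-abundance skew of
#' stool metagenomes.  The table is deterministic (no random draws) and can
#' be replaced by any table with the same columns, e.g. one fitted to a
#' cohort of interest (see [read_species_templates()]).
#'
#' @param n_species number of species templates.
#' @param prevalence_range prevalences, interpolated linearly from first to
#'   last species.
#' @param log_mean_range natural-log mean abundances, interpolated linearly
#'   so that abundance co-varies with prevalence rank.
#' @param log_sd common standard deviation of log abundance.
#' @return a data.frame with columns `species_id`, `prevalence`,
#'   `abund_log_mean`, `abund_log_sd`.
#' @examples
#' head(species_templates(10))
#' @export
species_templates <- function(n_species = 100,
                              prevalence_range = c(1.0, 0.1),
                              log_mean_range = c(2.5, -3.5),
                              log_sd = 2.0) {
  stopifnot(n_species >= 1, log_sd > 0,
            all(prevalence_range >= 0 & prevalence_range <= 1))
  interp <- function(rng) {
    if (n_species == 1) rng[1] else seq(rng[1], rng[2], length.out = n_species)
  }
  data.frame(
    species_id = sprintf("S%03d", seq_len(n_species)),
    prevalence = interp(prevalence_range),
    abund_log_mean = interp(log_mean_range),
    abund_log_sd = rep(log_sd, n_species),
    stringsAsFactors = FALSE
  )
}

#' Read or write a species template table
#'
#' Tab-separated, one row per species, columns `species_id`, `prevalence`,
#' `abund_log_mean`, `abund_log_sd`.
#'
#' @param path file path.
#' @return for the reader, a validated template data.frame.
#' @export
read_species_templates <- function(path) {
  tpl <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("species_id", "prevalence", "abund_log_mean", "abund_log_sd")
  miss <- setdiff(req, names(tpl))
  if (length(miss))
    stop("template table is missing columns: ", paste(miss, collapse = ", "))
  validate_templates(tpl[req])
  tpl[req]
}

#' @rdname read_species_templates
#' @param templates template data.frame.
#' @export
write_species_templates <- function(templates, path) {
  validate_templates(templates)
  write.table(templates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_templates <- function(templates) {
  if (!is.data.frame(templates) || nrow(templates) == 0)
    stop("species template table must be a non-empty data.frame")
  if (anyDuplicated(templates$species_id))
    stop("duplicated species_id in template table")
  if (any(templates$prevalence < 0 | templates$prevalence > 1))
    stop("prevalence must lie in [0, 1]")
  if (any(templates$abund_log_sd <= 0))
    stop("abund_log_sd must be positive")
  invisible(templates)
}
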