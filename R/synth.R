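# Community simulator primitives: composition, pangenomes, strain carriage,
# expression, spiking and multinomial read sampling.

#' Simulate per-sample species compositions
#'
#' Each species occurs in a sample with its template prevalence; when
#' present its abundance is drawn from the species' log-normal distribution
#' (absent species get abundance 0).
#'
#' @param templates species template table (see [species_templates()]).
#' @param n_samples number of samples.
#' @param seed optional integer seed (set only if non-NULL; callers that
#'   manage the RNG state themselves leave it NULL).
#' @return species x sample abundance matrix with dimnames.
#' @export
sample_composition <- function(templates, n_samples, seed = NULL) {
  validate_templates(templates)
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(templates)
  present <- matrix(runif(ns * n_samples) < templates$prevalence,
                    nrow = ns, ncol = n_samples)
  abund <- exp(matrix(rnorm(ns * n_samples, mean = templates$abund_log_mean,
                            sd = templates$abund_log_sd),
                      nrow = ns, ncol = n_samples))
  comp <- ifelse(present, abund, 0)
  dimnames(comp) <- list(templates$species_id,
                         sprintf("sample%03d", seq_len(n_samples)))
  comp
}

#' Build species pangenomes from a shared gene-family pool
#'
#' Each species' pangenome is a uniform random subset of `genes_per_species`
#' families out of a community-wide pool of `pool_size` families.  Family
#' identifiers are shared across species (orthogroup semantics), so the same
#' family can be encoded by several species.
#'
#' @param species_ids character vector of species identifiers.
#' @param pool_size size of the shared gene-family pool.
#' @param genes_per_species pangenome size per species; must not exceed
#'   `pool_size`.
#' @param seed optional integer seed.
#' @return list with `gene_pool` (character) and `genes`, a named list of
#'   per-species gene-family vectors.
#' @export
build_pangenomes <- function(species_ids, pool_size = 2000,
                             genes_per_species = 1000, seed = NULL) {
  if (genes_per_species > pool_size)
    stop("genes_per_species must not exceed pool_size")
  if (!is.null(seed)) set.seed(seed)
  pool <- sprintf("F%05d", seq_len(pool_size))
  genes <- lapply(species_ids, function(s) sort(sample(pool, genes_per_species)))
  names(genes) <- species_ids
  list(gene_pool = pool, genes = genes)
}

#' Feature universe of a set of pangenomes
#'
#' One feature per (gene family, species) pair, serialized in the stratified
#' `family|species` convention.
#'
#' @param pangenomes result of [build_pangenomes()].
#' @return data.frame with `feature_id`, `gene_family`, `species`.
#' @export
pangenome_features <- function(pangenomes) {
  sp <- rep(names(pangenomes$genes), lengths(pangenomes$genes))
  fam <- unlist(pangenomes$genes, use.names = FALSE)
  data.frame(feature_id = paste(fam, sp, sep = "|"),
             gene_family = fam, species = sp, stringsAsFactors = FALSE)
}

#' Draw per-sample strain carriage
#'
#' The strain of a species observed in a sample carries each pangenome gene
#' independently with probability `carriage_rate`, modeling genomic
#' plasticity (gene gain/loss between strains).
#'
#' @param features feature table from [pangenome_features()].
#' @param sample_ids character vector of sample identifiers.
#' @param carriage_rate per-gene carriage probability in (0, 1].
#' @param seed optional integer seed.
#' @return logical feature x sample matrix.
#' @export
draw_carriage <- function(features, sample_ids, carriage_rate = 0.8,
                          seed = NULL) {
  stopifnot(carriage_rate > 0, carriage_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(features) * length(sample_ids)
  m <- matrix(runif(n) < carriage_rate, nrow = nrow(features),
              dimnames = list(features$feature_id, sample_ids))
  m
}

#' Draw per-sample gene expression values
#'
#' Each feature has a reference log-mean expression `m ~ N(0, ref_sd^2)`;
#' per-sample expression for carried genes is log-normal,
#' `exp(N(m, sample_sd^2))`.  Non-carried cells are `NA` (expression is
#' undefined where the gene is absent).
#'
#' @param carriage logical feature x sample matrix from [draw_carriage()].
#' @param ref_log_mean optional numeric vector of per-feature reference
#'   log-means; drawn from `N(0, ref_sd^2)` when NULL.
#' @param ref_sd,sample_sd standard deviations of the reference and
#'   per-sample log-expression draws.
#' @param seed optional integer seed.
#' @return list with `ref_log_mean` (named numeric) and `expr`
#'   (feature x sample matrix, NA where not carried; positive elsewhere).
#' @export
draw_expression <- function(carriage, ref_log_mean = NULL, ref_sd = 1,
                            sample_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- nrow(carriage)
  if (is.null(ref_log_mean)) {
    ref_log_mean <- rnorm(nf, 0, ref_sd)
    names(ref_log_mean) <- rownames(carriage)
  }
  expr <- exp(matrix(rnorm(length(carriage), mean = ref_log_mean,
                           sd = sample_sd),
                     nrow = nf, dimnames = dimnames(carriage)))
  expr[!carriage] <- NA_real_
  list(ref_log_mean = ref_log_mean, expr = expr)
}

#' Permute a vector to a target rank correlation with a binary phenotype
#'
#' Re-arranges (never alters) the values of `values` so that their Spearman
#' correlation with `phenotype` approaches `rho_target * direction`.  The
#' algorithm starts from the rank-sorted arrangement against the phenotype
#' (the attainable extreme) and bisects on the number of random swaps until
#' the realized correlation falls within `eps` of the target.  For a binary
#' phenotype the maximum attainable |rho| is well below 1 (about 0.87 for a
#' balanced continuous vector of length 100, and lower still for tied
#' values); when the target exceeds it, the extreme arrangement is returned
#' and flagged rather than failing.
#'
#' @param values numeric vector to permute.
#' @param phenotype binary (0/1) vector, same length.
#' @param rho_target target |Spearman rho| in [0, 1].
#' @param direction +1 or -1, sign of the induced correlation.
#' @param eps acceptance tolerance on the realized correlation.
#' @param max_iter maximum bisection evaluations.
#' @param seed optional integer seed.
#' @return list with `values` (a permutation of the input), `attained`
#'   (realized Spearman rho), `target` (signed target) and `attainable`
#'   (FALSE when the target exceeds the arrangement maximum).
#' @export
spike_permute <- function(values, phenotype, rho_target, direction = 1,
                          eps = 0.05, max_iter = 60, seed = NULL) {
  stopifnot(length(values) == length(phenotype),
            rho_target >= 0, rho_target <= 1, direction %in% c(-1, 1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  target <- rho_target * direction
  rho_of <- function(v) {
    r <- suppressWarnings(cor(v, phenotype, method = "spearman"))
    if (is.na(r)) 0 else r
  }
  if (abs(rho_of(values) - target) <= eps)
    return(list(values = values, attained = rho_of(values), target = target,
                attainable = TRUE))
  # extreme arrangement: sorted values laid out against the phenotype groups
  # (random order within groups so ties among samples are not systematic)
  ord <- order(phenotype, runif(n))
  sorted <- sort(values, decreasing = (direction < 0))
  extreme <- numeric(n)
  extreme[ord] <- sorted
  rho_max <- rho_of(extreme)
  if (abs(rho_max) <= abs(target) + eps) {
    return(list(values = extreme, attained = rho_max, target = target,
                attainable = abs(abs(rho_max) - rho_target) <= eps))
  }
  swapped <- function(k) {
    v <- extreme
    if (k > 0) {
      i <- sample.int(n, k, replace = TRUE)
      j <- sample.int(n, k, replace = TRUE)
      for (s in seq_len(k)) {
        tmp <- v[i[s]]; v[i[s]] <- v[j[s]]; v[j[s]] <- tmp
      }
    }
    v
  }
  lo <- 0; hi <- 4L * n
  best <- extreme; best_rho <- rho_max
  for (iter in seq_len(max_iter)) {
    mid <- as.integer((lo + hi) / 2)
    v <- swapped(mid)
    r <- rho_of(v)
    if (abs(r - target) < abs(best_rho - target)) { best <- v; best_rho <- r }
    if (abs(r - target) <= eps)
      return(list(values = v, attained = r, target = target, attainable = TRUE))
    if (abs(r) > abs(target)) lo <- mid + 1L else hi <- max(mid - 1L, lo)
    if (lo >= hi) { lo <- 0; hi <- 4L * n }  # restart with fresh randomness
  }
  list(values = best, attained = best_rho, target = target,
       attainable = abs(best_rho - target) <= eps)
}

#' Sample sequencing reads for one modality
#'
#' Reads for each sample are drawn from a multinomial over the sample's
#' features, with weights proportional to the source species' abundance
#' (DNA) or to species abundance times the per-sample expression value
#' (RNA), restricted to carried genes.  Column sums equal the requested
#' per-sample depth exactly.
#'
#' @param composition species x sample abundance matrix.
#' @param carriage logical feature x sample matrix.
#' @param expression feature x sample expression matrix (NA where not
#'   carried) for RNA; NULL for DNA.
#' @param depth integer vector of per-sample read depths.
#' @param modality `"RNA"` or `"DNA"`.
#' @param feature_species character vector mapping features (rows) to
#'   species (rows of `composition`).
#' @param seed optional integer seed.
#' @return an [mtx_counts()] object.
#' @export
simulate_counts <- function(composition, carriage, expression = NULL,
                            depth, modality = c("RNA", "DNA"),
                            feature_species, seed = NULL) {
  modality <- match.arg(modality)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(depth) == ncol(carriage), all(depth >= 1))
  w <- composition[feature_species, , drop = FALSE] * carriage
  if (modality == "RNA") {
    stopifnot(!is.null(expression))
    e <- expression
    e[is.na(e)] <- 0
    w <- w * e
  }
  tot <- colSums(w)
  if (any(tot <= 0))
    stop("sample(s) with zero total sampling weight: ",
         paste(colnames(carriage)[tot <= 0], collapse = ", "))
  counts <- matrix(0L, nrow = nrow(w), ncol = ncol(w), dimnames = dimnames(carriage))
  for (j in seq_len(ncol(w))) {
    counts[, j] <- as.integer(rmultinom(1, size = depth[j], prob = w[, j]))
  }
  mtx_counts(counts, modality = modality,
             feature_taxon = setNames(feature_species, rownames(carriage)))
}

#' Count matrix container
#'
#' Integer reads per feature per sample for one modality (RNA or DNA), with
#' an optional feature-to-species map and per-sample depths (column sums).
#'
#' @param counts integer feature x sample matrix with dimnames.
#' @param modality `"RNA"` or `"DNA"`.
#' @param feature_taxon optional named character vector mapping feature ids
#'   to species; `NA` entries mark unclassified features.
#' @return an object of class `mtx_counts`.
#' @export
mtx_counts <- function(counts, modality = c("RNA", "DNA"),
                       feature_taxon = NULL) {
  modality <- match.arg(modality)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(feature_taxon)) {
    feature_taxon <- feature_taxon[rownames(counts)]
    names(feature_taxon) <- rownames(counts)
  }
  structure(list(counts = counts, modality = modality,
                 feature_taxon = feature_taxon,
                 sample_depth = colSums(counts)),
            class = "mtx_counts")
}

#' @export
print.mtx_counts <- function(x, ...) {
  cat(sprintf("<mtx_counts> %s: %d features x %d samples; depth %s-%s\n",
              x$modality, nrow(x$counts), ncol(x$counts),
              format(min(x$sample_depth)), format(max(x$sample_depth))))
  invisible(x)
}

#' @export
dim.mtx_counts <- function(x) dim(x$counts)
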