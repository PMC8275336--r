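# Dataset presets: paired MGX/MTX communities with spiked phenotype
# associations and recorded ground truth.

# Per-preset spike configuration.  Strengths are labels resolved through the
# strength map (high/med/low -> target Spearman rho of 0.8/0.5/0.2).
preset_table <- function() {
  list(
    "null"               = list(),
    "null-bug"           = list(bug_frac = 0.10, bug_strength = "high"),
    "null-enc"           = list(enc_frac = 0.10, enc_strength = "high"),
    "null-dep"           = list(dep = TRUE, dep_strength = "high"),
    "true-exp"           = list(exp_frac = 0.10, exp_strength = "high"),
    "true-exp-med"       = list(exp_frac = 0.10, exp_strength = "med"),
    "true-exp-low"       = list(exp_frac = 0.10, exp_strength = "low"),
    "true-combo-bug-exp" = list(exp_frac = 0.10, exp_strength = "high",
                                bug_frac = 0.50, bug_strength = "high"),
    "true-combo-dep-exp" = list(exp_frac = 0.10, exp_strength = "high",
                                dep = TRUE, dep_strength = "high"),
    "group-null-enc"     = list(enc_frac = 0.10, enc_strength = "high",
                                group = TRUE),
    "group-true-exp"     = list(exp_frac = 0.10, exp_strength = "high",
                                group = TRUE)
  )
}

#' Names of the built-in dataset presets
#' @return character vector of the 11 preset names.
#' @export
preset_names <- function() names(preset_table())

#' Reduced-scale simulation settings
#'
#' Override list for [make_dataset()] shrinking the community to 20 species
#' with 200-gene pangenomes drawn from a 400-family pool.  Sequencing depth
#' keeps its full default range, so desk-scale features are sampled at
#' least as deeply as full-scale ones.  Intended for desk-scale
#' benchmarking and tests.
#' @return named list of [make_dataset()] arguments.
#' @export
desk_scale <- function() {
  list(n_species = 20L, pool_size = 400L, genes_per_species = 200L)
}

#' Simulate a paired MGX/MTX dataset with spiked phenotype associations
#'
#' Generates a gut-like community (species compositions, pangenomes, strain
#' carriage, per-gene expression), assigns a balanced binary phenotype, and
#' spikes the configured phenomena (sequencing depth, species abundance,
#' gene presence/absence, gene expression) to rank-correlate with the
#' phenotype.  Read counts for both modalities are then drawn multinomially
#' up to each sample's depth.  Expression spikes define the DE-positive
#' ground truth; all other features are DE-negative.
#'
#' For the `group-*` presets, spikes are applied consistently to every
#' species' copy of a spiked gene family, feature taxonomy is marked
#' unknown, and the returned dataset is collapsed to orthogroup (gene
#' family) sums via [collapse_orthogroups()].
#'
#' @param preset one of [preset_names()], or `"custom"` with `spikes`.
#' @param seed master seed; the whole dataset is a deterministic function of
#'   (preset, seed, parameters).
#' @param n_samples number of samples (split exactly half/half between the
#'   two phenotype groups).
#' @param templates species template table; defaults to
#'   `species_templates(n_species)`.
#' @param n_species,pool_size,genes_per_species community dimensions.
#' @param carriage_rate per-gene strain carriage probability.
#' @param expr_ref_sd,expr_sample_sd standard deviations of the reference
#'   and per-sample log-expression draws.
#' @param depth_range per-sample sequencing depths are drawn log-uniformly
#'   from this range (independently for RNA and DNA).
#' @param strength_map named vector mapping spike strength labels to target
#'   Spearman rho.
#' @param spike_eps tolerance on realized spike correlations.
#' @param spikes for `preset = "custom"`: a list with any of `bug_frac`,
#'   `bug_strength`, `enc_frac`, `enc_strength`, `exp_frac`, `exp_strength`,
#'   `dep`, `dep_strength`, `group`.
#' @return an object of class `mtx_dataset`: list with `rna` and `dna`
#'   ([mtx_counts()]), `metadata` (sample_id, phenotype, depth_rna,
#'   depth_dna), `truth` (feature, label, spike_type, target_rho,
#'   attained_rho), `spikes` (log of applied spikes), `taxonomy_known`,
#'   `preset`, `seed` and `params`.
#' @examples
#' d <- make_dataset("null", seed = 1, n_species = 5, pool_size = 40,
#'                   genes_per_species = 20, n_samples = 20,
#'                   depth_range = c(500, 1000))
#' d
#' @export
make_dataset <- function(preset = "null", seed = 1, n_samples = 100,
                         templates = NULL, n_species = 100,
                         pool_size = 2000, genes_per_species = 1000,
                         carriage_rate = 0.8,
                         expr_ref_sd = 1, expr_sample_sd = 1,
                         depth_range = c(5e4, 2e5),
                         strength_map = c(high = 0.8, med = 0.5, low = 0.2),
                         spike_eps = 0.05, spikes = NULL) {
  cfgs <- preset_table()
  if (identical(preset, "custom")) {
    cfg <- if (is.null(spikes)) list() else spikes
  } else if (preset %in% names(cfgs)) {
    cfg <- cfgs[[preset]]
  } else {
    stop("unknown preset '", preset, "'; see preset_names()")
  }
  group <- isTRUE(cfg$group)
  set.seed(seed)

  if (is.null(templates)) templates <- species_templates(n_species)
  n_species <- nrow(templates)
  comp <- sample_composition(templates, n_samples)
  sample_ids <- colnames(comp)
  pg <- build_pangenomes(templates$species_id, pool_size, genes_per_species)
  features <- pangenome_features(pg)
  carriage <- draw_carriage(features, sample_ids, carriage_rate)

  # balanced binary phenotype
  phen <- integer(n_samples)
  phen[sample.int(n_samples, floor(n_samples / 2))] <- 1L

  rho_of <- function(lbl) unname(strength_map[[lbl]])
  spike_log <- list()
  note <- function(type, unit, r) {
    spike_log[[length(spike_log) + 1]] <<- data.frame(
      spike_type = type, unit = unit, target_rho = r$target,
      attained_rho = r$attained, attainable = r$attainable,
      stringsAsFactors = FALSE)
  }

  # species-abundance confounding
  if (!is.null(cfg$bug_frac)) {
    k <- max(1L, round(cfg$bug_frac * n_species))
    sp <- sample(templates$species_id, k)
    for (s in sp) {
      r <- spike_permute(comp[s, ], phen, rho_of(cfg$bug_strength),
                         direction = 1, eps = spike_eps)
      comp[s, ] <- r$values
      note("species_abundance", s, r)
    }
  }

  # gene presence/absence confounding
  enc_units <- character(0)
  if (!is.null(cfg$enc_frac)) {
    if (group) {
      fams <- sample(pg$gene_pool, max(1L, round(cfg$enc_frac * pool_size)))
      for (fam in fams) {
        idx <- which(features$gene_family == fam)
        for (i in idx) {
          r <- spike_permute(as.numeric(carriage[i, ]), phen,
                             rho_of(cfg$enc_strength), direction = 1,
                             eps = spike_eps)
          carriage[i, ] <- r$values > 0
          note("gene_presence", features$feature_id[i], r)
        }
      }
      enc_units <- fams
    } else {
      idx <- sample(nrow(features), max(1L, round(cfg$enc_frac * nrow(features))))
      for (i in idx) {
        r <- spike_permute(as.numeric(carriage[i, ]), phen,
                           rho_of(cfg$enc_strength),
                           direction = 1, eps = spike_eps)
        carriage[i, ] <- r$values > 0
        note("gene_presence", features$feature_id[i], r)
      }
      enc_units <- features$feature_id[idx]
    }
  }

  # expression (drawn on the final carriage, then spiked -> DE positives)
  ex <- draw_expression(carriage, ref_sd = expr_ref_sd,
                        sample_sd = expr_sample_sd)
  expr <- ex$expr
  pos_features <- character(0)
  pos_families <- character(0)
  exp_targets <- numeric(0)
  if (!is.null(cfg$exp_frac)) {
    spike_expr_row <- function(i, dir) {
      car <- which(!is.na(expr[i, ]))
      if (length(car) < 3) return(NULL)
      r <- spike_permute(expr[i, car], phen[car], rho_of(cfg$exp_strength),
                         direction = dir, eps = spike_eps)
      expr[i, car] <<- r$values
      note("expression", features$feature_id[i], r)
      r
    }
    if (group) {
      fams <- sample(pg$gene_pool, max(1L, round(cfg$exp_frac * pool_size)))
      for (fam in fams) {
        for (i in which(features$gene_family == fam)) spike_expr_row(i, 1)
      }
      pos_families <- fams
      pos_features <- features$feature_id[features$gene_family %in% fams]
    } else {
      idx <- sample(nrow(features), max(1L, round(cfg$exp_frac * nrow(features))))
      for (i in idx) spike_expr_row(i, 1)
      pos_features <- features$feature_id[idx]
    }
  }

  # sequencing depths (log-uniform), optionally confounded with phenotype
  draw_depth <- function() {
    as.integer(round(exp(runif(n_samples, log(depth_range[1]),
                               log(depth_range[2])))))
  }
  depth_rna <- draw_depth()
  depth_dna <- draw_depth()
  if (isTRUE(cfg$dep)) {
    r <- spike_permute(as.numeric(depth_rna), phen,
                       rho_of(cfg$dep_strength %||% "high"),
                       direction = 1, eps = spike_eps)
    depth_rna <- as.integer(r$values)
    note("depth", "rna_depth", r)
  }

  rna <- simulate_counts(comp, carriage, expr, depth_rna, "RNA",
                         features$species)
  dna <- simulate_counts(comp, carriage, NULL, depth_dna, "DNA",
                         features$species)

  truth <- data.frame(
    feature = features$feature_id,
    label = ifelse(features$feature_id %in% pos_features,
                   "positive", "negative"),
    spike_type = NA_character_, target_rho = NA_real_,
    attained_rho = NA_real_, stringsAsFactors = FALSE)
  if (length(spike_log)) {
    slog <- do.call(rbind, spike_log)
    m <- match(truth$feature, slog$unit)
    hit <- !is.na(m)
    truth$spike_type[hit] <- slog$spike_type[m[hit]]
    truth$target_rho[hit] <- slog$target_rho[m[hit]]
    truth$attained_rho[hit] <- slog$attained_rho[m[hit]]
  } else {
    slog <- data.frame(spike_type = character(0), unit = character(0),
                       target_rho = numeric(0), attained_rho = numeric(0),
                       attainable = logical(0))
  }

  ds <- structure(list(
    rna = rna, dna = dna,
    metadata = data.frame(sample_id = sample_ids, phenotype = phen,
                          depth_rna = depth_rna, depth_dna = depth_dna,
                          stringsAsFactors = FALSE),
    truth = truth, spikes = slog, taxonomy_known = !group,
    preset = preset, seed = seed,
    params = list(n_samples = n_samples, n_species = n_species,
                  pool_size = pool_size,
                  genes_per_species = genes_per_species,
                  carriage_rate = carriage_rate,
                  depth_range = depth_range,
                  strength_map = strength_map)),
    class = "mtx_dataset")
  if (group) ds <- collapse_orthogroups(ds, positive_families = pos_families)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse a stratified dataset to orthogroup (gene family) sums
#'
#' RNA and DNA counts are summed per gene family over all contributing
#' species; the feature-taxon map is dropped (taxonomy unknown).  An
#' orthogroup is DE-positive iff any of its member features was
#' expression-spiked (for `group-*` presets, spikes are applied consistently
#' across species, so this is equivalent to "the family was spiked").
#'
#' @param dataset an `mtx_dataset` with stratified feature ids.
#' @param positive_families optional character vector naming DE-positive
#'   families directly (used internally by `group-*` presets).
#' @return an `mtx_dataset` with orthogroup-level features.
#' @export
collapse_orthogroups <- function(dataset, positive_families = NULL) {
  stopifnot(inherits(dataset, "mtx_dataset"))
  fam <- parse_stratified_ids(rownames(dataset$rna$counts))$gene_family
  sum_by <- function(counts) {
    m <- rowsum(counts, group = fam, reorder = TRUE)
    storage.mode(m) <- "integer"
    m
  }
  rna <- mtx_counts(sum_by(dataset$rna$counts), "RNA")
  dna <- if (!is.null(dataset$dna)) mtx_counts(sum_by(dataset$dna$counts), "DNA")
  if (is.null(positive_families)) {
    positive_families <- unique(fam[dataset$truth$label == "positive"])
  }
  fam_rho <- tapply(dataset$truth$attained_rho, fam,
                    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  fam_ids <- rownames(rna$counts)
  truth <- data.frame(
    feature = fam_ids,
    label = ifelse(fam_ids %in% positive_families, "positive", "negative"),
    spike_type = ifelse(fam_ids %in% positive_families, "expression",
                        NA_character_),
    target_rho = NA_real_,
    attained_rho = as.numeric(fam_rho[fam_ids]),
    stringsAsFactors = FALSE)
  out <- dataset
  out$rna <- rna
  out$dna <- dna
  out$truth <- truth
  out$taxonomy_known <- FALSE
  out
}

#' @export
print.mtx_dataset <- function(x, ...) {
  npos <- sum(x$truth$label == "positive")
  cat(sprintf(paste0("<mtx_dataset> preset '%s' (seed %d): %d features x %d",
                     " samples, %d DE-positive, taxonomy %s\n"),
              x$preset, x$seed, nrow(x$rna$counts), ncol(x$rna$counts),
              npos, if (x$taxonomy_known) "known" else "unknown"))
  invisible(x)
}
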