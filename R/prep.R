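# Normalization, zero pre-filtering and smoothing/log transforms.

#' Abundance matrix container
#'
#' Real-valued feature x sample abundances tagged with their scale, plus a
#' per-cell inclusion mask (TRUE = usable for modeling).
#'
#' @param values numeric feature x sample matrix with dimnames.
#' @param scale one of `"community-TSS"`, `"within-taxon-TSS"`,
#'   `"smoothed"`, `"log-smoothed"`, `"log-ratio"`.
#' @param mask logical matrix of the same shape; defaults to all TRUE.
#' @return an object of class `mtx_abund`.
#' @export
mtx_abund <- function(values, scale, mask = NULL) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, scale = scale, mask = mask),
            class = "mtx_abund")
}

#' @export
print.mtx_abund <- function(x, ...) {
  cat(sprintf("<mtx_abund> %s: %d features x %d samples (%.1f%% cells masked out)\n",
              x$scale, nrow(x$values), ncol(x$values), 100 * mean(!x$mask)))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "mtx_counts")) x$counts else x
}

# plain-matrix TSS used throughout the model pipeline
tss_matrix <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[cs <= 0], collapse = ", "))
  sweep(counts, 2, cs, "/")
}

#' Community-level total-sum scaling
#'
#' Divides each sample (column) by its total, converting counts to relative
#' abundances; zeros stay zero.
#'
#' @param counts an [mtx_counts()] object or numeric matrix.
#' @return an [mtx_abund()] on the `"community-TSS"` scale.
#' @export
community_tss <- function(counts) {
  m <- as_count_matrix(counts)
  mtx_abund(tss_matrix(m), scale = "community-TSS")
}

#' Within-taxon total-sum scaling
#'
#' Divides each feature's per-sample abundance by the total abundance
#' contributed by its source species ("taxon-specific scaling").  Where a
#' species' total is zero in a sample, the feature value stays 0.
#'
#' @param abund an [mtx_abund()] (typically community-TSS) or matrix.
#' @param feature_taxon named character vector mapping features to species;
#'   must classify every feature.
#' @return an [mtx_abund()] on the `"within-taxon-TSS"` scale.
#' @export
within_taxon_tss <- function(abund, feature_taxon) {
  v <- if (inherits(abund, "mtx_abund")) abund$values else abund
  tx <- feature_taxon[rownames(v)]
  if (anyNA(tx))
    stop("unclassified feature(s): within-taxon scaling requires a taxon ",
         "for every feature (e.g. ",
         paste(utils::head(rownames(v)[is.na(tx)], 3), collapse = ", "), ")")
  mtx_abund(within_taxon_matrix(v, tx), scale = "within-taxon-TSS",
            mask = if (inherits(abund, "mtx_abund")) abund$mask else NULL)
}

within_taxon_matrix <- function(values, feature_taxon) {
  tot <- rowsum(values, group = feature_taxon)           # species x samples
  denom <- tot[feature_taxon[rownames(values)], , drop = FALSE]
  out <- values / denom
  out[denom == 0] <- 0
  dimnames(out) <- dimnames(values)
  out
}

#' Per-species abundance totals
#'
#' Sums community-TSS abundances over the features of each species, giving a
#' taxon-level relative abundance estimate for the matrix's modality (used
#' as the taxon-RNA covariate of model M3 and the taxon-DNA covariate of
#' model M5).
#'
#' @inheritParams within_taxon_tss
#' @return species x sample numeric matrix.
#' @export
taxon_totals <- function(abund, feature_taxon) {
  v <- if (inherits(abund, "mtx_abund")) abund$values else abund
  tx <- feature_taxon[rownames(v)]
  if (anyNA(tx)) stop("unclassified feature(s): taxon totals need full taxonomy")
  rowsum(v, group = tx)
}

#' Zero pre-filtering policies
#'
#' Computes the per-cell inclusion mask implied by one of the three
#' filtering policies, given the RNA zero pattern and (for models with a
#' gene-copy estimate) the copy zero pattern:
#' * `lenient`: a feature is dropped entirely iff its RNA row (or its copy
#'   row, when a copy estimate exists) is all zero; all samples of surviving
#'   features are kept.
#' * `semi-strict`: additionally masks a sample iff both the RNA and copy
#'   values are zero (no per-sample action when there is no copy estimate).
#' * `strict`: masks a sample iff either the RNA or copy value is zero.
#'
#' Dropped features are recorded so downstream evaluation can score them as
#' negative for DE.
#'
#' @param rna RNA counts or abundances ([mtx_counts()], [mtx_abund()] or
#'   matrix); only its zero pattern is used.
#' @param copy optional aligned gene-copy estimate (feature DNA, or taxon
#'   totals expanded to feature rows); NULL when the model has none (M1).
#' @param policy `"lenient"`, `"semi-strict"` or `"strict"`.
#' @return list with `mask` (logical feature x sample matrix; dropped
#'   features are all-FALSE) and `dropped` (character vector of feature ids
#'   failing the lenient existence check).
#' @export
apply_filter <- function(rna, copy = NULL,
                         policy = c("strict", "semi-strict", "lenient")) {
  policy <- match.arg(policy)
  rv <- if (inherits(rna, "mtx_abund")) rna$values else as_count_matrix(rna)
  zr <- rv == 0
  zc <- NULL
  if (!is.null(copy)) {
    cv <- if (inherits(copy, "mtx_abund")) copy$values else as_count_matrix(copy)
    if (!identical(dim(cv), dim(rv)) || !identical(colnames(cv), colnames(rv)))
      stop("rna and copy matrices are misaligned")
    zc <- cv == 0
  }
  mask <- switch(policy,
    "lenient" = matrix(TRUE, nrow(rv), ncol(rv)),
    "semi-strict" = if (is.null(zc)) matrix(TRUE, nrow(rv), ncol(rv)) else !(zr & zc),
    "strict" = if (is.null(zc)) !zr else !(zr | zc))
  dimnames(mask) <- dimnames(rv)
  dropped <- rownames(rv)[rowSums(!zr) == 0]
  if (!is.null(zc)) dropped <- union(dropped, rownames(rv)[rowSums(!zc) == 0])
  mask[rownames(mask) %in% dropped, ] <- FALSE
  list(mask = mask, dropped = dropped)
}

# half-minimum replacement on a vector of surviving (unmasked) values;
# returns NULL when no positive value exists (caller decides how to flag).
half_min_smooth <- function(v) {
  nz <- v[v > 0]
  if (!length(nz)) return(NULL)
  v[v == 0] <- min(nz) / 2
  v
}

#' Half-minimum smoothing of surviving zeros
#'
#' Per feature, zeros in unmasked cells are replaced by half the feature's
#' smallest non-zero unmasked value (half-min is computed over unmasked
#' cells only; masked cells are non-measurements and are set to NA).
#'
#' @param abund an [mtx_abund()].
#' @return an [mtx_abund()] on the `"smoothed"` scale.
#' @export
smooth_zeros <- function(abund) {
  stopifnot(inherits(abund, "mtx_abund"))
  v <- abund$values
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v))) {
    keep <- abund$mask[i, ]
    if (!any(keep)) next
    s <- half_min_smooth(v[i, keep])
    if (is.null(s))
      stop("feature '", rownames(v)[i],
           "' has no non-zero unmasked value; it should have been filtered")
    out[i, keep] <- s
  }
  mtx_abund(out, scale = "smoothed", mask = abund$mask)
}

#' Half-minimum smoothing followed by natural log
#'
#' @inheritParams smooth_zeros
#' @return an [mtx_abund()] on the `"log-smoothed"` scale; finite wherever
#'   the mask is TRUE.
#' @export
smooth_log <- function(abund) {
  s <- smooth_zeros(abund)
  mtx_abund(log(s$values), scale = "log-smoothed", mask = s$mask)
}

#' Log RNA/DNA ratio ("relative expression")
#'
#' Cell-wise `log(RNA / DNA)` of half-min-smoothed, community-TSS RNA and
#' DNA abundances over jointly unmasked cells: the response of model M4.
#'
#' @param rna,dna [mtx_abund()] objects on the `"smoothed"` (pre-log) scale,
#'   or `"community-TSS"` scale (smoothed internally).
#' @return an [mtx_abund()] on the `"log-ratio"` scale.
#' @export
rna_dna_log_ratio <- function(rna, dna) {
  stopifnot(inherits(rna, "mtx_abund"), inherits(dna, "mtx_abund"))
  mask <- rna$mask & dna$mask
  if (rna$scale != "smoothed") rna <- smooth_zeros(mtx_abund(rna$values, rna$scale, mask))
  if (dna$scale != "smoothed") dna <- smooth_zeros(mtx_abund(dna$values, dna$scale, mask))
  if (any(dna$values[mask] == 0, na.rm = TRUE))
    stop("DNA cell of exactly 0 after smoothing; smoothing invariant violated")
  mtx_abund(log(rna$values) - log(dna$values), scale = "log-ratio", mask = mask)
}
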