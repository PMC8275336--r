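# Per-feature DE regression under the six gene-copy normalization models.

#' Specify a DE analysis
#'
#' Bundles the choices defining one analysis: which of the six gene-copy
#' normalization models to fit, the zero pre-filtering policy, the response
#' family (linear on log abundances, or logistic on presence/absence), an
#' optional log read-depth covariate, an optional per-group random
#' intercept, and extra metadata covariates.
#'
#' Constraints: M2/M3/M5 need feature taxonomy; M4/M5/M6 need a DNA matrix;
#' the logistic response is incompatible with M4 (a presence/absence call
#' cannot be ratio-transformed) and with strict filtering (strict filtering
#' removes every RNA-zero sample, leaving a constant all-present response).
#'
#' @param model `"M1"` ... `"M6"`.
#' @param filter `"strict"`, `"semi-strict"` or `"lenient"`.
#' @param response `"linear"` or `"logistic"`.
#' @param depth_covariate include log RNA read depth as a covariate.
#' @param random_intercept optional metadata column name used as a random
#'   intercept grouping factor (fits a linear mixed model).
#' @param extra_covariates character vector of additional metadata columns.
#' @param fdr_alpha BH FDR threshold recorded with results.
#' @param min_n minimum unmasked samples (with both phenotype groups
#'   represented) required to test a feature.
#' @return an object of class `mtx_model_spec`.
#' @export
model_spec <- function(model = c("M1", "M2", "M3", "M4", "M5", "M6"),
                       filter = c("strict", "semi-strict", "lenient"),
                       response = c("linear", "logistic"),
                       depth_covariate = FALSE, random_intercept = NULL,
                       extra_covariates = character(), fdr_alpha = 0.05,
                       min_n = 5L) {
  model <- match.arg(model)
  filter <- match.arg(filter)
  response <- match.arg(response)
  if (response == "logistic" && model == "M4")
    stop("logistic response is incompatible with M4's ratio transform")
  if (response == "logistic" && filter == "strict")
    stop("logistic response is incompatible with strict filtering: ",
         "removing RNA-zero samples leaves a constant presence response")
  structure(list(model = model, filter = filter, response = response,
                 depth_covariate = isTRUE(depth_covariate),
                 random_intercept = random_intercept,
                 extra_covariates = extra_covariates,
                 fdr_alpha = fdr_alpha, min_n = as.integer(min_n)),
            class = "mtx_model_spec")
}

#' @export
print.mtx_model_spec <- function(x, ...) {
  cat(sprintf("<mtx_model_spec> %s, %s filtering, %s response%s%s\n",
              x$model, x$filter, x$response,
              if (x$depth_covariate) ", + log depth" else "",
              if (!is.null(x$random_intercept))
                paste0(", + (1|", x$random_intercept, ")") else ""))
  invisible(x)
}

#' Check whether a model spec applies to a dataset
#'
#' @param spec an [model_spec()].
#' @param taxonomy_known does the dataset map features to taxa?
#' @param has_dna is a paired DNA (MGX) matrix available?
#' @return list with `ok` (logical) and `reason` (NULL or character).
#' @export
spec_applicable <- function(spec, taxonomy_known, has_dna) {
  if (spec$model %in% c("M2", "M3", "M5") && !taxonomy_known)
    return(list(ok = FALSE, reason = "taxonomy unknown"))
  if (spec$model %in% c("M4", "M5", "M6") && !has_dna)
    return(list(ok = FALSE, reason = "no DNA matrix"))
  list(ok = TRUE, reason = NULL)
}

# Precompute the per-analysis matrices shared across features.
prepare_de_inputs <- function(dataset, spec) {
  rna_counts <- dataset$rna$counts
  taxa <- dataset$rna$feature_taxon
  app <- spec_applicable(spec, taxonomy_known = !is.null(taxa) && !anyNA(taxa),
                         has_dna = !is.null(dataset$dna))
  if (!app$ok) stop("model ", spec$model, " is inapplicable: ", app$reason)
  rna_tss <- tss_matrix(rna_counts)
  dna_tss <- if (spec$model %in% c("M4", "M5", "M6"))
    tss_matrix(dataset$dna$counts)
  # gene-copy estimate used for filtering and (M3/M5/M6) as covariate.
  # M1 and M2 have none: copy-aware filtering belongs to M3-M6 only, so
  # M2 keeps samples where its species' RNA total is barely detected and
  # inherits M1's vulnerability to noise at low within-species abundance
  copy <- switch(spec$model,
    M1 = ,
    M2 = NULL,
    M3 = {
      tot <- rowsum(rna_tss, group = taxa)
      tot[taxa, , drop = FALSE]
    },
    M5 = {
      tot <- rowsum(dna_tss, group = taxa)
      tot[taxa, , drop = FALSE]
    },
    M4 = ,
    M6 = dna_tss)
  if (!is.null(copy)) dimnames(copy) <- dimnames(rna_counts)
  flt <- apply_filter(rna_counts, copy, spec$filter)
  wtx <- if (spec$model %in% c("M2", "M3")) within_taxon_matrix(rna_tss, taxa)
  list(rna_counts = rna_counts, rna_tss = rna_tss, dna_tss = dna_tss,
       copy = copy, wtx = wtx, mask = flt$mask, dropped = flt$dropped)
}

#' Build the response and design for one feature
#'
#' Assembles, over the feature's unmasked samples, the model response
#' (log community-TSS RNA for M1/M5/M6, log within-taxon RNA for M2/M3, log
#' RNA/DNA ratio for M4, or a presence indicator in logistic mode) and the
#' covariate matrix (intercept, phenotype, the model's copy covariate, and
#' optional log depth / extra covariates).  Zeros surviving filtration are
#' half-min smoothed before the log, for responses and covariates alike.
#'
#' @param feature_id feature to prepare.
#' @param spec an [model_spec()].
#' @param prepared precomputed matrices from the internal preparation step
#'   (an element of a [run_de()] run); pass a dataset to have it computed.
#' @param metadata sample metadata with `phenotype` and (if used)
#'   `depth_rna`, extra covariate and grouping columns.
#' @return list with `y`, `X` (first data column named `phenotype`),
#'   `n_used`, `groups` (or NULL), or a list with `status = "filtered"` and
#'   a `reason` when the feature cannot be tested.
#' @export
build_design <- function(feature_id, spec, prepared, metadata) {
  if (inherits(prepared, "mtx_dataset"))
    prepared <- prepare_de_inputs(prepared, spec)
  i <- match(feature_id, rownames(prepared$rna_counts))
  if (is.na(i)) stop("unknown feature '", feature_id, "'")
  ctx <- design_context(spec, prepared, metadata)
  build_design_idx(i, spec, prepared, ctx)
}

# per-analysis quantities shared by every feature's design
design_context <- function(spec, prepared, metadata) {
  list(phen = metadata$phenotype,
       logdep = if (spec$depth_covariate) log(metadata$depth_rna),
       extra = if (length(spec$extra_covariates))
         lapply(spec$extra_covariates, function(cv) metadata[[cv]]),
       groups = if (!is.null(spec$random_intercept))
         metadata[[spec$random_intercept]],
       dropped = rownames(prepared$rna_counts) %in% prepared$dropped)
}

build_design_idx <- function(i, spec, prepared, ctx) {
  filtered <- function(reason) list(status = "filtered", reason = reason,
                                    n_used = 0L)
  if (ctx$dropped[i]) return(filtered("all-zero row"))
  keep <- prepared$mask[i, ]
  n <- sum(keep)
  if (n < spec$min_n) return(filtered("too few samples after filtering"))
  phen <- ctx$phen[keep]
  if (all(phen == phen[1])) return(filtered("one phenotype group left"))

  log_sm <- function(v) {
    s <- half_min_smooth(v)
    if (is.null(s)) NULL else log(s)
  }
  if (spec$response == "linear") {
    y <- switch(spec$model,
      M4 = {
        r <- half_min_smooth(prepared$rna_tss[i, keep])
        d <- half_min_smooth(prepared$dna_tss[i, keep])
        if (is.null(r) || is.null(d)) NULL else log(r) - log(d)
      },
      M2 = ,
      M3 = log_sm(prepared$wtx[i, keep]),
      log_sm(prepared$rna_tss[i, keep]))
    if (is.null(y)) return(filtered("no non-zero response values"))
  } else {
    y <- as.numeric(prepared$rna_counts[i, keep] > 0)
    if (all(y == y[1])) return(filtered("constant presence response"))
  }
  X <- cbind(`(Intercept)` = 1, phenotype = phen)
  if (spec$model %in% c("M3", "M5", "M6")) {
    cov_v <- switch(spec$model,
      M3 = ,
      M5 = log_sm(prepared$copy[i, keep]),
      M6 = log_sm(prepared$dna_tss[i, keep]))
    if (is.null(cov_v)) return(filtered("all-zero copy covariate"))
    X <- cbind(X, copy = cov_v)
  }
  if (!is.null(ctx$logdep)) X <- cbind(X, log_depth = ctx$logdep[keep])
  if (!is.null(ctx$extra)) {
    for (k in seq_along(ctx$extra)) {
      mm <- stats::model.matrix(~x, data.frame(x = ctx$extra[[k]][keep]))
      X <- cbind(X, mm[, -1, drop = FALSE])
    }
  }
  groups <- if (!is.null(ctx$groups)) ctx$groups[keep]
  list(y = y, X = X, n_used = n, groups = groups)
}

#' Fit one feature's DE regression
#'
#' Ordinary least squares with a Wald t-test on the phenotype coefficient
#' (residual degrees of freedom) for the linear family; maximum-likelihood
#' logistic regression with a Wald z-test for the logistic family; and a
#' linear mixed model with a per-group random intercept (Satterthwaite t)
#' when `groups` is supplied.  Rank-deficient designs and separated
#' logistic fits are flagged untestable rather than fitted.
#'
#' @param y response vector.
#' @param X design matrix whose column named `phenotype` is tested.
#' @param family `"linear"` or `"logistic"`.
#' @param groups optional random-intercept grouping vector (linear only).
#' @return list with `coef`, `se`, `stat`, `p`, `status` (and `reason` when
#'   not `"tested"`).
#' @export
fit_feature <- function(y, X, family = c("linear", "logistic"),
                        groups = NULL) {
  family <- match.arg(family)
  n <- length(y)
  p <- ncol(X)
  term <- match("phenotype", colnames(X))
  untestable <- function(reason) list(coef = NA_real_, se = NA_real_,
                                      stat = NA_real_, p = NA_real_,
                                      status = "filtered", reason = reason)
  if (n <= p) return(untestable("fewer samples than parameters"))
  if (!is.null(groups)) {
    if (family != "linear")
      stop("random intercepts are supported for the linear family only")
    df <- data.frame(y = y, X[, -1, drop = FALSE], g = groups,
                     check.names = FALSE)
    fml <- as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)[-1]),
                                         collapse = " + "), "+ (1 | g)"))
    fit <- tryCatch(lmerTest::lmer(fml, data = df), error = function(e) NULL)
    if (is.null(fit)) return(untestable("mixed model failed"))
    cs <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (is.null(cs) || !("phenotype" %in% rownames(cs)))
      return(untestable("mixed model failed"))
    return(list(coef = cs["phenotype", "Estimate"],
                se = cs["phenotype", "Std. Error"],
                stat = cs["phenotype", "t value"],
                p = cs["phenotype", "Pr(>|t|)"], status = "tested"))
  }
  if (family == "linear") {
    if (var(y) == 0) return(untestable("constant response"))
    fit <- stats::lm.fit(X, y)
    if (fit$rank < p) return(untestable("rank-deficient design"))
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    xtx_inv <- chol2inv(qr.R(fit$qr))
    se_all <- numeric(p)
    se_all[fit$qr$pivot] <- sqrt(sigma2 * diag(xtx_inv))
    se <- se_all[term]
    b <- fit$coefficients[term]
    if (se == 0) {
      # perfect fit: coefficient exact, no sampling noise to test against
      return(list(coef = unname(b), se = 0, stat = Inf,
                  p = if (b == 0) 1 else 0, status = "tested"))
    }
    tval <- b / se
    list(coef = unname(b), se = unname(se), stat = unname(tval),
         p = unname(2 * pt(-abs(tval), df = n - p)), status = "tested")
  } else {
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial(),
                               control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < p)
      return(untestable("logistic fit failed or rank-deficient"))
    if (any(abs(fit$coefficients) > 15))
      return(untestable("probable complete separation"))
    covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    se_all <- numeric(p)
    se_all[fit$qr$pivot] <- sqrt(diag(covmat))
    se <- se_all[term]
    b <- fit$coefficients[term]
    z <- b / se
    list(coef = unname(b), se = unname(se), stat = unname(z),
         p = unname(2 * pnorm(-abs(z))), status = "tested")
  }
}

#' Run a DE analysis over all features of a dataset
#'
#' Prepares (normalizes, filters, smooths) every feature per the spec, fits
#' the per-feature regression, and applies Benjamini-Hochberg FDR
#' correction across tested features.  Filtered/untestable features are
#' retained in the output with `status = "filtered"` and no p-value; they
#' are scored negative for DE downstream.
#'
#' @param dataset an `mtx_dataset` (see [make_dataset()]) or a list with
#'   `rna` ([mtx_counts()]), optional `dna`, and `metadata`.
#' @param spec an [model_spec()].
#' @return data.frame of class `mtx_de_result` with columns `feature`,
#'   `coef`, `stderr`, `pval`, `qval`, `n_used`, `status`, `reason`.
#' @examples
#' d <- make_dataset("null", seed = 1, n_species = 5, pool_size = 60,
#'                   genes_per_species = 30, n_samples = 30,
#'                   depth_range = c(2000, 4000))
#' res <- run_de(d, model_spec("M6", "strict"))
#' head(res[order(res$pval), ])
#' @export
run_de <- function(dataset, spec) {
  stopifnot(inherits(spec, "mtx_model_spec"))
  metadata <- dataset$metadata
  stopifnot(identical(metadata$sample_id, colnames(dataset$rna$counts)))
  prepared <- prepare_de_inputs(dataset, spec)
  ctx <- design_context(spec, prepared, metadata)
  ids <- rownames(prepared$rna_counts)
  nf <- length(ids)
  coef_ <- stderr_ <- pval <- rep(NA_real_, nf)
  n_used <- integer(nf)
  status <- rep("filtered", nf)
  reason <- rep(NA_character_, nf)
  for (k in seq_len(nf)) {
    des <- build_design_idx(k, spec, prepared, ctx)
    if (!is.null(des$status) && des$status == "filtered") {
      reason[k] <- des$reason
      next
    }
    f <- fit_feature(des$y, des$X, family = spec$response,
                     groups = des$groups)
    status[k] <- f$status
    if (f$status == "tested") {
      n_used[k] <- des$n_used
      coef_[k] <- f$coef
      stderr_[k] <- f$se
      pval[k] <- f$p
    } else {
      reason[k] <- f$reason
    }
  }
  tested <- status == "tested"
  qval <- rep(NA_real_, nf)
  qval[tested] <- p.adjust(pval[tested], method = "BH")
  out <- data.frame(feature = ids, coef = coef_, stderr = stderr_,
                    pval = pval, qval = qval, n_used = n_used,
                    status = status, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "n_filtered") <- sum(!tested)
  class(out) <- c("mtx_de_result", class(out))
  out
}
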