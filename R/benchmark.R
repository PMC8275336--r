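# Ground-truth scoring (TPR/FPR), the evaluation grid and report rendering.

#' Score a DE result against ground truth
#'
#' A true positive is a truth-positive feature with BH `q < alpha_fdr`
#' (conservative: FDR-corrected).  A false positive is a truth-negative
#' feature with nominal `p < alpha_nominal`.  Features filtered before
#' testing are counted as negative calls: a filtered truth-positive is a
#' false negative and a filtered truth-negative is a true negative.  TPR is
#' the fraction of ALL truth-positives that were TPs (undefined -- `NA` --
#' when the dataset has no positives), so filtering can only cost
#' sensitivity.  FPR is the fraction of analyzed (tested) truth-negatives
#' that were FPs: unanalyzed features are negative calls by construction
#' and carry no information about the test's type-I error, and a
#' well-calibrated model must sit at the nominal 0.05 on null data
#' regardless of how aggressively technical zeros were filtered.
#'
#' @param results an `mtx_de_result` from [run_de()].
#' @param truth data.frame with columns `feature` and `label`
#'   ("positive"/"negative") covering every feature in `results`.
#' @param alpha_fdr,alpha_nominal thresholds for TP and FP calls.
#' @return one-row data.frame of class `mtx_eval` with counts, rates,
#'   Wilson 95% CIs and `n_filtered`.
#' @export
score_de <- function(results, truth, alpha_fdr = 0.05,
                     alpha_nominal = 0.05) {
  m <- match(results$feature, truth$feature)
  if (anyNA(m))
    stop("feature(s) in results missing from truth: ",
         paste(utils::head(results$feature[is.na(m)], 3), collapse = ", "))
  lab <- truth$label[m]
  pos <- lab == "positive"
  tested <- results$status == "tested"
  tp_call <- tested & !is.na(results$qval) & results$qval < alpha_fdr
  fp_call <- tested & !is.na(results$pval) & results$pval < alpha_nominal
  tp <- sum(pos & tp_call)
  fn <- sum(pos) - tp
  fp <- sum(!pos & fp_call)
  tn <- sum(!pos) - fp
  n_pos <- sum(pos)
  n_neg_tested <- sum(!pos & tested)
  tpr <- if (n_pos > 0) tp / n_pos else NA_real_
  fpr <- if (n_neg_tested > 0) fp / n_neg_tested else NA_real_
  ci_t <- if (n_pos > 0) proportion_ci(tp, n_pos) else c(NA_real_, NA_real_)
  ci_f <- if (n_neg_tested > 0) proportion_ci(fp, n_neg_tested)
          else c(NA_real_, NA_real_)
  out <- data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
                    n_pos = n_pos, n_neg_tested = n_neg_tested,
                    tpr = tpr, fpr = fpr,
                    tpr_lo = ci_t[1], tpr_hi = ci_t[2],
                    fpr_lo = ci_f[1], fpr_hi = ci_f[2],
                    n_filtered = sum(!tested))
  class(out) <- c("mtx_eval", class(out))
  out
}

#' Wilson score interval for a proportion
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
proportion_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  denom <- 1 + z^2 / n
  center <- (ph + z^2 / (2 * n)) / denom
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Run the full evaluation grid
#'
#' For every requested preset, generates `replicates` datasets (seeds
#' derived deterministically from `seed`), runs each applicable
#' (model, filter, response) combination and scores it against ground
#' truth.  Inapplicable combinations (taxonomy-dependent models on
#' orthogroup-level presets; logistic with strict filtering; logistic M4)
#' are reported as skipped with a reason.  Per combination, TP/FP counts
#' are pooled over replicates and mean per-replicate rates are reported.
#'
#' @param presets character vector of preset names.
#' @param models,filters,responses grid axes.
#' @param replicates datasets per preset.
#' @param seed master seed.
#' @param depth_covariate passed to [model_spec()].
#' @param sim_args list of extra arguments for [make_dataset()] (e.g.
#'   [desk_scale()]).
#' @return data.frame with one row per (preset, model, filter, response).
#' @export
run_grid <- function(presets = preset_names(),
                     models = paste0("M", 1:6),
                     filters = c("lenient", "semi-strict", "strict"),
                     responses = "linear",
                     replicates = 10, seed = 1, depth_covariate = FALSE,
                     sim_args = list()) {
  rows <- list()
  for (preset in presets) {
    datasets <- lapply(seq_len(replicates), function(r) {
      do.call(make_dataset,
              c(list(preset = preset, seed = grid_seed(seed, preset, r)),
                sim_args))
    })
    tax_known <- datasets[[1]]$taxonomy_known
    for (model in models) for (filter in filters) for (resp in responses) {
      skip_reason <- NULL
      if (resp == "logistic" && model == "M4")
        skip_reason <- "logistic response incompatible with ratio transform"
      else if (resp == "logistic" && filter == "strict")
        skip_reason <- "logistic response incompatible with strict filtering"
      else {
        app <- spec_applicable(list(model = model), tax_known, TRUE)
        if (!app$ok) skip_reason <- app$reason
      }
      if (!is.null(skip_reason)) {
        rows[[length(rows) + 1]] <- data.frame(
          preset = preset, model = model, filter = filter, response = resp,
          replicates = 0L, tp = NA, fp = NA, tn = NA, fn = NA,
          tpr = NA_real_, fpr = NA_real_,
          tpr_lo = NA_real_, tpr_hi = NA_real_,
          fpr_lo = NA_real_, fpr_hi = NA_real_, n_filtered = NA,
          skipped = TRUE, reason = skip_reason, stringsAsFactors = FALSE)
        next
      }
      spec <- model_spec(model, filter, resp,
                         depth_covariate = depth_covariate)
      evs <- lapply(datasets, function(d) score_de(run_de(d, spec), d$truth))
      ev <- do.call(rbind, evs)
      npos <- ev$n_pos
      nneg <- ev$n_neg_tested
      ci_t <- if (sum(npos) > 0) proportion_ci(sum(ev$tp), sum(npos))
              else c(NA_real_, NA_real_)
      ci_f <- proportion_ci(sum(ev$fp), sum(nneg))
      rows[[length(rows) + 1]] <- data.frame(
        preset = preset, model = model, filter = filter, response = resp,
        replicates = replicates,
        tp = sum(ev$tp), fp = sum(ev$fp), tn = sum(ev$tn), fn = sum(ev$fn),
        tpr = if (sum(npos) > 0) mean(ev$tpr) else NA_real_,
        fpr = mean(ev$fpr),
        tpr_lo = ci_t[1], tpr_hi = ci_t[2],
        fpr_lo = ci_f[1], fpr_hi = ci_f[2],
        n_filtered = sum(ev$n_filtered),
        skipped = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# deterministic per-(preset, replicate) seed below 2^31
grid_seed <- function(seed, preset, replicate) {
  h <- sum(utf8ToInt(preset) * seq_along(utf8ToInt(preset)))
  (as.integer(seed) * 1009L + h * 31L + replicate * 7919L) %% 2147483647L
}

#' Render benchmark reports
#'
#' Writes the grid as a machine-readable TSV, a TPR/FPR heatmap (undefined
#' TPR cells are labeled "undef") and a bar chart with 95% CI error bars.
#'
#' @param grid result of [run_grid()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
render_report <- function(grid, outdir) {
  stopifnot(nrow(grid) > 0)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(outdir, "benchmark_grid.tsv")
  write.table(grid, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- grid[!grid$skipped, , drop = FALSE]
  g$cell <- paste(g$model, g$filter, g$response)
  long <- rbind(
    data.frame(g[c("preset", "cell")], metric = "TPR", value = g$tpr),
    data.frame(g[c("preset", "cell")], metric = "FPR", value = g$fpr))
  heat <- ggplot2::ggplot(long, ggplot2::aes(x = preset, y = cell,
                                             fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(value), "undef",
                     sprintf("%.2f", value))), size = 2.5) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  heat_path <- file.path(outdir, "benchmark_heatmap.pdf")
  ggplot2::ggsave(heat_path, heat, width = 9, height = 6)
  bars <- ggplot2::ggplot(g, ggplot2::aes(x = model, y = fpr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = fpr_lo,
                                        ymax = fpr_hi), width = 0.25) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::facet_grid(filter ~ preset) +
    ggplot2::labs(y = "FPR (pooled 95% CI)", x = NULL) +
    ggplot2::theme_minimal()
  bars_path <- file.path(outdir, "benchmark_fpr_bars.pdf")
  ggplot2::ggsave(bars_path, bars, width = 10, height = 6)
  invisible(c(tsv, heat_path, bars_path))
}

utils::globalVariables(c("cell", "value", "metric", "fpr_lo", "fpr_hi",
                         "preset", "model", "fpr"))
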