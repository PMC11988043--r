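## Ablation harness: varies exactly one architecture axis at a time and
## trains/evaluates every variant under an identical budget and seed set.

#' Run an ablation experiment
#'
#' Supported axes, mirroring the study design:
#' * `cfs_count`: number of encoder stages with cross-modality feature
#'   supplementation (0..6; k means stages 1..k).
#' * `fusion_scheme`: decoder cross-modality step — `"cff"` (the full
#'   architecture), `"addition"`, `"max"`, `"concatenation"`.
#' * `modality`: `"rgbd"`, `"rgb"`, `"depth"` (single-branch baselines).
#' * `topology`: `"multiscale"`, `"early"` (4-channel input, one backbone),
#'   `"late"` (independent backbones, concatenated final features).
#'
#' @param axis one of `"cfs_count"`, `"fusion_scheme"`, `"modality"`,
#'   `"topology"`.
#' @param values vector of axis values to compare.
#' @param manifest manifest data.frame with train/test splits.
#' @param base_mconfig,base_tconfig shared configuration; only the ablation
#'   axis (and the per-run seed) varies between runs.
#' @param seeds integer vector of training seeds per variant.
#' @param pairs optional pre-loaded pairs (skips repeated disk reads).
#' @return data.frame with one row per (variant, seed): MAE, RMSE, R2, n.
#' @export
run_ablation <- function(axis = c("cfs_count", "fusion_scheme", "modality",
                                  "topology"),
                         values, manifest, base_mconfig, base_tconfig,
                         seeds = 1:5, pairs = NULL) {
  axis <- match.arg(axis)
  if (is.null(pairs))
    pairs <- load_pairs(manifest, gaussian_sigma = base_tconfig$gaussian_sigma)
  rows <- list()
  for (val in values) {
    mcfg <- base_mconfig
    if (axis == "cfs_count") {
      k <- as.integer(val)
      if (k < 0L || k > 6L) stop("cfs_count must be in 0..6")
      mcfg$cfs_stages <- if (k == 0L) integer(0) else seq_len(k)
    } else if (axis == "fusion_scheme") {
      if (!val %in% c("cff", "addition", "max", "concatenation"))
        stop("invalid fusion scheme: ", val)
      mcfg$fusion_scheme <- val
    } else if (axis == "modality") {
      if (!val %in% c("rgbd", "rgb", "depth"))
        stop("invalid modality: ", val)
      mcfg$modality <- val
    } else {
      if (!val %in% c("multiscale", "early", "late"))
        stop("invalid topology: ", val)
      mcfg$topology <- val
    }
    for (s in seeds) {
      tcfg <- base_tconfig
      tcfg$seed <- as.integer(s)
      fit <- train(manifest, mcfg, tcfg, pairs = pairs)
      rep <- evaluate(fit$checkpoint, manifest, "test", pairs = pairs)$report
      rows[[length(rows) + 1L]] <-
        data.frame(axis = axis, variant = as.character(val), seed = s,
                   mae = rep$mae, rmse = rep$rmse, r2 = rep$r2, n = rep$n,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize an ablation table as mean and sd over seeds
#' @param results data.frame from [run_ablation()].
#' @export
summarize_ablation <- function(results) {
  agg <- function(f) stats::aggregate(cbind(mae, rmse, r2) ~ variant,
                                      data = results, FUN = f)
  m <- agg(mean)
  s <- agg(stats::sd)
  data.frame(variant = m$variant,
             mae_mean = m$mae, mae_sd = s$mae,
             rmse_mean = m$rmse, rmse_sd = s$rmse,
             r2_mean = m$r2, r2_sd = s$r2,
             stringsAsFactors = FALSE)
}
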