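# Threshold selection: evaluate every mask in the series by cross-species
# sensitivity (number of commonly-selected genes) and accuracy (Pearson r
# of the two species' log2 tissue ratios over those genes), then pick the
# operating threshold by a maximin rule over the min-max-scaled curves.

#' Per-probe-set log2 ratio between two sample groups
#'
#' @param expr log2 expression matrix (probe sets x samples).
#' @param groupA,groupB disjoint, non-empty sets of sample ids (columns).
#' @return named numeric vector: mean log2 expression(A) - mean(B).
#' @export
log_ratio <- function(expr, groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop_csh("log_ratio: empty sample group", "value_error")
  if (length(intersect(groupA, groupB)))
    stop_csh("log_ratio: groups overlap", "value_error")
  miss <- setdiff(c(groupA, groupB), colnames(expr))
  if (length(miss))
    stop_csh(paste("log_ratio: samples not in matrix:", paste(miss, collapse = ", ")),
             "value_error")
  rowMeans(expr[, groupA, drop = FALSE]) - rowMeans(expr[, groupB, drop = FALSE])
}

#' Commonly-selected genes across two species
#'
#' Genes whose tissue log2 ratio is at least `log2(fold)` in magnitude in
#' *both* species. Direction is not required to agree unless
#' `concordant = TRUE`.
#'
#' @param ratios_ref,ratios_target named log2-ratio vectors for the
#'   reference and target species; the shared gene universe is the
#'   intersection of names (must be non-empty).
#' @param fold fold-change cutoff (default 2).
#' @param concordant also require the same ratio sign in both species.
#' @return sorted character vector of selected gene (probe-set) ids.
#' @export
commonly_selected <- function(ratios_ref, ratios_target, fold = 2,
                              concordant = FALSE) {
  shared <- intersect(names(ratios_ref), names(ratios_target))
  if (!length(shared))
    stop_csh("commonly_selected: disjoint gene universes", "value_error")
  a <- ratios_ref[shared]
  b <- ratios_target[shared]
  lf <- log2(fold)
  sel <- abs(a) >= lf & abs(b) >= lf
  if (concordant) sel <- sel & (sign(a) == sign(b))
  sort(shared[sel])
}

#' Sensitivity/accuracy curve over a mask series
#'
#' For each mask: summarize the target species with the mask, compute the
#' target tissue ratio, find the commonly-selected genes against the
#' (unmasked) reference ratio, and record the Pearson correlation of the
#' two species' log2 ratios over those genes.
#'
#' @param norm_target normalized linear-scale target probe matrix.
#' @param masks list of [mask_file()]s (e.g. [build_threshold_series()]).
#' @param map probe map.
#' @param samples sample sheet (used to form the target PES/ES groups).
#' @param ref_ratio named log2 PES/ES ratio vector of the reference species
#'   (computed once, unmasked, via [log_ratio()]).
#' @param genotype optionally restrict the target ratio to one genotype.
#' @param fold fold-change cutoff for common selection.
#' @param concordant passed to [commonly_selected()].
#' @param min_probes passed to [summarize_expression()].
#' @return `data.frame` with columns `threshold`, `n_probes_retained`,
#'   `n_probesets_retained`, `n_common_genes`, `pearson_r` (`NA` when fewer
#'   than 3 common genes).
#' @export
threshold_curve <- function(norm_target, masks, map, samples, ref_ratio,
                            genotype = NULL, fold = 2, concordant = FALSE,
                            min_probes = 1L) {
  tgt <- samples[samples$species == "target", , drop = FALSE]
  if (!is.null(genotype)) tgt <- tgt[tgt$genotype %in% genotype, , drop = FALSE]
  gPES <- tgt$sample_id[tgt$tissue == "PES"]
  gES <- tgt$sample_id[tgt$tissue == "ES"]
  if (!length(gPES) || !length(gES))
    stop_csh("threshold_curve: need both ES and PES target samples", "schema_error")

  rows <- lapply(masks, function(mask) {
    masked <- apply_mask(norm_target, mask)
    expr <- summarize_expression(masked, map, min_probes = min_probes,
                                 verbose = FALSE)
    ratio <- log_ratio(expr, gPES, gES)
    common <- commonly_selected(ref_ratio, ratio, fold = fold,
                                concordant = concordant)
    r <- if (length(common) >= 3L)
      cor(ref_ratio[common], ratio[common]) else NA_real_
    data.frame(threshold = mask$threshold,
               n_probes_retained = nrow(masked),
               n_probesets_retained = nrow(expr),
               n_common_genes = length(common),
               pearson_r = r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pick the operating threshold from a sensitivity/accuracy curve
#'
#' Sensitivity (`n_common_genes`) and accuracy (`pearson_r`) are min-max
#' scaled to \[0, 1\] over the thresholds with a defined correlation; the
#' chosen threshold maximizes `min(scaled sensitivity, scaled accuracy)` —
#' the formalization of the point where the two curves intersect. Ties go
#' to the smaller threshold (a constant curve therefore returns the
#' smallest threshold).
#'
#' @param curves a [threshold_curve()] `data.frame`.
#' @return the selected threshold (numeric scalar).
#' @export
pick_threshold <- function(curves) {
  ok <- !is.na(curves$pearson_r)
  if (sum(ok) < 2L)
    stop_csh("pick_threshold: need >= 2 thresholds with a defined correlation",
             "value_error")
  cv <- curves[ok, , drop = FALSE]
  cv <- cv[order(cv$threshold), , drop = FALSE]
  scale01 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) rep(1, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
  }
  score <- pmin(scale01(cv$n_common_genes), scale01(cv$pearson_r))
  cv$threshold[which.max(score)] # which.max: first (smallest threshold) on ties
}
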