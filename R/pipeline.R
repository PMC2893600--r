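# End-to-end workflow: preprocess -> threshold-series masking ->
# per-threshold summarization -> threshold selection -> double-mask ->
# differential expression -> mask-condition comparison. Every written
# artifact carries a '# cshmask ...' provenance header so a rerun with the
# same inputs reproduces it byte-identically.

#' Run the full cross-species masking pipeline
#'
#' @param target,reference linear-scale probe matrices (raw) for the two
#'   species.
#' @param map probe map.
#' @param samples combined sample sheet (both species).
#' @param sfp character vector of SFP probe ids.
#' @param thresholds masking threshold series (default [mask_thresholds()]).
#' @param bg_method background-correction method
#'   (see [background_correct()]).
#' @param genotype optional genotype restriction for the threshold-curve
#'   tissue ratio.
#' @param fold fold cutoff for commonly-selected genes and DE.
#' @param p_cut,fdr_cut DE significance cutoffs.
#' @param min_probes minimum retained probes per summarized probe set.
#' @param exclude probe-set id regexes excluded from DE testing.
#' @param out_dir if non-NULL, intermediate TSV files are written there.
#' @return list with `curve` (threshold curve incl. the unmasked point at
#'   threshold 0), `threshold` (picked), `masks` (ISV series), `sfp_mask`,
#'   `double_mask`, `expr` (list: `none`, `isv`, `double`), `de` (per
#'   tissue, per mask condition), `compare` (per tissue,
#'   [mask_condition_compare()]), `ref_ratio`, `params`.
#' @export
run_pipeline <- function(target, reference, map, samples, sfp,
                         thresholds = mask_thresholds(),
                         bg_method = "rma_convolution",
                         genotype = NULL, fold = 2,
                         p_cut = 0.001, fdr_cut = 0.05, min_probes = 1L,
                         exclude = NULL, out_dir = NULL) {
  samples <- validate_sample_sheet(samples)
  params <- mask_rule_params(samples, species = "target")

  norm_tgt <- quantile_normalize(background_correct(target, bg_method))
  norm_ref <- quantile_normalize(background_correct(reference, bg_method))

  # reference branch: summarized once, unmasked
  ref_expr <- summarize_expression(norm_ref, map, min_probes = min_probes,
                                   verbose = FALSE)
  ref_sheet <- samples[samples$species == "reference", ]
  ref_ratio <- log_ratio(ref_expr,
                         ref_sheet$sample_id[ref_sheet$tissue == "PES"],
                         ref_sheet$sample_id[ref_sheet$tissue == "ES"])

  masks <- build_threshold_series(norm_tgt, thresholds, params)
  no_mask <- mask_file(character(0), threshold = 0, P = params$P,
                       provenance = "ISV")
  curve <- threshold_curve(norm_tgt, c(list(`0` = no_mask), masks), map,
                           samples, ref_ratio, genotype = genotype,
                           fold = fold, min_probes = min_probes)
  picked <- pick_threshold(curve)

  isv_mask <- if (picked == 0) no_mask else masks[[format(picked, trim = TRUE)]]
  sfp_mask <- build_sfp_mask(sfp, rownames(target))
  double_mask <- combine_masks(isv_mask, sfp_mask)

  expr <- list(
    none = summarize_expression(norm_tgt, map, min_probes = min_probes,
                                verbose = FALSE),
    isv = summarize_expression(apply_mask(norm_tgt, isv_mask), map,
                               min_probes = min_probes, verbose = FALSE),
    double = summarize_expression(apply_mask(norm_tgt, double_mask), map,
                                  min_probes = min_probes, verbose = FALSE)
  )

  tgt_sheet <- samples[samples$species == "target", ]
  genos <- sort(unique(tgt_sheet$genotype))
  de <- list(); compare <- list()
  if (length(genos) == 2L) {
    for (tis in c("ES", "PES")) {
      gA <- tgt_sheet$sample_id[tgt_sheet$tissue == tis &
                                  tgt_sheet$genotype == genos[1L]]
      gB <- tgt_sheet$sample_id[tgt_sheet$tissue == tis &
                                  tgt_sheet$genotype == genos[2L]]
      de[[tis]] <- lapply(expr, function(e)
        ttest_de(e, gA, gB, p_cut = p_cut, fdr_cut = fdr_cut,
                 fold_cut = fold, exclude = exclude))
      compare[[tis]] <- mask_condition_compare(
        de_genes(de[[tis]]$none), de_genes(de[[tis]]$isv),
        de_genes(de[[tis]]$double))
    }
  }

  res <- list(curve = curve, threshold = picked, masks = masks,
              sfp_mask = sfp_mask, double_mask = double_mask,
              expr = expr, de = de, compare = compare,
              ref_ratio = ref_ratio, params = params)
  if (!is.null(out_dir)) write_pipeline_outputs(res, norm_tgt, out_dir)
  res
}

write_pipeline_outputs <- function(res, norm_tgt, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- function(stage, ...) {
    sprintf("cshmask %s v%s; %s", stage, packageVersion("cshmask"),
            paste(..., sep = "; "))
  }
  write_probe_matrix(norm_tgt, file.path(out_dir, "norm_target.tsv"),
                     comments = prov("preprocess", "bg+quantile-normalized"))
  for (nm in names(res$masks))
    write_mask_file(res$masks[[nm]],
                    file.path(out_dir, sprintf("mask_t%s.txt", nm)))
  write_mask_file(res$double_mask, file.path(out_dir, "mask_double.txt"))
  write_tsv(res$curve, file.path(out_dir, "threshold_curve.tsv"),
            comments = prov("select", sprintf("picked=%g", res$threshold)))
  for (cond in names(res$expr)) {
    e <- res$expr[[cond]]
    df <- data.frame(probeset_id = rownames(e), as.data.frame(unclass_plain(e)),
                     check.names = FALSE)
    write_tsv(df, file.path(out_dir, sprintf("expr_%s.tsv", cond)),
              comments = prov("summarize", paste("mask =", cond)))
  }
  for (tis in names(res$de))
    for (cond in names(res$de[[tis]]))
      write_tsv(res$de[[tis]][[cond]],
                file.path(out_dir, sprintf("de_%s_%s.tsv", tis, cond)),
                comments = prov("de", paste("tissue =", tis),
                                paste("mask =", cond)))
  invisible(out_dir)
}

write_tsv <- function(df, path, comments = NULL) {
  con <- open_out(path)
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
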