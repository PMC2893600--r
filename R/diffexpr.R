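# Differential expression between genotypes within a tissue: per-probe-set
# two-sample t-test on log2 expression, BH FDR across all tested probe
# sets, plus a 2-fold ratio cutoff; and the three-way comparison of DE sets
# across masking conditions (none / ISV / double).

#' Per-probe-set two-sample t-test
#'
#' Pooled-variance (default) or Welch t-test of `groupA` vs `groupB` on
#' log2 expression, with Benjamini-Hochberg FDR across all tested probe
#' sets. A probe set is `significant` iff `p < p_cut`, `fdr < fdr_cut` and
#' `|log2fc| >= log2(fold_cut)`. Probe sets matching any `exclude` regex
#' (e.g. microsymbiont controls) are removed before testing so they do not
#' enter the FDR correction.
#'
#' @param expr log2 expression matrix.
#' @param groupA,groupB disjoint sample-id sets, each of size >= 2.
#' @param p_cut,fdr_cut,fold_cut significance cutoffs
#'   (defaults 0.001, 0.05, 2).
#' @param exclude character vector of regular expressions; matching
#'   probe-set ids are excluded from testing.
#' @param welch use the Welch (unequal-variance) test instead of the
#'   pooled-variance test.
#' @return `data.frame` with `probeset_id`, `log2fc` (A - B), `t_stat`,
#'   `p_value`, `fdr`, `significant`.
#' @export
ttest_de <- function(expr, groupA, groupB, p_cut = 0.001, fdr_cut = 0.05,
                     fold_cut = 2, exclude = NULL, welch = FALSE) {
  if (length(intersect(groupA, groupB)))
    stop_csh("ttest_de: groups overlap", "value_error")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_csh("ttest_de: each group needs >= 2 samples", "value_error")
  miss <- setdiff(c(groupA, groupB), colnames(expr))
  if (length(miss))
    stop_csh(paste("ttest_de: samples not in matrix:", paste(miss, collapse = ", ")),
             "value_error")
  keep <- rep(TRUE, nrow(expr))
  for (pat in exclude) keep <- keep & !grepl(pat, rownames(expr))
  x <- expr[keep, , drop = FALSE]

  A <- x[, groupA, drop = FALSE]
  B <- x[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1L)
  vB <- rowSums((B - mB)^2) / (nB - 1L)
  diff <- mA - mB
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
    se <- sqrt(se2)
  } else {
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2L, length(se))
  }
  tt <- diff / se
  p <- 2 * pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  zero <- se == 0
  tt[zero & diff == 0] <- 0
  p[zero & diff == 0] <- 1       # equal means, no spread: no evidence
  tt[zero & diff != 0] <- sign(diff[zero & diff != 0]) * Inf
  p[zero & diff != 0] <- 0
  fdr <- bh_fdr(p)
  data.frame(probeset_id = rownames(x), log2fc = diff, t_stat = tt,
             p_value = p, fdr = fdr,
             significant = p < p_cut & fdr < fdr_cut &
               abs(diff) >= log2(fold_cut),
             row.names = NULL)
}

#' Significant probe-set ids from a [ttest_de()] result
#' @param de a `data.frame` from [ttest_de()].
#' @return character vector of significant probe-set ids.
#' @export
de_genes <- function(de) de$probeset_id[de$significant]

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_csh("bh_fdr: p-values must be in [0, 1]", "value_error")
  p.adjust(pvalues, method = "BH")
}

#' Compare DE sets across masking conditions
#'
#' Given the significant probe-set ids from the same contrast under no
#' masking, ISV masking, and double-masking, label the putative artifacts:
#' genes DE before masking but lost after double-masking are putative false
#' positives caused by ISV regions and/or SFPs; genes DE after ISV masking
#' but lost after double-masking are putative false positives caused by
#' SFPs; genes DE only after double-masking are putative false negatives.
#'
#' @param de_none,de_isv,de_double character sets of significant ids.
#' @return list with `fp_isv_sfp`, `fp_sfp`, `fn` counts, the corresponding
#'   id sets (`fp_isv_sfp_ids`, ...), and `venn`, the 7-region Venn counts.
#' @export
mask_condition_compare <- function(de_none, de_isv, de_double) {
  de_none <- unique(as.character(de_none))
  de_isv <- unique(as.character(de_isv))
  de_double <- unique(as.character(de_double))
  fp1 <- setdiff(de_none, de_double)
  fp2 <- setdiff(de_isv, de_double)
  fn <- setdiff(de_double, union(de_none, de_isv))
  all_ids <- union(union(de_none, de_isv), de_double)
  inN <- all_ids %in% de_none
  inI <- all_ids %in% de_isv
  inD <- all_ids %in% de_double
  venn <- c(
    only_none = sum(inN & !inI & !inD),
    only_isv = sum(!inN & inI & !inD),
    only_double = sum(!inN & !inI & inD),
    none_isv = sum(inN & inI & !inD),
    none_double = sum(inN & !inI & inD),
    isv_double = sum(!inN & inI & inD),
    all_three = sum(inN & inI & inD)
  )
  list(fp_isv_sfp = length(fp1), fp_sfp = length(fp2), fn = length(fn),
       fp_isv_sfp_ids = sort(fp1), fp_sfp_ids = sort(fp2), fn_ids = sort(fn),
       venn = venn)
}
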