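# Masked multi-chip summarization: per probe set, fit
#   log2(intensity) = probe effect + sample effect + residual
# by Tukey median polish; expression = overall + sample effect. This is the
# RMA summarization step restricted to retained (unmasked) probes.

#' Summarize retained probes into probe-set expression
#'
#' Per probe set, log2 intensities are decomposed into probe and sample
#' effects by median polish (row sweep then column sweep, at most
#' `maxiter` iterations, relative tolerance `eps` on the total absolute
#' residual); the returned expression is overall + sample effect. Probe
#' sets with fewer than `min_probes` retained probes are dropped (a
#' message reports the attrition).
#'
#' @param masked masked, normalized probe matrix (linear scale; log2 taken
#'   internally — a log2-scale matrix is used as-is).
#' @param map probe map (`data.frame` with `probe_id`, `probeset_id`),
#'   see [read_probe_map()].
#' @param min_probes minimum retained probes for a probe set to be reported.
#' @param maxiter,eps median-polish iteration cap and relative tolerance.
#' @param verbose report probe-set attrition with a message.
#' @return log2 expression matrix, probe sets x samples
#'   (`scale` attribute `"log2"`).
#' @export
summarize_expression <- function(masked, map, min_probes = 1L,
                                 maxiter = 10L, eps = 0.01, verbose = TRUE) {
  if (min_probes < 1L) stop_csh("min_probes must be >= 1", "value_error")
  if (nrow(masked) == 0L) {
    warn_csh("summarize_expression: empty probe matrix")
    out <- matrix(numeric(0), 0L, ncol(masked),
                  dimnames = list(NULL, colnames(masked)))
    return(set_scale(out, "log2"))
  }
  x <- if (probe_scale(masked) == "linear") log2(unclass_plain(masked))
       else unclass_plain(masked)

  ps <- map$probeset_id[match(rownames(x), map$probe_id)]
  if (anyNA(ps))
    stop_csh("probe(s) in matrix missing from the probe map", "schema_error")

  ord <- order(ps, rownames(x))
  x <- x[ord, , drop = FALSE]
  ps <- ps[ord]
  sizes <- rle(ps)
  n_total_sets <- length(unique(map$probeset_id))
  keep_set <- sizes$lengths >= min_probes
  if (!all(keep_set)) {
    keep_row <- rep(keep_set, sizes$lengths)
    x <- x[keep_row, , drop = FALSE]
    sizes <- list(values = sizes$values[keep_set],
                  lengths = sizes$lengths[keep_set])
  }
  n_kept <- length(sizes$values)
  if (verbose) message(sprintf("summarize_expression: %d/%d probe sets retained (%d dropped by masking/min_probes)",
                  n_kept, n_total_sets, n_total_sets - n_kept))
  if (n_kept == 0L) {
    warn_csh("summarize_expression: no probe set survives masking")
    out <- matrix(numeric(0), 0L, ncol(masked),
                  dimnames = list(NULL, colnames(masked)))
    return(set_scale(out, "log2"))
  }
  expr <- medpolish_groups(x, as.integer(sizes$lengths),
                           maxiter = as.integer(maxiter), eps = eps)
  dimnames(expr) <- list(sizes$values, colnames(masked))
  set_scale(expr, "log2")
}
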