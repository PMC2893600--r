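# ISV mask construction over a threshold series, SFP masks, double-masking.
#
# The retention rule: a probe is kept iff at least R of the Ts samples are
# at/above the signal-intensity threshold (R = replicates per sample type);
# equivalently it is masked iff it falls below threshold in at least
# ceil(P * Ts) = Ts - R + 1 samples, where P is the "defined percentage".
# Masks are global: a masked probe is dropped for all samples.

#' Default masking intensity thresholds
#'
#' The standard 16-point series spanning the intensity range of a
#' normalized chip.
#'
#' @return numeric vector of 16 thresholds.
#' @export
mask_thresholds <- function() {
  c(5, 7, 10, 15, 20, 30, 40, 60, 80, 100, 120, 160, 320, 640, 1280, 2560)
}

#' Defined masking percentage P
#'
#' For a balanced design with `Ts` total sample files, `R` replicates per
#' sample type and `S` sample types, a probe is retained iff at least `R`
#' samples are at/above threshold, so it is masked iff below threshold in at
#' least `Ts - R + 1` samples: `P = (Ts - R + 1) / Ts`, reported rounded to
#' two decimals. For `Ts = 12, R = 3, S = 4` this gives `P = 0.83`.
#'
#' @param Ts total number of sample files.
#' @param R replicates per sample type.
#' @param S number of sample types (used to validate balance).
#' @return P, rounded to two decimals.
#' @export
compute_mask_percentage <- function(Ts, R, S) {
  if (R < 1 || R > Ts) stop_csh("need 1 <= R <= Ts", "value_error")
  if (S < 1) stop_csh("need S >= 1", "value_error")
  if (Ts != R * S)
    warn_csh(sprintf("unbalanced design: Ts (%d) != R * S (%d)", Ts, R * S))
  round((Ts - R + 1) / Ts, 2)
}

#' Mask-rule parameters from a sample sheet
#'
#' @param samples sample sheet (`data.frame`); `species` selects the chip
#'   design the masks are built for.
#' @param species species whose samples define `Ts`, `R`, `S`.
#' @return list with `Ts`, `R`, `S` and the defined percentage `P`.
#' @export
mask_rule_params <- function(samples, species = "target") {
  d <- design_params(samples, species = species)
  d$P <- compute_mask_percentage(d$Ts, d$R, d$S)
  d
}

#' Build an ISV mask at one intensity threshold
#'
#' A probe is masked (for all samples) iff fewer than `R` samples have
#' intensity at/above `threshold`.
#'
#' @param norm normalized linear-scale probe matrix (all `Ts` samples).
#' @param threshold signal-intensity threshold (>= 0).
#' @param params [mask_rule_params()] list (`Ts`, `R`, `S`, `P`).
#' @return a [mask_file()] with `provenance = "ISV"`.
#' @export
build_isv_mask <- function(norm, threshold, params) {
  if (threshold < 0) stop_csh("threshold must be >= 0", "value_error")
  if (ncol(norm) != params$Ts)
    stop_csh(sprintf("matrix has %d samples but params say Ts = %d",
                     ncol(norm), params$Ts), "schema_error")
  n_above <- rowSums(norm >= threshold)
  mask_file(rownames(norm)[n_above < params$R],
            threshold = threshold, P = params$P, provenance = "ISV")
}

#' Build the ISV mask series over a threshold ladder
#'
#' @inheritParams build_isv_mask
#' @param thresholds strictly increasing thresholds
#'   (default [mask_thresholds()]).
#' @return list of [mask_file()]s, one per threshold; masked sets are nested
#'   (non-decreasing in threshold).
#' @export
build_threshold_series <- function(norm, thresholds = mask_thresholds(), params) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_csh("thresholds must be strictly increasing", "value_error")
  masks <- lapply(thresholds, function(t) build_isv_mask(norm, t, params))
  names(masks) <- format(thresholds, trim = TRUE)
  masks
}

#' Build an SFP mask
#'
#' @param sfps character vector of SFP probe ids.
#' @param universe character vector of all probe ids on the chip; SFP ids
#'   not in the universe are dropped with a warning.
#' @return a [mask_file()] with `provenance = "SFP"`.
#' @export
build_sfp_mask <- function(sfps, universe) {
  sfps <- unique(as.character(sfps))
  if (!length(sfps)) warn_csh("empty SFP list: mask masks nothing")
  unknown <- setdiff(sfps, universe)
  if (length(unknown)) {
    warn_csh(sprintf("%d SFP probe id(s) not in the probe universe, dropped",
                     length(unknown)))
    sfps <- intersect(sfps, universe)
  }
  mask_file(sfps, provenance = "SFP")
}

#' Combine two masks (double-masking)
#'
#' Union of the masked sets; threshold/P metadata is inherited from the
#' first (ISV) parent.
#'
#' @param a,b [mask_file()]s over the same probe universe.
#' @return a [mask_file()] with `provenance = "combined"`.
#' @export
combine_masks <- function(a, b) {
  stopifnot(inherits(a, "mask_file"), inherits(b, "mask_file"))
  mask_file(union(a$probes, b$probes),
            threshold = a$threshold, P = a$P, provenance = "combined")
}

#' Apply a mask to a probe matrix
#'
#' @param m probe matrix.
#' @param mask a [mask_file()].
#' @return `m` restricted to retained probes (all samples kept).
#' @export
apply_mask <- function(m, mask) {
  stopifnot(inherits(mask, "mask_file"))
  keep <- !(rownames(m) %in% mask$probes)
  if (!any(keep)) warn_csh("mask removes every probe: empty matrix returned")
  set_scale(m[keep, , drop = FALSE], probe_scale(m))
}
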