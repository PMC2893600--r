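# Tabular formats: tab-separated UTF-8, one header row, '#' comment lines.
# Locus coordinates are 0-based; genome windows are half-open [start, start+W).

#' Construct a probe-level intensity matrix
#'
#' Thin wrapper around a numeric matrix (probes x samples) that validates
#' the probe-matrix invariants and records the intensity scale.
#'
#' @param values numeric matrix, rownames = probe ids, colnames = sample ids.
#' @param scale `"linear"` (raw/normalized intensities, strictly positive)
#'   or `"log2"`.
#' @return the validated matrix with a `scale` attribute.
#' @export
probe_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_csh("probe matrix must be a numeric matrix", "format_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_csh("probe matrix needs probe ids (rownames) and sample ids (colnames)",
             "format_error")
  if (anyDuplicated(rownames(values)))
    stop_csh("duplicate probe ids in probe matrix", "format_error")
  if (anyNA(values))
    stop_csh("probe matrix contains missing values", "value_error")
  if (scale == "linear" && any(values <= 0))
    stop_csh("linear-scale intensities must be strictly positive", "value_error")
  attr(values, "scale") <- scale
  values
}

#' Intensity scale of a probe matrix
#' @param m a probe matrix.
#' @return `"linear"` or `"log2"` (matrices without the attribute are
#'   assumed linear).
#' @export
probe_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) "linear" else s
}

# carry the scale attribute through subsetting/transforms
set_scale <- function(m, scale) {
  attr(m, "scale") <- scale
  m
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `species` (reference|target), `genotype`,
#' `tissue` (ES|PES), `replicate`.
#'
#' @param path path to a tab-separated sample sheet.
#' @return validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples a sample-sheet `data.frame` to validate in place.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "species", "genotype", "tissue", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_csh(paste("sample sheet missing column(s):", paste(miss, collapse = ", ")),
             "schema_error")
  if (anyDuplicated(samples$sample_id))
    stop_csh("duplicate sample_id in sample sheet", "schema_error")
  if (!all(samples$tissue %in% c("ES", "PES")))
    stop_csh("tissue must be 'ES' or 'PES'", "schema_error")
  if (!all(samples$species %in% c("reference", "target")))
    stop_csh("species must be 'reference' or 'target'", "schema_error")
  if (any(samples$replicate < 1))
    stop_csh("replicate must be a positive integer", "schema_error")
  samples
}

#' Design parameters of a (balanced) one-species design
#'
#' `Ts` is the total number of sample files, `S` the number of distinct
#' (genotype, tissue) sample types and `R` the replicate count per sample
#' type, which must be constant within the species.
#'
#' @param samples sample sheet (`data.frame`).
#' @param species restrict to one species (`"target"` or `"reference"`);
#'   required when the sheet holds both.
#' @return `list(Ts =, R =, S =)`.
#' @export
design_params <- function(samples, species = NULL) {
  samples <- validate_sample_sheet(samples)
  if (!is.null(species)) samples <- samples[samples$species == species, , drop = FALSE]
  if (length(unique(samples$species)) > 1L)
    stop_csh("design_params needs a single species; pass `species=`", "schema_error")
  if (nrow(samples) == 0L)
    stop_csh("no samples for the requested species", "schema_error")
  grp <- interaction(samples$genotype, samples$tissue, drop = TRUE)
  sizes <- table(grp)
  if (length(unique(as.integer(sizes))) != 1L)
    stop_csh("unbalanced design: replicate count differs between sample types",
             "schema_error")
  list(Ts = nrow(samples), R = as.integer(sizes[1L]), S = length(sizes))
}

#' Read / write a probe intensity matrix
#'
#' The on-disk format is a TSV with header `probe_id` followed by the
#' sample ids; `#`-prefixed lines are comments. Intensities are linear
#' scale unless `scale = "log2"`.
#'
#' @param path file path.
#' @param samples sample sheet (`data.frame` or path); the matrix columns
#'   must match its `sample_id`s exactly (order from the file is kept).
#' @param scale intensity scale of the stored values.
#' @return [probe_matrix()] for the reader; `path`, invisibly, for the writer.
#' @export
read_probe_matrix <- function(path, samples = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- read_tsv(path)
  if (names(df)[1L] != "probe_id")
    stop_csh("probe matrix file must start with a 'probe_id' column", "format_error")
  if (anyDuplicated(df$probe_id))
    stop_csh("duplicate probe ids in probe matrix file", "format_error")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop_csh("non-numeric intensity values in probe matrix file", "format_error")
  rownames(m) <- df$probe_id
  if (!is.null(samples)) {
    if (is.character(samples) && length(samples) == 1L)
      samples <- read_sample_sheet(samples)
    if (!setequal(colnames(m), samples$sample_id))
      stop_csh("probe matrix columns do not match sample sheet sample_ids",
               "schema_error")
  }
  probe_matrix(m, scale)
}

#' @rdname read_probe_matrix
#' @param m probe matrix to write.
#' @param comments character vector written as leading `# ` comment lines.
#' @export
write_probe_matrix <- function(m, path, comments = NULL) {
  con <- open_out(path)
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(x) paste(sprintf("%.10g", x), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a probe -> probe-set map
#'
#' Columns: `probe_id`, `probeset_id`, `probe_index` (1-based position of
#' the probe within its set). Each probe maps to exactly one probe set.
#'
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
read_probe_map <- function(path) {
  df <- read_tsv(path)
  need <- c("probe_id", "probeset_id", "probe_index")
  if (!all(need %in% names(df)))
    stop_csh("probe map must have columns probe_id, probeset_id, probe_index",
             "schema_error")
  if (anyDuplicated(df$probe_id))
    stop_csh("a probe maps to more than one probe set (duplicate probe_id)",
             "format_error")
  if (any(df$probe_index < 1))
    stop_csh("probe_index must be >= 1", "value_error")
  df
}

#' Read an SFP probe list (one probe id per line, '#' comments allowed)
#' @param path file path.
#' @return character vector of probe ids (duplicates removed).
#' @export
read_sfp_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!startsWith(trimws(x), "#")])
  unique(x[nzchar(x)])
}

#' Read a probe-set locus table
#'
#' Columns: `probeset_id`, `chromosome`, `position_bp` (0-based). Only the
#' first row per probe set is kept (top-hit-only convention); additional
#' rows trigger a warning.
#'
#' @param path TSV path.
#' @return `data.frame` with one locus per probe set.
#' @export
read_locus_table <- function(path) {
  df <- read_tsv(path)
  need <- c("probeset_id", "chromosome", "position_bp")
  if (!all(need %in% names(df)))
    stop_csh("locus table must have columns probeset_id, chromosome, position_bp",
             "schema_error")
  if (any(df$position_bp < 0))
    stop_csh("position_bp must be >= 0", "value_error")
  dup <- duplicated(df$probeset_id)
  if (any(dup)) {
    warn_csh(sprintf("locus table: %d extra loci dropped (first row per probe set wins)",
                     sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Read a genome table (columns `chromosome`, `length_bp`)
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
read_genome <- function(path) {
  df <- read_tsv(path)
  if (!all(c("chromosome", "length_bp") %in% names(df)))
    stop_csh("genome table must have columns chromosome, length_bp", "schema_error")
  validate_genome(df)
}

validate_genome <- function(genome) {
  if (any(genome$length_bp <= 0))
    stop_csh("chromosome lengths must be > 0", "value_error")
  if (anyDuplicated(genome$chromosome))
    stop_csh("duplicate chromosome names in genome table", "format_error")
  genome
}

#' Mask files
#'
#' A mask file is a set of probe ids to drop, plus the threshold, defined
#' percentage `P` and provenance (`ISV`, `SFP` or `combined`) that produced
#' it. On disk: `# threshold=`, `# P=`, `# provenance=` header lines, then
#' one masked probe id per line, lexicographically sorted.
#'
#' @param probes character vector of masked probe ids.
#' @param threshold signal-intensity threshold that produced the mask
#'   (`NA` for SFP masks).
#' @param P defined masking percentage (`NA` for SFP masks).
#' @param provenance `"ISV"`, `"SFP"` or `"combined"`.
#' @return an object of class `mask_file`.
#' @export
mask_file <- function(probes, threshold = NA_real_, P = NA_real_,
                      provenance = c("ISV", "SFP", "combined")) {
  provenance <- match.arg(provenance)
  structure(
    list(probes = sort(unique(as.character(probes))),
         threshold = as.numeric(threshold), P = as.numeric(P),
         provenance = provenance),
    class = "mask_file"
  )
}

#' @export
print.mask_file <- function(x, ...) {
  cat(sprintf("<mask_file> %s: %d probes masked (threshold=%s, P=%s)\n",
              x$provenance, length(x$probes),
              format(x$threshold), format(x$P)))
  invisible(x)
}

#' @rdname mask_file
#' @param mask a `mask_file`.
#' @param path file path.
#' @export
write_mask_file <- function(mask, path) {
  stopifnot(inherits(mask, "mask_file"))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(c(sprintf("# threshold=%s", format(mask$threshold)),
               sprintf("# P=%s", format(mask$P)),
               sprintf("# provenance=%s", mask$provenance)), con)
  if (length(mask$probes)) writeLines(mask$probes, con)
  invisible(path)
}

#' @rdname mask_file
#' @export
read_mask_file <- function(path) {
  x <- readLines(path)
  hdr <- x[startsWith(x, "#")]
  body <- trimws(x[!startsWith(x, "#")])
  get <- function(key) {
    ln <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(sprintf("^#\\s*%s=", key), "", ln[1L])
  }
  prov <- get("provenance")
  if (is.na(prov)) stop_csh("mask file lacks a '# provenance=' header", "format_error")
  mask_file(body[nzchar(body)],
            threshold = suppressWarnings(as.numeric(get("threshold"))),
            P = suppressWarnings(as.numeric(get("P"))),
            provenance = prov)
}

# ---- shared low-level helpers ----

read_tsv <- function(path) {
  if (!file.exists(path)) stop_csh(paste("file not found:", path), "io_error")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

open_out <- function(path) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_csh(paste("cannot write:", path), "io_error"),
                  warning = function(w) stop_csh(paste("cannot write:", path), "io_error"))
  con
}
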