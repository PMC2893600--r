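# Synthetic two-species probe-level generator with known truth.
#
# Observation model (per probe p of gene g, sample s):
#   linear intensity = 2^( b_g + a_p + tissue_{g,t(s)} + geno_{g,geno(s)}
#                          - d_isv * [p in ISV, target]
#                          - d_sfp * [p in SFP, affected genotype]
#                          + eps_{p,s} ) + bg_{p,s}
# with eps ~ N(0, noise_sd^2) and bg a probe-specific lognormal
# nonspecific-hybridization (cross-hybridization) level with a
# condition-specific component and per-sample jitter:
#   bg_{p,s} = bg_p * exp(c_{p,cond(s)}) * exp(jitter_{p,s})
# where cond(s) is the (genotype, tissue) sample type. The additive,
# probe-specific background is what makes ISV attenuation bias results: a
# global background correction can only remove the distribution-level
# background, so probes attenuated into the nonspecific range keep a
# probe-specific residual. The condition component models sequence-driven
# cross-hybridization to whatever transcript pool is present, which is
# reproducible across replicates — so a probe reading mostly background
# shows spurious, replicable tissue or genotype "ratios" (false positives)
# while its true signal is compressed (false negatives). Both biases are
# what intensity-threshold masking removes. The reference species shares
# tissue effects (correlation rho) but draws its own probe affinities and
# background levels and carries no ISV/SFP attenuation or genotype effects.

#' Simulation configuration
#'
#' Defaults emulate a 2-genotype x 2-tissue x 3-replicate target design on
#' an 11-probe-per-set chip, with a correlated reference species.
#' ISV and SFP probes are planted gene-clustered: sequence divergence hits
#' most probes of an affected transcript, and the robust median-polish
#' summary is insensitive to a single aberrant probe.
#'
#' @param n_probesets number of probe sets (genes).
#' @param probes_per_set perfect-match probes per set.
#' @param replicates replicates per (genotype, tissue) sample type.
#' @param baseline_log2_mean,baseline_log2_sd gene baseline log2 abundance.
#' @param probe_affinity_sd per-probe affinity SD (log2), drawn
#'   independently per species.
#' @param probe_slope_sd SD of the per-probe response gain: probe `p`
#'   responds to a differential log2 signal `d` with `s_p * d`,
#'   `s_p ~ N(1, probe_slope_sd^2)` drawn independently per species.
#'   Response heterogeneity is why summaries built from few retained
#'   probes lose ratio accuracy.
#' @param tissue_effect_fraction fraction of genes with a tissue (PES vs
#'   ES) effect of magnitude >= 1 log2.
#' @param tissue_effect_sd SD of the (truncated) tissue-effect draw.
#' @param regulated_dim_tilt exponential tilt applied when choosing which
#'   genes carry tissue or genotype effects: selection weight
#'   `exp(-tilt * standardized baseline)`, so regulated genes sit lower in
#'   the intensity distribution than constitutive genes (0 = uniform).
#' @param cross_species_ratio_corr correlation of the two species' tissue
#'   effects (bivariate-normal construction).
#' @param genotype_de_fraction fraction of genes differentially expressed
#'   between the target genotypes.
#' @param genotype_de_range range of |log2 effect| for DE genes (uniform).
#' @param isv_probe_fraction overall fraction of target probes in ISV
#'   regions.
#' @param isv_within_gene_rate per-probe ISV probability within an
#'   ISV-affected gene (the affected-gene fraction is
#'   `isv_probe_fraction / isv_within_gene_rate`).
#' @param isv_attenuation log2 attenuation of ISV probes (target species).
#' @param isv_floor_log2 if non-`NULL`, ISV probes are instead modelled as
#'   fully non-hybridizing: they carry no transcript signal and read pure
#'   cross-hybridization at a per-probe level `2^Unif(isv_floor_log2 - 3,
#'   isv_floor_log2 - 1)` (modulated by the condition and sample factors) —
#'   an attenuation placed essentially below the intensity
#'   `2^isv_floor_log2`. Because the condition component is replicable,
#'   such probes show spurious tissue/genotype ratios until masked. Used
#'   to study threshold recovery when the biased-probe intensity ceiling
#'   is known.
#' @param sfp_probe_count total number of SFP probes planted.
#' @param sfp_probes_per_gene SFP probes per affected gene.
#' @param sfp_attenuation log2 attenuation of SFP probes in the affected
#'   genotype.
#' @param noise_sd replicate noise SD (log2; lognormal on the linear scale).
#' @param background_median per-probe nonspecific-hybridization level,
#'   median in linear units (lognormal across probes).
#' @param background_probe_sdlog lognormal sdlog of the per-probe
#'   background level.
#' @param background_cond_gene_sdlog sdlog of the per-gene,
#'   per-(genotype, tissue) cross-hybridization component, shared by all
#'   probes of a gene and by replicates of a condition (a diverged
#'   transcript cross-hybridizes to some other, condition-dependent
#'   transcript as a unit).
#' @param background_cond_probe_sdlog sdlog of the per-probe,
#'   per-(genotype, tissue) cross-hybridization component (shared by
#'   replicates of a condition).
#' @param background_sample_sdlog lognormal sdlog of the per-sample
#'   background jitter.
#' @param n_chromosomes,chromosome_length_bp genome used for the locus
#'   table (gene density comparable to a sequenced legume genome at this
#'   gene count).
#' @param seed RNG seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_probesets = 2000L, probes_per_set = 11L,
                       replicates = 3L,
                       baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                       probe_affinity_sd = 0.8, probe_slope_sd = 0.4,
                       tissue_effect_fraction = 0.15, tissue_effect_sd = 1.5,
                       regulated_dim_tilt = 0.7,
                       cross_species_ratio_corr = 0.9,
                       genotype_de_fraction = 0.05,
                       genotype_de_range = c(1, 3),
                       isv_probe_fraction = 0.25, isv_within_gene_rate = 0.7,
                       isv_attenuation = 3, isv_floor_log2 = NULL,
                       sfp_probe_count = 200L, sfp_probes_per_gene = 6L,
                       sfp_attenuation = 2.5,
                       noise_sd = 0.3,
                       background_median = 10, background_probe_sdlog = 0.45,
                       background_cond_gene_sdlog = 0.45,
                       background_cond_probe_sdlog = 0.4,
                       background_sample_sdlog = 0.15,
                       n_chromosomes = 8L, chromosome_length_bp = 1.3e6,
                       seed) {
  if (missing(seed)) stop_csh("sim_config: seed is mandatory", "value_error")
  cfg <- as.list(environment())
  fracs <- c(tissue_effect_fraction, genotype_de_fraction,
             isv_probe_fraction, isv_within_gene_rate)
  if (any(fracs < 0 | fracs > 1))
    stop_csh("fractions must be in [0, 1]", "value_error")
  if (sfp_probes_per_gene > probes_per_set)
    stop_csh("sfp_probes_per_gene cannot exceed probes_per_set", "value_error")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic two-species probe-level dataset
#'
#' @param config a [sim_config()].
#' @return list (class `csh_sim`) with elements `target` and `reference`
#'   (linear-scale probe matrices), `map` (probe map), `samples` (combined
#'   sample sheet), `sfp` (planted SFP probe ids), `loci` (locus table),
#'   `genome`, `truth` (planted effects: `de`, `tissue`, `isv_probes`,
#'   `isv_genes`, `sfp_genes`, `target_expression` — the noise-free log2
#'   probe-set expression of the target samples) and `config`.
#' @export
simulate_csh <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  G <- cfg$n_probesets
  K <- cfg$probes_per_set
  R <- cfg$replicates

  genes <- sprintf("ps%05d_at", seq_len(G))
  map <- data.frame(
    probe_id = sprintf("%s:p%02d", rep(genes, each = K), rep(seq_len(K), G)),
    probeset_id = rep(genes, each = K),
    probe_index = rep(seq_len(K), G)
  )

  # sample sheets: target 2 genotypes x 2 tissues x R; reference 2 tissues x R
  tgt <- expand.grid(replicate = seq_len(R), tissue = c("ES", "PES"),
                     genotype = c("gA", "gB"), stringsAsFactors = FALSE)
  ref <- expand.grid(replicate = seq_len(R), tissue = c("ES", "PES"),
                     genotype = "ref", stringsAsFactors = FALSE)
  tgt$species <- "target"; ref$species <- "reference"
  samples <- rbind(tgt, ref)
  samples$sample_id <- with(samples, sprintf("%s_%s_%s_r%d",
                                             ifelse(species == "target", "tgt", "ref"),
                                             genotype, tissue, replicate))
  samples <- validate_sample_sheet(
    samples[, c("sample_id", "species", "genotype", "tissue", "replicate")])

  # gene-level effects
  baseline <- rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  # regulated genes tilted toward the dim end of the baseline distribution
  reg_weight <- exp(-cfg$regulated_dim_tilt *
                      (baseline - cfg$baseline_log2_mean) / cfg$baseline_log2_sd)
  tissue_ref <- tissue_tgt <- numeric(G)
  n_tis <- round(cfg$tissue_effect_fraction * G)
  if (n_tis > 0) {
    idx <- sample.int(G, n_tis, prob = reg_weight)
    eff <- bvn_truncated(n_tis, cfg$tissue_effect_sd,
                         cfg$cross_species_ratio_corr, min_abs = 1)
    tissue_ref[idx] <- eff[, 1L]
    tissue_tgt[idx] <- eff[, 2L]
  }
  geno_eff <- numeric(G) # effect of genotype gB relative to gA (target only)
  n_de <- round(cfg$genotype_de_fraction * G)
  de_idx <- integer(0)
  if (n_de > 0) {
    de_idx <- sample.int(G, n_de, prob = reg_weight)
    geno_eff[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      runif(n_de, cfg$genotype_de_range[1L], cfg$genotype_de_range[2L])
  }

  # ISV probes: gene-clustered
  isv_gene_frac <- min(1, cfg$isv_probe_fraction / cfg$isv_within_gene_rate)
  isv_genes <- sort(sample.int(G, round(isv_gene_frac * G)))
  isv_flag <- logical(nrow(map))
  in_isv_gene <- map$probeset_id %in% genes[isv_genes]
  isv_flag[in_isv_gene] <- runif(sum(in_isv_gene)) < cfg$isv_within_gene_rate

  # SFP probes: sfp_probes_per_gene probes in each affected gene, one
  # affected genotype per gene
  n_sfp_genes <- ceiling(cfg$sfp_probe_count / cfg$sfp_probes_per_gene)
  n_sfp_genes <- min(n_sfp_genes, G)
  sfp_gene_idx <- sort(sample.int(G, n_sfp_genes))
  sfp_flag <- logical(nrow(map))
  sfp_geno_by_gene <- sample(c("gA", "gB"), n_sfp_genes, replace = TRUE)
  remaining <- cfg$sfp_probe_count
  for (i in seq_along(sfp_gene_idx)) {
    take <- min(cfg$sfp_probes_per_gene, remaining)
    if (take <= 0) break
    rows <- which(map$probeset_id == genes[sfp_gene_idx[i]])
    sfp_flag[sample(rows, take)] <- TRUE
    remaining <- remaining - take
  }
  sfp_affected_geno <- setNames(sfp_geno_by_gene, genes[sfp_gene_idx])

  # probe affinities, one independent draw per species
  aff_tgt <- rnorm(nrow(map), 0, cfg$probe_affinity_sd)
  aff_ref <- rnorm(nrow(map), 0, cfg$probe_affinity_sd)
  slope_tgt <- rnorm(nrow(map), 1, cfg$probe_slope_sd)
  slope_ref <- rnorm(nrow(map), 1, cfg$probe_slope_sd)
  # fixed per-probe floor level for the non-hybridizing ISV mode
  isv_floor_level <- if (!is.null(cfg$isv_floor_log2))
    runif(nrow(map), cfg$isv_floor_log2 - 3, cfg$isv_floor_log2 - 1)

  gene_row <- match(map$probeset_id, genes)
  # probe-specific nonspecific-hybridization level, one draw per species
  bg_tgt <- cfg$background_median *
    exp(rnorm(nrow(map), 0, cfg$background_probe_sdlog))
  bg_ref <- cfg$background_median *
    exp(rnorm(nrow(map), 0, cfg$background_probe_sdlog))
  build <- function(sheet, species) {
    n <- nrow(sheet)
    m <- matrix(0, nrow(map), n,
                dimnames = list(map$probe_id, sheet$sample_id))
    # replicable cross-hybridization: gene- plus probe-level factor per
    # sample type
    cond <- paste(sheet$genotype, sheet$tissue)
    nc <- length(unique(cond))
    gene_fac <- matrix(rnorm(G * nc, 0, cfg$background_cond_gene_sdlog), G)
    cond_fac <- gene_fac[gene_row, , drop = FALSE] +
      matrix(rnorm(nrow(map) * nc, 0, cfg$background_cond_probe_sdlog),
             nrow(map))
    colnames(cond_fac) <- unique(cond)
    for (s in seq_len(n)) {
      tis <- sheet$tissue[s]
      gen <- sheet$genotype[s]
      slope <- if (species == "target") slope_tgt else slope_ref
      diff_sig <- (if (tis == "PES") {
        if (species == "target") tissue_tgt[gene_row] else tissue_ref[gene_row]
      } else 0) +
        (if (species == "target" && gen == "gB") geno_eff[gene_row] else 0)
      lg <- baseline[gene_row] +
        (if (species == "target") aff_tgt else aff_ref) +
        slope * diff_sig
      dead <- rep(FALSE, nrow(map)) # probes with no specific signal at all
      if (species == "target") {
        if (is.null(cfg$isv_floor_log2)) {
          lg <- lg - cfg$isv_attenuation * isv_flag
        } else {
          dead <- isv_flag
        }
        hit <- sfp_flag & (sfp_affected_geno[map$probeset_id] == gen)
        hit[is.na(hit)] <- FALSE
        lg <- lg - cfg$sfp_attenuation * hit
      }
      lg <- lg + rnorm(nrow(map), 0, cfg$noise_sd)
      bg0 <- if (species == "target") bg_tgt else bg_ref
      if (any(dead)) bg0[dead] <- 2^isv_floor_level[dead]
      bg <- bg0 * exp(cond_fac[, cond[s]]) *
        exp(rnorm(nrow(map), 0, cfg$background_sample_sdlog))
      sig <- 2^lg
      sig[dead] <- 0
      m[, s] <- sig + bg
    }
    probe_matrix(m, "linear")
  }
  target <- build(samples[samples$species == "target", ], "target")
  reference <- build(samples[samples$species == "reference", ], "reference")

  # loci: uniform over the genome, chromosome chosen proportional to length
  genome <- data.frame(chromosome = sprintf("chr%d", seq_len(cfg$n_chromosomes)),
                       length_bp = rep(cfg$chromosome_length_bp, cfg$n_chromosomes))
  chr_i <- sample.int(cfg$n_chromosomes, G, replace = TRUE,
                      prob = genome$length_bp)
  loci <- data.frame(probeset_id = genes,
                     chromosome = genome$chromosome[chr_i],
                     position_bp = floor(runif(G) * genome$length_bp[chr_i]))

  # noise-free log2 probe-set expression of the target samples
  tgt_sheet <- samples[samples$species == "target", ]
  true_expr <- matrix(0, G, nrow(tgt_sheet),
                      dimnames = list(genes, tgt_sheet$sample_id))
  for (s in seq_len(nrow(tgt_sheet))) {
    true_expr[, s] <- baseline +
      (if (tgt_sheet$tissue[s] == "PES") tissue_tgt else 0) +
      (if (tgt_sheet$genotype[s] == "gB") geno_eff else 0)
  }

  truth <- list(
    de = data.frame(probeset_id = genes[de_idx], effect = geno_eff[de_idx]),
    tissue = data.frame(probeset_id = genes, ref = tissue_ref,
                        target = tissue_tgt),
    isv_probes = map$probe_id[isv_flag],
    isv_genes = genes[isv_genes],
    sfp_genes = data.frame(probeset_id = genes[sfp_gene_idx],
                           genotype = sfp_geno_by_gene),
    target_expression = true_expr
  )
  structure(list(target = target, reference = reference, map = map,
                 samples = samples, sfp = map$probe_id[sfp_flag],
                 loci = loci, genome = genome, truth = truth,
                 config = cfg),
            class = "csh_sim")
}

# bivariate normal (sd, correlation rho) rejection-sampled so both margins
# have |x| >= min_abs
bvn_truncated <- function(n, sd, rho, min_abs = 1) {
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(16L, 4L * (n - nrow(out)))
    z1 <- rnorm(m); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
    cand <- cbind(z1, z2) * sd
    ok <- abs(cand[, 1L]) >= min_abs & abs(cand[, 2L]) >= min_abs
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Reposition genes into a planted cluster
#'
#' Places the listed genes uniformly within `[start_bp, start_bp + span_bp)`
#' on one chromosome, so that (when the span lies inside one genome bin)
#' they occupy a single window. Uses the current RNG state.
#'
#' @param loci locus table.
#' @param gene_ids probe-set ids to reposition (must be present).
#' @param chromosome target chromosome.
#' @param start_bp,span_bp cluster start and span (bp).
#' @return the modified locus table.
#' @export
plant_cluster <- function(loci, gene_ids, chromosome, start_bp, span_bp) {
  if (!length(gene_ids)) return(loci)
  idx <- match(gene_ids, loci$probeset_id)
  if (anyNA(idx))
    stop_csh("plant_cluster: gene id(s) absent from the locus table", "value_error")
  loci$chromosome[idx] <- chromosome
  loci$position_bp[idx] <- start_bp + floor(runif(length(idx)) * span_bp)
  loci
}

#' @export
print.csh_sim <- function(x, ...) {
  cat(sprintf(paste0("<csh_sim> %d probe sets x %d probes, %d target + %d ",
                     "reference samples\n  planted: %d DE genes, %d ISV probes, %d SFP probes\n"),
              x$config$n_probesets, x$config$probes_per_set,
              sum(x$samples$species == "target"),
              sum(x$samples$species == "reference"),
              nrow(x$truth$de), length(x$truth$isv_probes), length(x$sfp)))
  invisible(x)
}
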