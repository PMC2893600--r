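# Genome-window profiling and the Monte-Carlo bin-occupancy clustering
# test: partition the genome into non-overlapping windows, count how many
# bins hold exactly k selected genes, and compare with the distribution of
# that count when the same number of genes is placed at random. |z| >= 2
# flags non-random clustering.

#' Gene frequency in sliding windows
#'
#' Counts loci per half-open window `[start, start + window_bp)` with the
#' window start advancing by `step_bp` along each chromosome (starts at 0).
#'
#' @param loci locus table (`probeset_id`, `chromosome`, `position_bp`;
#'   0-based), see [read_locus_table()].
#' @param genome genome table (`chromosome`, `length_bp`).
#' @param window_bp,step_bp window size and step (defaults 50 kb / 10 kb).
#' @return `data.frame` with `chromosome`, `start`, `end`, `count`.
#' @export
sliding_window_frequency <- function(loci, genome, window_bp = 50000,
                                     step_bp = 10000) {
  validate_genome(genome)
  check_loci(loci, genome)
  if (window_bp < step_bp)
    warn_csh("window smaller than step: genome positions between windows are never counted")
  out <- lapply(seq_len(nrow(genome)), function(i) {
    chr <- genome$chromosome[i]
    len <- genome$length_bp[i]
    starts <- seq(0, len - 1, by = step_bp)
    pos <- sort(loci$position_bp[loci$chromosome == chr])
    # loci with start <= pos < start + window  (positions are integers)
    count <- findInterval(starts + window_bp - 0.5, pos) -
      findInterval(starts - 0.5, pos)
    data.frame(chromosome = chr, start = starts,
               end = pmin(starts + window_bp, len), count = count)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Partition a genome into non-overlapping bins
#'
#' Per chromosome: bins `[i*W, (i+1)*W)` with the last bin truncated at the
#' chromosome end, giving `ceil(length / W)` bins per chromosome.
#'
#' @param genome genome table.
#' @param window_bp bin width in bp.
#' @return `data.frame` with `chromosome`, `start`, `end`, `bin_id`
#'   (1..B, global).
#' @export
partition_bins <- function(genome, window_bp) {
  validate_genome(genome)
  if (window_bp <= 0) stop_csh("window_bp must be > 0", "value_error")
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    nb <- ceiling(len / window_bp)
    starts <- (seq_len(nb) - 1) * window_bp
    data.frame(chromosome = genome$chromosome[i], start = starts,
               end = pmin(starts + window_bp, len))
  })
  out <- do.call(rbind, out)
  out$bin_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Observed bin-occupancy histogram
#'
#' Maps each locus to its bin and returns, for every k >= 1, the number of
#' bins holding exactly k loci (empty bins are excluded).
#'
#' @param loci locus table.
#' @param bins a [partition_bins()] `data.frame`.
#' @return named integer vector; names are the occupancy counts k.
#' @export
observed_occupancy <- function(loci, bins) {
  window_bp <- max(bins$end - bins$start)
  genome <- bin_genome(bins)
  check_loci(loci, genome, error = TRUE)
  ids <- locus_bin_ids(loci$chromosome, loci$position_bp, genome, window_bp)
  occupancy_hist(ids, nbins = nrow(bins))
}

#' Monte-Carlo null distribution of bin occupancy
#'
#' Repeatedly places `n_genes` genes at random on the genome
#' (`uniform_genome`: iid uniform positions over the concatenated
#' chromosomes; `permute_loci`: sampled without replacement from
#' `locus_universe`), bins them with [partition_bins()] windows, and
#' records the per-repetition occupancy histogram. Returns the
#' across-repetition mean and SD (sample SD, n-1 denominator) of the
#' number of bins with exactly k genes, for k = 1..max observed.
#'
#' @param n_genes number of genes placed per repetition.
#' @param genome genome table.
#' @param window_bp bin width in bp.
#' @param reps number of repetitions (default 2000).
#' @param null null model, `"uniform_genome"` (default) or `"permute_loci"`.
#' @param locus_universe locus table to resample under `"permute_loci"`.
#' @param seed RNG seed (required: the result is deterministic given it).
#' @return `data.frame` with `k`, `sim_mean`, `sim_sd`.
#' @export
clustering_simulation <- function(n_genes, genome, window_bp, reps = 2000,
                                  null = c("uniform_genome", "permute_loci"),
                                  locus_universe = NULL, seed) {
  null <- match.arg(null)
  validate_genome(genome)
  if (n_genes < 1) stop_csh("n_genes must be >= 1", "value_error")
  if (reps < 2) stop_csh("reps must be >= 2", "value_error")
  if (missing(seed)) stop_csh("clustering_simulation needs a seed", "value_error")
  set.seed(seed)

  nb_per_chr <- ceiling(genome$length_bp / window_bp)
  nbins <- sum(nb_per_chr)
  cum_len <- cumsum(as.numeric(genome$length_bp))
  bin_offset <- c(0, cumsum(nb_per_chr))[seq_len(nrow(genome))]

  if (null == "permute_loci") {
    if (is.null(locus_universe) || nrow(locus_universe) < n_genes)
      stop_csh("permute_loci needs a locus_universe with >= n_genes rows",
               "value_error")
    check_loci(locus_universe, genome, error = TRUE)
    universe_ids <- locus_bin_ids(locus_universe$chromosome,
                                  locus_universe$position_bp,
                                  genome, window_bp)
  }

  K <- 1L
  sums <- sumsq <- numeric(1L)
  for (rep_i in seq_len(reps)) {
    if (null == "uniform_genome") {
      u <- runif(n_genes) * cum_len[length(cum_len)]
      chr_i <- findInterval(u, cum_len) + 1L
      within <- floor(u - c(0, cum_len)[chr_i])
      ids <- bin_offset[chr_i] + floor(within / window_bp) + 1L
    } else {
      ids <- universe_ids[sample.int(length(universe_ids), n_genes)]
    }
    h <- occupancy_hist(ids, nbins)
    kmax <- length(h)
    if (kmax > K) { # extend; earlier repetitions implicitly contributed 0
      sums <- c(sums, numeric(kmax - K))
      sumsq <- c(sumsq, numeric(kmax - K))
      K <- kmax
    }
    idx <- seq_len(kmax)
    sums[idx] <- sums[idx] + h
    sumsq[idx] <- sumsq[idx] + h^2
  }
  mu <- sums / reps
  vr <- pmax(0, (sumsq - reps * mu^2) / (reps - 1))
  data.frame(k = seq_len(K), sim_mean = mu, sim_sd = sqrt(vr))
}

#' Clustering z-scores against the simulated null
#'
#' For each occupancy level k: `z = (observed - sim_mean) / sim_sd`,
#' reported rounded to 1 decimal; `significant` iff `|z| >= 2` (on the
#' unrounded value). When the simulation never produced level k (or
#' `sim_sd = 0` with `observed != sim_mean`), z is undefined and the row is
#' flagged (`z = NA`), never infinite.
#'
#' @param observed named vector from [observed_occupancy()] (names = k).
#' @param sim `data.frame` from [clustering_simulation()].
#' @return `data.frame` with `k`, `sim_mean`, `sim_sd`, `observed`, `z`
#'   (1 decimal), `significant`.
#' @export
z_scores <- function(observed, sim) {
  obs_k <- as.integer(names(observed))
  ks <- sort(union(obs_k, sim$k))
  obs <- setNames(rep(0, length(ks)), ks)
  obs[as.character(obs_k)] <- observed
  mu <- sim$sim_mean[match(ks, sim$k)]
  sdv <- sim$sim_sd[match(ks, sim$k)]
  z <- (obs - mu) / sdv
  z[is.na(mu)] <- NA_real_                 # k never seen in the simulation
  undef_sd <- !is.na(sdv) & sdv == 0 & obs != mu
  z[undef_sd] <- NA_real_
  z[!is.na(sdv) & sdv == 0 & obs == mu] <- 0
  data.frame(k = ks,
             sim_mean = ifelse(is.na(mu), NA_real_, mu),
             sim_sd = sdv,
             observed = as.numeric(obs),
             z = round(z, 1),
             significant = ifelse(is.na(z), NA, abs(z) >= 2),
             row.names = NULL)
}

# ---- internal helpers ----

# reconstruct the genome table from a partition_bins() result
bin_genome <- function(bins) {
  agg <- tapply(bins$end, bins$chromosome, max)
  data.frame(chromosome = names(agg), length_bp = as.numeric(agg))
}

check_loci <- function(loci, genome, error = TRUE) {
  bad_chr <- setdiff(loci$chromosome, genome$chromosome)
  if (length(bad_chr))
    stop_csh(paste("loci on unknown chromosome(s):", paste(bad_chr, collapse = ", ")),
             "value_error")
  len <- genome$length_bp[match(loci$chromosome, genome$chromosome)]
  if (any(loci$position_bp >= len | loci$position_bp < 0))
    stop_csh("locus position beyond chromosome length", "value_error")
  invisible(TRUE)
}

locus_bin_ids <- function(chrom, pos, genome, window_bp) {
  nb_per_chr <- ceiling(genome$length_bp / window_bp)
  bin_offset <- c(0, cumsum(nb_per_chr))[match(chrom, genome$chromosome)]
  as.integer(bin_offset + floor(pos / window_bp) + 1L)
}

occupancy_hist <- function(bin_ids, nbins) {
  occ <- tabulate(bin_ids, nbins)
  h <- tabulate(occ[occ > 0L])
  setNames(h, seq_along(h))
}
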