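tiny_genome <- function(lens = c(chr1 = 2e5, chr2 = 1.01e5)) {
  data.frame(chromosome = names(lens), length_bp = unname(lens))
}

test_that("sliding windows count loci with half-open interval arithmetic", {
  genome <- tiny_genome(c(chr1 = 2e5))
  loci <- data.frame(probeset_id = "g1", chromosome = "chr1",
                     position_bp = 55000)
  prof <- sliding_window_frequency(loci, genome, 50000, 10000)
  hit <- prof$start[prof$count == 1]
  expect_equal(hit, seq(10000, 50000, by = 10000))
  expect_true(all(prof$count[!prof$start %in% hit] == 0))

  # no loci: all-zero profile
  none <- sliding_window_frequency(loci[0, ], genome, 50000, 10000)
  expect_true(all(none$count == 0))
  # window < step warns
  expect_warning(sliding_window_frequency(loci, genome, 5000, 10000),
                 "never counted")
})

test_that("window profile sums equal (window/step) x N away from chromosome ends", {
  set.seed(61)
  genome <- tiny_genome(c(chr1 = 1e6))
  # keep loci away from both ends by a full window
  loci <- data.frame(probeset_id = sprintf("g%d", 1:40), chromosome = "chr1",
                     position_bp = sample(60000:940000, 40))
  prof <- sliding_window_frequency(loci, genome, 50000, 10000)
  expect_equal(sum(prof$count), (50000 / 10000) * 40)
  # brute-force recount of every window
  brute <- vapply(seq_len(nrow(prof)), function(i) {
    sum(loci$position_bp >= prof$start[i] &
          loci$position_bp < prof$start[i] + 50000)
  }, numeric(1))
  expect_equal(prof$count, brute)
})

test_that("bin partition follows the ceiling rule with a truncated last bin", {
  bins <- partition_bins(tiny_genome(c(a = 1e5, b = 1.01e5)), 5e4)
  expect_equal(sum(bins$chromosome == "a"), 2L)
  expect_equal(sum(bins$chromosome == "b"), 3L)
  last_b <- bins[bins$chromosome == "b", ][3, ]
  expect_equal(last_b$end - last_b$start, 1000)
  expect_identical(bins$bin_id, seq_len(5L))

  # random genomes vs brute force
  set.seed(10)
  for (i in 1:5) {
    lens <- sample(1e5:1e6, 4)
    names(lens) <- paste0("c", 1:4)
    got <- nrow(partition_bins(tiny_genome(lens), 37000))
    expect_equal(got, sum(ceiling(lens / 37000)))
  }
})

test_that("observed occupancy histograms match brute-force binning", {
  genome <- tiny_genome(c(chr1 = 5e5, chr2 = 5e5))
  bins <- partition_bins(genome, 5e4)
  # N loci in N distinct bins
  loci <- data.frame(probeset_id = sprintf("g%d", 1:6),
                     chromosome = c(rep("chr1", 3), rep("chr2", 3)),
                     position_bp = c(0, 60000, 120000, 5000, 70000, 130000))
  expect_equal(observed_occupancy(loci, bins), c(`1` = 6L))
  # 3 loci in one bin
  trip <- data.frame(probeset_id = paste0("t", 1:3), chromosome = "chr1",
                     position_bp = c(1, 2, 49999))
  expect_equal(observed_occupancy(trip, bins), c(`1` = 0L, `2` = 0L, `3` = 1L))
  # random placement vs brute force
  set.seed(33)
  rnd <- data.frame(probeset_id = sprintf("r%d", 1:80),
                    chromosome = sample(c("chr1", "chr2"), 80, TRUE),
                    position_bp = sample(0:499999, 80))
  got <- observed_occupancy(rnd, bins)
  key <- paste(rnd$chromosome, rnd$position_bp %/% 5e4)
  brute <- table(table(key))
  expect_equal(got[got > 0], setNames(as.integer(brute), names(brute)))
  # locus beyond chromosome end
  bad <- data.frame(probeset_id = "x", chromosome = "chr1", position_bp = 5e5)
  expect_error(observed_occupancy(bad, bins), class = "cshmask_value_error")
})

test_that("occupancy simulation is deterministic and matches the closed form on equal bins", {
  genome <- tiny_genome(c(chr1 = 1e6)) # exactly 20 equal bins at 50 kb
  B <- 20; N <- 15
  sim1 <- clustering_simulation(N, genome, 5e4, reps = 2000, seed = 99)
  sim2 <- clustering_simulation(N, genome, 5e4, reps = 2000, seed = 99)
  expect_identical(sim1, sim2)
  # E[#bins with exactly k] = B * C(N,k) p^k (1-p)^(N-k), p = 1/B
  for (k in 1:3) {
    expected <- B * choose(N, k) * (1 / B)^k * (1 - 1 / B)^(N - k)
    row <- sim1[sim1$k == k, ]
    mc_se <- row$sim_sd / sqrt(2000)
    expect_lt(abs(row$sim_mean - expected), 3 * mc_se + 1e-9)
  }
  # genes conserved in every repetition, hence exactly in the mean
  expect_equal(sum(sim1$k * sim1$sim_mean), N, tolerance = 1e-9)

  # single gene: always exactly one singleton bin
  s1 <- clustering_simulation(1, genome, 5e4, reps = 10, seed = 1)
  expect_equal(s1$sim_mean, 1)
  expect_equal(s1$sim_sd, 0)
  expect_error(clustering_simulation(5, genome, 5e4, reps = 1, seed = 1),
               class = "cshmask_value_error")
})

test_that("permute_loci null resamples the locus universe without replacement", {
  genome <- tiny_genome(c(chr1 = 5e5))
  uni <- data.frame(probeset_id = sprintf("u%d", 1:30), chromosome = "chr1",
                    position_bp = seq(0, 499000, length.out = 30))
  sim <- clustering_simulation(10, genome, 5e4, reps = 100,
                               null = "permute_loci", locus_universe = uni,
                               seed = 3)
  expect_equal(sum(sim$k * sim$sim_mean), 10, tolerance = 0.5)
  expect_error(clustering_simulation(40, genome, 5e4, reps = 100,
                                     null = "permute_loci",
                                     locus_universe = uni, seed = 3),
               class = "cshmask_value_error")
})

test_that("under the uniform null, spurious significance is rare", {
  genome <- data.frame(chromosome = sprintf("chr%d", 1:8),
                       length_bp = rep(25e6, 8))
  bins <- partition_bins(genome, 5e4)
  n_sig <- 0L
  for (s in 1:20) {
    set.seed(s + 500)
    N <- 300
    loci <- data.frame(probeset_id = sprintf("g%03d", seq_len(N)),
                       chromosome = sample(genome$chromosome, N, TRUE),
                       position_bp = floor(runif(N) * 25e6))
    obs <- observed_occupancy(loci, bins)
    sim <- clustering_simulation(N, genome, 5e4, reps = 400, seed = s + 900)
    z <- z_scores(obs, sim)
    if (any(!is.na(z$z) & abs(z$z) >= 2)) n_sig <- n_sig + 1L
  }
  # a handful of k-levels are tested per seed without multiplicity
  # correction, so allow up to 20% of seeds to trip the 2-SD line
  expect_lte(n_sig, 4L)
})

test_that("z-scores reproduce known worked rows and handle degenerate SDs", {
  sim <- data.frame(k = c(1, 4), sim_mean = c(309.5, 1.0), sim_sd = c(8.3, 0.1))
  z <- z_scores(c(`1` = 262, `4` = 3), sim)
  expect_equal(z$z[z$k == 1], -5.7)
  expect_equal(z$z[z$k == 4], 20.0)
  expect_true(all(z$significant))

  # observed equal to mean: z = 0, not significant, even at sd 0
  z0 <- z_scores(c(`1` = 5), data.frame(k = 1, sim_mean = 5, sim_sd = 0))
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  # sd 0 with a different observed value: flagged, not infinite
  zf <- z_scores(c(`1` = 6), data.frame(k = 1, sim_mean = 5, sim_sd = 0))
  expect_true(is.na(zf$z))
  # observed k never seen in simulation: flagged
  zm <- z_scores(c(`2` = 1), data.frame(k = 1, sim_mean = 1, sim_sd = 0.5))
  expect_true(is.na(zm$z[zm$k == 2]))
})
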