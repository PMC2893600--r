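test_that("log ratios are group mean differences on the log2 scale", {
  samples <- tiny_samples(R = 1)[1:4, ]
  ids <- samples$sample_id
  e <- matrix(rnorm(20 * 4, 8), 20,
              dimnames = list(sprintf("g%02d", 1:20), ids))
  # identical groups: zero
  e2 <- cbind(e[, 1:2], e[, 1:2]); colnames(e2) <- ids
  expect_equal(unname(log_ratio(e2, ids[1:2], ids[3:4])), rep(0, 20))
  # constant 2x on the linear scale = +1 in log2
  e3 <- cbind(e[, 1:2] + 1, e[, 1:2]); colnames(e3) <- ids
  expect_equal(unname(log_ratio(e3, ids[1:2], ids[3:4])), rep(1, 20))
  # brute force on a random matrix
  set.seed(14)
  e4 <- matrix(rnorm(20 * 6, 8), 20,
               dimnames = list(sprintf("g%02d", 1:20), paste0("x", 1:6)))
  got <- log_ratio(e4, paste0("x", 1:3), paste0("x", 4:6))
  brute <- apply(e4, 1, function(r) mean(r[1:3]) - mean(r[4:6]))
  expect_equal(got, brute)
  expect_error(log_ratio(e4, character(0), "x1"), class = "cshmask_value_error")
  expect_error(log_ratio(e4, "x1", "x1"), class = "cshmask_value_error")
})

test_that("commonly-selected genes need a 2-fold ratio in both species", {
  ref <- c(a = 1.2, b = 1.2, c = -1.4, d = 0.5, e = 2.0)
  tgt <- c(a = 1.4, b = 0.8, c = 1.1, d = 2.0, e = -2.0, zzz = 3)
  expect_identical(commonly_selected(ref, tgt), c("a", "c", "e"))
  # concordant flag additionally requires matching sign
  expect_identical(commonly_selected(ref, tgt, concordant = TRUE), "a")
  # fold parameter: only gene e reaches 4-fold in both species
  expect_identical(commonly_selected(ref, tgt, fold = 4), "e")
  expect_error(commonly_selected(c(x = 1), c(y = 1)),
               class = "cshmask_value_error")
  # brute-force count on random vectors
  set.seed(6)
  r1 <- setNames(rnorm(200, 0, 1.2), sprintf("g%03d", 1:200))
  r2 <- setNames(rnorm(200, 0, 1.2), sprintf("g%03d", 1:200))
  brute <- sum(abs(r1) >= 1 & abs(r2) >= 1)
  expect_length(commonly_selected(r1, r2), brute)
})

test_that("threshold selection maximizes the scaled sensitivity/accuracy minimum", {
  # hand-built crossing curves: sensitivity falls, accuracy rises, the
  # min-max scaled curves cross between 30 and 40
  curves <- data.frame(
    threshold = c(10, 20, 30, 40, 60),
    n_probes_retained = 0, n_probesets_retained = 0,
    n_common_genes = c(100, 95, 85, 70, 40),
    pearson_r = c(0.20, 0.24, 0.28, 0.33, 0.34)
  )
  # by hand: scaled sens = (n-40)/60 -> 1, .917, .75, .5, 0
  #          scaled acc = (r-.2)/.14 -> 0, .286, .571, .929, 1
  # minima: 0, .286, .571, .5, 0 -> max at 30
  expect_equal(pick_threshold(curves), 30)
  # dominance: one threshold best on both metrics
  dom <- data.frame(threshold = c(10, 20, 30),
                    n_common_genes = c(50, 90, 60),
                    pearson_r = c(0.2, 0.4, 0.3))
  expect_equal(pick_threshold(dom), 20)
  # constant curves: tie broken toward the smallest threshold
  flat <- data.frame(threshold = c(10, 20, 30),
                     n_common_genes = 50, pearson_r = 0.5)
  expect_equal(pick_threshold(flat), 10)
  # undefined correlations are excluded; too few defined is an error
  na2 <- data.frame(threshold = 1:3, n_common_genes = 5,
                    pearson_r = c(0.1, NA, NA))
  expect_error(pick_threshold(na2), class = "cshmask_value_error")
})

test_that("on simulator defaults, sensitivity rises then falls while accuracy rises from the unmasked point", {
  for (s in 1:5) {
    sim <- simulate_csh(sim_config(n_probesets = 1000, seed = s + 40))
    res <- run_pipeline(sim$target, sim$reference, sim$map, sim$samples,
                        sim$sfp)
    cv <- res$curve
    peak <- which.max(cv$n_common_genes)
    expect_gt(peak, 1)                       # rises from threshold 0
    expect_lt(peak, nrow(cv))                # and falls again
    expect_lt(cv$n_common_genes[nrow(cv)], max(cv$n_common_genes))
    # accuracy above the unmasked value somewhere in the masked series
    expect_gt(max(cv$pearson_r[-1], na.rm = TRUE), cv$pearson_r[1])
  }
})

test_that("threshold curve reproduces the unmasked analysis at threshold 0", {
  sim <- small_sim(seed = 31)
  norm <- quantile_normalize(background_correct(sim$target))
  normr <- quantile_normalize(background_correct(sim$reference))
  ref_expr <- summarize_expression(normr, sim$map, verbose = FALSE)
  rs <- sim$samples[sim$samples$species == "reference", ]
  ref_ratio <- log_ratio(ref_expr, rs$sample_id[rs$tissue == "PES"],
                         rs$sample_id[rs$tissue == "ES"])
  params <- mask_rule_params(sim$samples)
  no_mask <- mask_file(character(0), threshold = 0, provenance = "ISV")
  masks <- c(list(`0` = no_mask),
             build_threshold_series(norm, c(40, 100), params))
  curve <- threshold_curve(norm, masks, sim$map, sim$samples, ref_ratio)
  expect_equal(nrow(curve), 3L)
  expect_equal(curve$threshold, c(0, 40, 100))
  expect_equal(curve$n_probes_retained[1], nrow(norm))
  expect_equal(curve$n_probesets_retained[1], sim$config$n_probesets)
  # direct recomputation of the unmasked point
  e0 <- summarize_expression(norm, sim$map, verbose = FALSE)
  ts <- sim$samples[sim$samples$species == "target", ]
  ratio0 <- log_ratio(e0, ts$sample_id[ts$tissue == "PES"],
                      ts$sample_id[ts$tissue == "ES"])
  common0 <- commonly_selected(ref_ratio, ratio0)
  expect_equal(curve$n_common_genes[1], length(common0))
  expect_equal(curve$pearson_r[1], cor(ref_ratio[common0], ratio0[common0]))
  # identical ratio vectors correlate exactly at 1
  expect_equal(cor(ratio0[common0], ratio0[common0]), 1)
  # probes/probe sets retained are non-increasing in threshold
  expect_true(all(diff(curve$n_probes_retained) <= 0))
  expect_true(all(diff(curve$n_probesets_retained) <= 0))
})
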