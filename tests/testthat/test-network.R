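test_that("channel EC enumerates ordered pairs and honours conditions", {
  pr <- pair_recording(a = 0.5, f = c(0.1, 0.1), noise = 0.05, seed = 31,
                       duration = 400)
  rec <- pr$rec
  m <- toy_montage()
  colnames(rec$hbo) <- colnames(rec$hhb) <- c("CH01", "CH03")
  rec$channels <- c("CH01", "CH03")
  ec <- compute_channel_ec(rec, m, bands = band_set()[3, ],
                           n_surrogates = 5, seed = 3)
  # 2 channels -> 2 ordered pairs (self-pairs excluded by construction)
  expect_equal(nrow(ec), 2)
  expect_true(all(ec$source != ec$target))
  expect_setequal(paste(ec$source, ec$target),
                  c("CH01 CH03", "CH03 CH01"))
  # the planted direction CH03 -> CH01 dominates and is significant
  expect_true(ec$significant[ec$source == "CH03"])
  # a band whose 10-cycle requirement exceeds the segment is skipped
  expect_warning(
    ec4 <- compute_channel_ec(rec, m, bands = band_set()[4, ],
                              n_surrogates = 5, seed = 3),
    "skipped")
  expect_equal(nrow(ec4), 0)
})

test_that("region aggregation averages significant pairs only", {
  m <- toy_montage()
  # hand-built: 2 regions x 2 channels; LMC = CH01, CH02; LPFC = CH03, CH04
  res <- fake_channel_results(m, sigma = 1)
  lmc_to_lpfc <- res$source %in% c("CH01", "CH02") &
    res$target %in% c("CH03", "CH04")
  res$sigma[lmc_to_lpfc] <- c(1, 2, 3, 4)
  agg <- aggregate_regions(res, m)
  expect_equal(agg$value[agg$source == "LMC" & agg$target == "LPFC"], 2.5)
  expect_equal(agg$n_significant[agg$source == "LMC" &
                                   agg$target == "LPFC"], 4L)
  # non-significant pairs are excluded, empty cells report 0 with count 0
  res$significant[lmc_to_lpfc] <- FALSE
  agg2 <- aggregate_regions(res, m)
  expect_equal(agg2$value[agg2$source == "LMC" & agg2$target == "LPFC"], 0)
  expect_equal(agg2$n_significant[agg2$source == "LMC" &
                                    agg2$target == "LPFC"], 0L)
  # within-region channel pairs never contribute
  expect_false(any(agg$source == agg$target))
})

test_that("six regions give 30 directed cells and support asymmetry", {
  m <- default_montage()
  agg <- aggregate_regions(fake_channel_results(m, sigma = 2), m)
  expect_equal(nrow(agg), 30)
  expect_true(all(agg$value == 2))
  # relabeling channels within a region leaves the aggregate unchanged
  res <- fake_channel_results(m, sigma = seq(0, 1, length.out = 552))
  agg1 <- aggregate_regions(res, m)
  swap <- c(CH01 = "CH02", CH02 = "CH01")
  res2 <- res
  res2$source <- dplyr::recode(res$source, !!!swap)
  res2$target <- dplyr::recode(res$target, !!!swap)
  agg2 <- aggregate_regions(res2, m)
  key <- function(a) a[order(a$source, a$target), ]
  expect_equal(key(agg1)$value, key(agg2)$value)
  # planted asymmetry is representable
  res3 <- fake_channel_results(m, sigma = 0.1)
  up <- res3$source == "CH13" & res3$target == "CH05"
  res3$sigma[up] <- 5
  agg3 <- aggregate_regions(res3, m)
  expect_gt(agg3$value[agg3$source == "RMC" & agg3$target == "RPFC"],
            agg3$value[agg3$source == "RPFC" & agg3$target == "RMC"])
  expect_equal(dim(network_matrix(agg3)), c(6, 6))
  expect_equal(sum(diag(network_matrix(agg3))), 0)
})

test_that("activation maps interpolate by inverse distance", {
  m <- default_montage()
  n <- 100
  hbo <- matrix(2.5, n, 24, dimnames = list(NULL, m$channels$channel))
  rec <- hemo_recording(hbo, -hbo, 10)
  am <- activation_map(rec, "all", m, grid_n = 16)
  # constant field stays constant
  expect_true(all(abs(am$grid$value - 2.5) < 1e-9))
  # node coincident with a channel midpoint takes that channel's mean
  set.seed(5)
  hbo2 <- matrix(rnorm(n * 24), n, 24,
                 dimnames = list(NULL, m$channels$channel))
  rec2 <- hemo_recording(hbo2, -hbo2, 10)
  am2 <- activation_map(rec2, "all", m, grid_n = 16)
  expect_equal(am2$channel_means$mean, unname(colMeans(hbo2)))
  # hand IDW: two channels 0 and 10, equidistant query, power 2 -> 5
  w <- 1 / c(4, 4)^1
  expect_equal(sum(w * c(0, 10)) / sum(w), 5)
  d2 <- (am2$grid$x - am2$channel_means$x[1])^2 +
    (am2$grid$y - am2$channel_means$y[1])^2
  hit <- which.min(d2)
  if (d2[hit] < 1e-12) {
    expect_equal(am2$grid$value[hit], am2$channel_means$mean[1])
  }
  expect_s3_class(ggplot2::autoplot(am2), "ggplot")
})

test_that("planted channel coupling survives to the region level", {
  # two coupled channels in different regions, interval III for speed
  pr <- pair_recording(a = 0.5, f = c(0.1, 0.11), noise = 0.05, seed = 77,
                       duration = 500)
  rec <- pr$rec
  m <- toy_montage()
  colnames(rec$hbo) <- colnames(rec$hhb) <- c("CH03", "CH01") # LPFC <- LMC
  rec$channels <- c("CH03", "CH01")
  ec <- compute_channel_ec(rec, m, bands = band_set()[3, ],
                           n_surrogates = 19, seed = 5)
  agg <- aggregate_regions(ec, m)
  cell <- agg[agg$source == "LMC" & agg$target == "LPFC", ]
  expect_gt(cell$value, 0)
  expect_gte(cell$n_significant, 1)
})
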