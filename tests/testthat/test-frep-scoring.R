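test_that("size factors recover pure depth shifts and respect the geomean-1 convention", {
  set.seed(2)
  base <- rpois(200, 50) + 1
  m <- cbind(s1 = base, s2 = 2L * base)
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # single sample
  expect_equal(unname(size_factors(matrix(base, ncol = 1,
                                          dimnames = list(NULL, "s1")))), 1)
  expect_error(size_factors(cbind(s1 = base, s2 = 0L * base)), "s2")
})

test_that("median-of-ratios resists a DE subset better than total-count scaling", {
  set.seed(7)
  n <- 1000
  base <- rpois(n, 100) + 1
  s2 <- rpois(n, 3 * base) # true depth ratio 3
  de <- sample.int(n, 100) # 10% of features 8-fold up in sample 2 only
  s2[de] <- rpois(length(de), 8 * 3 * base[de])
  m <- cbind(s1 = rpois(n, base), s2 = s2)
  sf <- size_factors(m)
  mor_ratio <- sf[["s2"]] / sf[["s1"]]
  tc_ratio <- sum(m[, 2]) / sum(m[, 1])
  expect_lt(abs(log(mor_ratio / 3)), abs(log(tc_ratio / 3)))
})

test_that("barcode log-ratios follow the pseudocounted formula", {
  lr <- barcode_log_ratio(100, 100, c(1, 1))
  expect_equal(lr$log_ratio, 0)
  lr0 <- barcode_log_ratio(0, 100, c(1, 1), pseudocount = 0.5)
  expect_equal(lr0$log_ratio, -7.65105169118, tolerance = 1e-10)
  expect_equal(lr0$reference_abundance, 100)
  # joint 3x scaling with matching factors is absorbed exactly
  lr1 <- barcode_log_ratio(c(10, 40), c(20, 30), c(1, 1))
  lr3 <- barcode_log_ratio(3 * c(10, 40), 3 * c(20, 30), c(3, 3))
  expect_equal(lr1$log_ratio, lr3$log_ratio, tolerance = 1e-12)
})

test_that("neighbourhood statistics match brute-force window recomputation", {
  set.seed(12)
  n <- 400
  rows <- data.frame(barcode = sprintf("BC%04d", 1:n),
                     log_ratio = rnorm(n),
                     reference_abundance = runif(n, 20, 2000))
  out <- neighborhood_normalize(rows, window_size = 51, min_count = 20)
  expect_equal(nrow(out), n)
  for (i in c(1, 2, 26, 200, 399, 400)) {
    lo <- max(1, i - 25); hi <- min(n, i + 25)
    w <- out$log_ratio[lo:hi]
    med <- median(w)
    expect_equal(out$nbhd_location[i], med)
    expect_equal(out$nbhd_scale[i], max(1.4826 * median(abs(w - med)), 1e-8))
    expect_equal(out$nns[i], (out$log_ratio[i] - med) / out$nbhd_scale[i])
  }
  # all identical log-ratios: floored scale, zero scores
  same <- rows
  same$log_ratio <- 1.5
  z <- neighborhood_normalize(same, window_size = 51)
  expect_true(all(z$nns == 0))
  expect_error(neighborhood_normalize(rows[1:2, ]), "fewer than 3")
  expect_error(neighborhood_normalize(rows, window_size = 50), "odd")
})

test_that("null neighbourhood scores are calibrated (mean ~0, sd ~1)", {
  set.seed(3)
  n <- 10000
  rows <- data.frame(barcode = sprintf("BC%05d", 1:n),
                     log_ratio = rnorm(n),
                     reference_abundance = exp(runif(n, log(20), log(5000))))
  out <- neighborhood_normalize(rows)
  expect_lt(abs(mean(out$nns)), 0.05)
  expect_gt(sd(out$nns), 0.9)
  expect_lt(sd(out$nns), 1.1)
})

test_that("gene scores aggregate barcode scores through guides", {
  lib <- validate_guide_library(data.frame(
    barcode = c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG", "TTTTTTTTTTTT"),
    guide_id = c("GA_g1", "GA_g2", "GA_g3", "GB_g1"),
    gene = c("GA", "GA", "GA", "GB"), is_control = FALSE))
  bs <- data.frame(barcode = lib$barcode[1:3], nns = c(2, 0, 1))
  gs <- gene_frep_score(bs, lib)
  expect_equal(gs$score[gs$gene == "GA"], 1)
  expect_true(is.na(gs$score[gs$gene == "GB"])) # no surviving guide
  one <- gene_frep_score(data.frame(barcode = "TTTTTTTTTTTT", nns = 1.7), lib)
  expect_equal(one$score[one$gene == "GB"], 1.7)
})

test_that("replicate combination reproduces the one-sample t-test", {
  sc <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   r1 = c(1, 1.8, 2, 1), r2 = c(-1, 2.2, 2, NA),
                   r3 = c(1, 2.0, 2, NA), r4 = c(-1, 2.0, 2, NA))
  out <- combine_replicates(sc)
  expect_equal(out$frep_score, c(0, 2, 2, 1))
  expect_equal(out$t_stat[1], 0)
  expect_equal(out$p_value[1], 1)
  # hand-computed: sd = 0.1633, t = 24.4949, df = 3
  expect_equal(out$t_stat[2], 24.4948974278, tolerance = 1e-8)
  expect_equal(out$p_value[2], 0.000149157201285, tolerance = 1e-8)
  expect_equal(out$flag[3], "degenerate_variance")
  expect_equal(out$p_value[3], 1e-12)
  expect_equal(out$flag[4], "insufficient_replicates")
  expect_true(is.na(out$p_value[4]))
})

test_that("screen scoring recovers planted modulators with the right sign", {
  cfg <- sim_config(n_genes = 80, frac_effect_genes = 0.1,
                    effect_logfc_mean = 1.5, effect_logfc_sd = 0, seed = 31)
  lib <- simulate_guide_library(cfg)
  sim <- simulate_screen(lib, cfg)
  res <- frep_score_screen(sim$counts, lib)
  g <- merge(res$genes, sim$truth, by = "gene")
  pos <- g$effect_log2 != 0
  expect_gte(auroc(abs(g$frep_score), pos), 0.9)
  expect_true(all(g$frep_score[pos] > 0))
  # negative planted effects give negative scores
  cfg2 <- sim_config(n_genes = 80, frac_effect_genes = 0.1,
                     effect_logfc_mean = -1.5, effect_logfc_sd = 0, seed = 32)
  lib2 <- simulate_guide_library(cfg2)
  sim2 <- simulate_screen(lib2, cfg2)
  res2 <- frep_score_screen(sim2$counts, lib2)
  g2 <- merge(res2$genes, sim2$truth, by = "gene")
  expect_true(all(g2$frep_score[g2$effect_log2 != 0] < 0))
})

test_that("auroc matches brute-force pair counting", {
  set.seed(44)
  score <- c(rnorm(30, 1), rnorm(50, 0), rnorm(3, 1)[c(1, 1, 1)])
  positive <- c(rep(TRUE, 30), rep(FALSE, 50), c(TRUE, FALSE, FALSE))
  expect_equal(auroc(score, positive), bf_auroc(score, positive))
})

test_that("screen comparison labels interactions and reports correlation", {
  a <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                  frep_score = c(3.5, 2.5, 0.5, 1.0, 2.2))
  b <- data.frame(gene = c("g1", "g2", "g3", "g4", "g6"),
                  frep_score = c(0.5, 2.6, 3.0, 1.2, 9))
  cmp <- compare_screens(a, b)
  tab <- cmp$table
  expect_equal(cmp$n_shared, 4)
  expect_equal(tab$label[tab$gene == "g1"], "alleviating")
  expect_equal(tab$label[tab$gene == "g2"], "shared")
  expect_equal(tab$label[tab$gene == "g3"], "aggravating")
  expect_equal(tab$label[tab$gene == "g4"], "neither")
  # identical screens: r = 1, non-hits all neither
  same <- compare_screens(a, a)
  expect_equal(same$pearson_r, 1)
  expect_true(all(same$table$label[same$table$score_a < 2] == "neither"))
  # independent null screens decorrelate
  set.seed(9)
  n0 <- data.frame(gene = sprintf("g%04d", 1:1000), frep_score = rnorm(1000))
  n1 <- data.frame(gene = sprintf("g%04d", 1:1000), frep_score = rnorm(1000))
  expect_lt(abs(compare_screens(n0, n1)$pearson_r), 0.1)
  expect_error(compare_screens(a[1:2, ], b), "3 shared")
})

test_that("scaling one sample is fully absorbed by depth-anchored factors", {
  cfg <- sim_config(n_genes = 30, seed = 61)
  lib <- simulate_guide_library(cfg)
  sim <- simulate_screen(lib, cfg)
  res1 <- frep_score_screen(sim$counts, lib)
  for (col in c(2L, 5L)) {
    scaled <- sim$counts
    scaled[[col]] <- scaled[[col]] * 7
    res2 <- frep_score_screen(scaled, lib)
    for (r in names(res1$barcodes)) {
      expect_identical(res1$barcodes[[r]]$barcode, res2$barcodes[[r]]$barcode)
      expect_lt(max(abs(res1$barcodes[[r]]$nns - res2$barcodes[[r]]$nns)),
                1e-9)
    }
  }
})
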