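test_that("guide libraries have the requested geometry and unique barcodes", {
  cfg <- sim_config(n_genes = 2, guides_per_gene = 12, barcodes_per_guide = 1,
                    seed = 11)
  lib <- simulate_guide_library(cfg)
  expect_equal(nrow(lib), 24)
  expect_equal(length(unique(lib$guide_id)), 24)
  expect_equal(length(unique(lib$barcode)), 24)
  expect_equal(length(unique(lib$gene)), 2)

  one <- simulate_guide_library(sim_config(n_genes = 1, guides_per_gene = 1,
                                           barcodes_per_guide = 1, seed = 3))
  expect_equal(nrow(one), 1)
})

test_that("generated barcodes are pairwise Hamming distance >= 3 (all-pairs scan)", {
  cfg <- sim_config(n_genes = 10, guides_per_gene = 4, barcodes_per_guide = 2,
                    seed = 5)
  lib <- simulate_guide_library(cfg)
  d <- Inf
  for (i in seq_len(nrow(lib) - 1))
    for (j in (i + 1):nrow(lib))
      d <- min(d, bf_hamming(lib$barcode[i], lib$barcode[j]))
  expect_gte(d, 3)
  expect_equal(min_pairwise_hamming(lib$barcode), d)
})

test_that("a too-small barcode space fails naming the barcode length", {
  cfg <- sim_config(n_genes = 50, guides_per_gene = 12, barcodes_per_guide = 2,
                    barcode_length = 6, seed = 1)
  expect_error(simulate_guide_library(cfg), "barcode_length")
})

test_that("screen simulation is deterministic and honours the null model", {
  cfg <- sim_config(n_genes = 20, seed = 42)
  lib <- simulate_guide_library(cfg)
  a <- simulate_screen(lib, cfg)
  b <- simulate_screen(lib, cfg)
  expect_identical(a, b)
  expect_true(all(a$truth$effect_log2 == 0))
  expect_equal(ncol(a$counts), 1 + 2 * cfg$n_replicates)
  expect_true(all(as.matrix(a$counts[-1]) >= 0))
})

test_that("planted effects shift only the pellet fraction, with the right sign", {
  cfg <- sim_config(n_genes = 40, frac_effect_genes = 0.25,
                    effect_logfc_mean = 1, effect_logfc_sd = 0,
                    nb_dispersion = 0, replicate_sd = 0, depth_per_sample = 1e6,
                    seed = 9)
  lib <- simulate_guide_library(cfg)
  sim <- simulate_screen(lib, cfg)
  mods <- sim$truth$gene[sim$truth$effect_log2 != 0]
  expect_length(mods, 10)
  lr <- log2((sim$counts$WT_30_0_pellet_rep1 + 0.5) /
               (sim$counts$WT_30_0_total_rep1 + 0.5))
  is_mod <- lib$gene %in% mods
  # truth channel: modulator barcodes carry the planted log2 shift
  expect_gt(mean(lr[is_mod]) - mean(lr[!is_mod]), 0.8)
  # total fraction untouched: per-barcode total means comparable
  tot_ratio <- mean(sim$counts$WT_30_0_total_rep1[is_mod]) /
    mean(sim$counts$WT_30_0_total_rep1[!is_mod])
  expect_lt(abs(log2(tot_ratio)), 0.5)
})

test_that("simulated counts follow the mu + phi*mu^2 variance law", {
  phi <- 0.1
  mus <- c(10, 100, 1000)
  set.seed(1)
  for (mu in mus) {
    x <- frepscreen:::rnbinom_disp(20000, mu, phi)
    expected <- mu + phi * mu^2
    expect_lt(abs(var(x) / expected - 1), 0.15)
  }
  set.seed(1)
  x <- frepscreen:::rnbinom_disp(20000, 50, 0)
  expect_lt(abs(var(x) / 50 - 1), 0.1)
})

test_that("column sums track the configured depth (NB Monte-Carlo)", {
  cfg <- sim_config(n_genes = 42, guides_per_gene = 12, barcodes_per_guide = 2,
                    depth_per_sample = 1e5, nb_dispersion = 0.05,
                    replicate_sd = 0, seed = 7)
  lib <- simulate_guide_library(cfg) # ~1000 barcodes
  sim <- simulate_screen(lib, cfg)
  tot <- sum(sim$counts$WT_30_0_total_rep1)
  # NB variance summed over barcodes gives the sd of the column total
  abund_sd <- sqrt(1e5 + cfg$nb_dispersion * sum((1e5 / nrow(lib))^2) *
                     nrow(lib) * exp(1)) # loose upper bound on sd
  expect_lt(abs(tot - 1e5), 5 * max(abund_sd, sqrt(1e5) * 3))
})

test_that("simulated reads round-trip exactly at zero error rate", {
  lay <- read_layout()
  counts <- c(ACGTACGTACGT = 3L, GGGGTTTTAAAA = 2L)
  reads <- simulate_reads(counts, lay, error_rate = 0, seed = 2)
  expect_length(reads, 5)
  expect_true(all(substr(reads[1:3], 9, 20) == "ACGTACGTACGT"))
  f <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(counts, lay, error_rate = 0, seed = 2, path = f)
  lib <- tiny_library(names(counts))
  res <- count_barcodes(f, lib, lay)
  expect_equal(res$counts, counts)
  expect_equal(res$qc$reads_unmatched, 0)
  # byte-identical regeneration
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(counts, lay, error_rate = 0, seed = 2, path = f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("read error rate matches the binomial closed form", {
  # P(>=1 error in a 12-nt barcode) at e=0.01 is 1 - 0.99^12 ~ 0.11362
  lay <- read_layout()
  bc <- strrep("A", 12)
  reads <- simulate_reads(stats::setNames(20000L, bc), lay,
                          error_rate = 0.01, seed = 4)
  obs <- mean(substr(reads, 9, 20) != bc)
  expect_lt(abs(obs - 0.113615128284), 0.01)
})

test_that("transcriptome generator plants length confound and group shifts", {
  tc <- transcriptome_config(n_transcripts = 2000,
                             group_sizes = c(Hsf1 = 100, `Msn2/4` = 100,
                                             RPG = 100),
                             seed = 21)
  sim <- simulate_fraction_transcriptome(tc)
  expect_identical(sim$tx, simulate_fraction_transcriptome(tc)$tx)
  expect_equal(nrow(sim$tx), 2000)
  expect_equal(sum(sim$tx$group == "RPG"), 100)
  # length slope > 0 makes raw condensation correlate with length
  raw30 <- log2((sim$tx$WT_30_0_pellet_rep1 + 0.5) /
                  (sim$tx$WT_30_0_total_rep1 + 0.5))
  expect_gt(cor(raw30, log(sim$tx$length)), 0.5)
  # zero slope, zero effects: condensation flat in expectation
  tc0 <- transcriptome_config(n_transcripts = 1000, length_slope = 0,
                              cond_effect_42 = c(Hsf1 = 0, `Msn2/4` = 0, RPG = 0),
                              ribo_effect_42 = c(Hsf1 = 0, `Msn2/4` = 0, RPG = 0),
                              bio_sd = 0, seed = 8)
  sim0 <- simulate_fraction_transcriptome(tc0)
  raw0 <- log2((sim0$tx$WT_42_30_pellet_rep1 + 0.5) /
                 (sim0$tx$WT_42_30_total_rep1 + 0.5))
  expect_lt(abs(cor(raw0, log(sim0$tx$length))), 0.1)
  # planted RPG shift at 42C separates from background (rank-sum)
  sc <- score_transcriptome(sim$tx)
  p <- wilcox.test(sc$delta_cond_z[sc$group == "RPG"],
                   sc$delta_cond_z[sc$group == "background"])$p.value
  expect_lt(p, 0.05)
})

test_that("Ct simulation follows the log2 abundance model", {
  ab <- data.frame(target = c("HSP12", "HSP12"), fraction = c("pellet", "pellet"),
                   condition = "HS", strain = c("WT", "WT2"),
                   abundance = c(1, 2))
  ct <- simulate_ct_table(ab, intercept = 30, ct_sd = 0, seed = 1)
  # doubling abundance lowers Ct by exactly one cycle
  expect_equal(ct$ct1[2], ct$ct1[1] - 1)
  expect_equal(ct$ct1, ct$ct2)
  # median-of-3 estimator beats a single well under noise
  set.seed(99)
  seeds <- sample.int(1e6, 800)
  single <- vapply(seeds[1:400], function(s)
    simulate_ct_table(ab[1, ], ct_sd = 0.2, n_tech = 3, seed = s)$ct1,
    numeric(1))
  meds <- vapply(seeds[401:800], function(s) {
    w <- simulate_ct_table(ab[1, ], ct_sd = 0.2, n_tech = 3, seed = s)
    median(c(w$ct1, w$ct2, w$ct3))
  }, numeric(1))
  expect_lt(sd(meds), sd(single))
})

test_that("labelled substreams are independent and reproducible", {
  a <- with_substream <- frepscreen:::with_substream
  x1 <- a(7, "alpha", rnorm(5))
  x2 <- a(7, "alpha", rnorm(5))
  y <- a(7, "beta", rnorm(5))
  expect_identical(x1, x2)
  expect_false(identical(x1, y))
  expect_false(identical(substream_seed(7, "alpha"), substream_seed(8, "alpha")))
})
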