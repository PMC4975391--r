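test_that("heterozygous SNP selection enforces depth > 19 and inclusive AF bounds", {
  tr <- rbind(
    make_snp_track(100, tumor_af = 0.5, depth = 50, normal_af = 0.48),
    make_snp_track(200, tumor_af = 0.5, depth = 19, normal_af = 0.5),
    make_snp_track(300, tumor_af = 0.5, depth = 20, normal_af = 0.5),
    make_snp_track(400, tumor_af = 0.5, depth = 100, normal_af = 0.40),
    make_snp_track(500, tumor_af = 0.5, depth = 100, normal_af = 0.39),
    make_snp_track(600, tumor_af = 0.5, depth = 100, normal_af = 0.61)
  )
  kept <- identify_het_snps(tr)
  expect_equal(kept$pos, c(100, 300, 400))
  # unpaired track is redirected
  un <- tr
  un$normal_ref <- NA; un$normal_alt <- NA; un$paired <- FALSE
  expect_error(identify_het_snps(un), "unpaired")
})

test_that("het selection agrees with a brute-force re-filter on simulated sites", {
  set.seed(7)
  n <- 1000
  depth <- rpois(n, 80)
  alt <- rbinom(n, depth, 0.5)
  tr <- data.frame(chrom = "chr16", pos = seq_len(n) * 1000,
                   normal_ref = depth - alt, normal_alt = alt,
                   tumor_ref = 40, tumor_alt = 40, paired = TRUE)
  kept <- identify_het_snps(tr)
  af <- alt / depth
  oracle <- depth >= 20 & af >= 0.40 & af <= 0.60
  expect_equal(kept$pos, tr$pos[oracle])
})

test_that("unpaired candidate selection keeps AF in [0.05, 0.95]", {
  tr <- make_snp_track(c(100, 200, 300, 400), tumor_af = c(0.96, 0.05, 0.5, 1))
  tr$normal_ref <- NA; tr$normal_alt <- NA; tr$paired <- FALSE
  kept <- identify_candidate_snps_unpaired(tr)
  expect_equal(kept$pos, c(200, 300))
})

test_that("skew calls are strict at the 0.40/0.60 boundaries", {
  tr <- make_snp_track(c(100, 200, 300, 400, 500),
                       tumor_af = c(0.39, 0.50, 0.60, 0.40, 0.61))
  sk <- call_skew(tr)
  expect_equal(as.character(sk$skew),
               c("skewed", "normal", "normal", "normal", "skewed"))
  # zero tumor depth is dropped with a warning
  tr0 <- tr
  tr0$tumor_ref[1] <- 0; tr0$tumor_alt[1] <- 0
  expect_warning(sk0 <- call_skew(tr0), "zero tumor depth")
  expect_equal(nrow(sk0), 4)
})

test_that("a telomere-anchored skewed run becomes one region with correct bounds", {
  pos_loh <- seq(50e3, 3e6, length.out = 50)       # 50 skewed SNPs
  pos_norm <- seq(3.2e6, 10e6, length.out = 30)
  tr <- rbind(make_snp_track(pos_loh, tumor_af = 0.8),
              make_snp_track(pos_norm, tumor_af = 0.5))
  reg <- delineate_loh_regions(tr)
  expect_equal(nrow(reg), 1)
  expect_true(reg$telomere_anchored)
  expect_equal(reg$confident_start, 50e3)
  expect_equal(reg$confident_end, 3e6)
  expect_equal(reg$uncertain_start, 50e3)  # no normal SNP telomeric of it
  expect_equal(reg$uncertain_end, pos_norm[1])
  expect_equal(reg$n_skewed, 50)
  expect_true(reg$start_censored)
  expect_false(reg$end_censored)
})

test_that("all-normal tracks and sub-threshold runs give no region", {
  tr <- make_snp_track(seq(1e5, 1e6, by = 1e5), tumor_af = 0.5)
  expect_equal(nrow(delineate_loh_regions(tr)), 0)
  tr2 <- rbind(make_snp_track(seq(1e5, 5e5, by = 1e5), tumor_af = 0.9),
               make_snp_track(seq(6e5, 2e6, by = 1e5), tumor_af = 0.5))
  reg <- delineate_loh_regions(tr2)  # 5 skewed < min_skewed = 10
  expect_equal(nrow(reg), 0)
  expect_equal(sort(attr(reg, "unassigned")), seq(1e5, 5e5, by = 1e5))
})

test_that("isolated interior normal SNPs are tolerated and counted", {
  af <- rep(0.8, 40)
  af[c(15, 30)] <- 0.5
  tr <- make_snp_track(seq_len(40) * 1e5, tumor_af = af)
  reg <- delineate_loh_regions(tr)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_skewed, 38)
  expect_equal(reg$n_discordant_interior, 2)
  expect_equal(reg$confident_start, 1e5)
  expect_equal(reg$confident_end, 40e5)
})

test_that("every skewed SNP is inside a region or reported unassigned", {
  set.seed(33)
  for (rep in 1:20) {
    cfg <- simulation_config(seed = NULL, n_snps = 400, purity = 0.5,
                             cnloh_breakpoint = 12e6)
    sim <- simulate_snp_track(cfg)
    sk <- call_skew(identify_het_snps(sim$track))
    reg <- delineate_loh_regions(sk)
    skew_pos <- sk$pos[sk$skew == "skewed"]
    in_region <- rep(FALSE, length(skew_pos))
    for (i in seq_len(nrow(reg)))
      in_region <- in_region | (skew_pos >= reg$confident_start[i] &
                                  skew_pos <= reg$confident_end[i])
    expect_setequal(skew_pos[!in_region], attr(reg, "unassigned"))
    # confident spans disjoint
    if (nrow(reg) > 1) {
      o <- order(reg$confident_start)
      expect_true(all(reg$confident_start[o][-1] >
                        reg$confident_end[o][-nrow(reg)]))
    }
  }
})

test_that("per-SNP skew call rate matches the binomial tail probability", {
  set.seed(55)
  purity <- 0.5
  cfg <- simulation_config(seed = NULL, n_snps = 6000, purity = purity,
                           mean_depth = 80, cnloh_breakpoint = 30e6)
  sim <- simulate_snp_track(cfg)
  sk <- call_skew(sim$track)
  in_loh <- sim$truth$in_loh[match(sk$pos, sim$track$pos)]
  d <- sk$tumor_ref + sk$tumor_alt
  af_true <- sim$truth$af_true[match(sk$pos, sim$track$pos)]
  # P(AF-hat < 0.4 or > 0.6) at each site's realised depth
  k_lo <- ifelse(abs(0.4 * d - round(0.4 * d)) < 1e-9,
                 round(0.4 * d) - 1, floor(0.4 * d))
  k_hi <- ifelse(abs(0.6 * d - round(0.6 * d)) < 1e-9,
                 round(0.6 * d), floor(0.6 * d))
  p_skew <- pbinom(k_lo, d, af_true) + 1 - pbinom(k_hi, d, af_true)
  observed <- mean(sk$skew[in_loh] == "skewed")
  expected <- mean(p_skew[in_loh])
  se <- sqrt(sum(p_skew[in_loh] * (1 - p_skew[in_loh]))) / sum(in_loh)
  expect_lt(abs(observed - expected), 3 * se + 1e-4)
})

test_that("copy status is read off the median log2 ratio", {
  reg <- data.frame(chrom = "chr16", confident_start = 1e6,
                    confident_end = 2e6)
  win <- function(ratio, n = 10)
    data.frame(start = seq(1e6, 2e6 - 1, length.out = n),
               end = seq(1e6, 2e6 - 1, length.out = n) + 5e4,
               ratio = ratio)
  expect_equal(assess_copy_neutrality(reg, win(1.0)), "neutral")
  # homozygous deletion at purity 0.8: 0.4 mixture copies -> ratio 0.2
  expect_equal(assess_copy_neutrality(reg, win(0.2)), "homozygous_loss")
  # single-copy loss at purity ~0.55: ~1.47 copies -> ratio 0.735
  expect_equal(assess_copy_neutrality(reg, win(1.47 / 2)), "single_loss")
  expect_equal(assess_copy_neutrality(reg, win(1.5)), "gain")
  expect_equal(assess_copy_neutrality(reg, win(1.0, n = 3)),
               "indeterminate")
})

test_that("nested homozygous deletions are recovered from coverage runs", {
  # 150 kb single-loss interval containing a 50 kb homozygous dip
  start <- seq(2.0e6, 2.25e6 - 1e4, by = 1e4)
  ratio <- rep(1.0, length(start))
  loss <- start >= 2.03e6 & start < 2.18e6
  hom <- start >= 2.08e6 & start < 2.13e6
  ratio[loss] <- 0.7
  ratio[hom] <- 0.2
  cov <- data.frame(start = start, end = start + 1e4, ratio = ratio)
  dels <- detect_homozygous_deletion(cov)
  expect_equal(nrow(dels), 2)
  outer <- dels[dels$copy_status == "single_loss", ]
  inner <- dels[dels$copy_status == "homozygous_loss", ]
  expect_equal(c(outer$start, outer$end), c(2.03e6, 2.18e6))
  expect_equal(c(inner$start, inner$end), c(2.08e6, 2.13e6))
  expect_true(inner$start >= outer$start && inner$end <= outer$end)
  # flat track -> nothing; single low window -> low confidence
  flat <- data.frame(start = start, end = start + 1e4, ratio = 1)
  expect_equal(nrow(detect_homozygous_deletion(flat)), 0)
  one <- flat; one$ratio[5] <- 0.1
  d1 <- detect_homozygous_deletion(one)
  expect_equal(nrow(d1), 1)
  expect_true(d1$low_confidence)
})
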