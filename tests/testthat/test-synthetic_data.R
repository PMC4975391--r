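test_that("identical seeds give bit-identical output", {
  a <- simulate_snp_track(simulation_config(seed = 5))
  b <- simulate_snp_track(simulation_config(seed = 5))
  expect_identical(a, b)
  pa <- simulate_patient(patient_preset("p13_like", seed = 5, n_snps = 200))
  pb <- simulate_patient(patient_preset("p13_like", seed = 5, n_snps = 200))
  expect_identical(pa, pb)
  c2 <- simulate_snp_track(simulation_config(seed = 6))
  expect_false(identical(a$track$tumor_alt, c2$track$tumor_alt))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(purity = 1.5), "purity")
  expect_error(simulation_config(cnloh_breakpoint = 99e6), "chrom_length")
  expect_error(simulation_config(n_snps = 0), "n_snps")
  expect_error(simulation_config(depth_dispersion = 0.5), "dispersion")
  cfgp <- patient_preset("p13_like", seed = 1)
  cfgp$truncal_groups <- list(list(members = c(1, 99), n_shared = 2))
  expect_error(simulate_patient(cfgp), "inconsistent")
  cfgp2 <- patient_preset("p13_like", seed = 1)
  cfgp2$second_hit <- "cnloh"
  expect_error(simulate_patient(cfgp2), "one entry per tumor")
})

test_that("purity 0 tumors are indistinguishable from normal", {
  cfg <- simulation_config(seed = 31, n_snps = 5000, purity = 0,
                           cnloh_breakpoint = 20e6)
  sim <- simulate_snp_track(cfg)
  taf <- sim$track$tumor_alt / (sim$track$tumor_alt + sim$track$tumor_ref)
  naf <- sim$track$normal_alt / (sim$track$normal_alt +
                                   sim$track$normal_ref)
  ks <- suppressWarnings(stats::ks.test(taf, naf))
  expect_gt(ks$p.value, 0.01)
})

test_that("purity 1 drives LOH-segment AFs to 0 or 1", {
  cfg <- simulation_config(seed = 32, purity = 1, cnloh_breakpoint = 20e6)
  sim <- simulate_snp_track(cfg)
  in_loh <- sim$truth$in_loh
  af <- sim$track$tumor_alt / (sim$track$tumor_alt + sim$track$tumor_ref)
  expect_true(all(af[in_loh] %in% c(0, 1)))
  expect_false(all(af[!in_loh] %in% c(0, 1)))
})

test_that("segment AF displacement matches the mixture model at moderate depth", {
  cfg <- simulation_config(seed = 33, n_snps = 2000, purity = 0.5,
                           mean_depth = 80, cnloh_breakpoint = 30e6)
  sim <- simulate_snp_track(cfg)
  in_loh <- sim$truth$in_loh
  af <- sim$track$tumor_alt / (sim$track$tumor_alt + sim$track$tumor_ref)
  disp <- abs(af[in_loh] - 0.5)
  se <- sd(disp) / sqrt(sum(in_loh))
  # |AF - 1/2| concentrates near p/2 = 0.25 (binomial jitter inflates it
  # slightly, hence the 3-SE-plus-bias allowance)
  expect_lt(abs(mean(disp) - 0.25), 3 * se + 0.01)
})

test_that("empirical AF means converge to the model at extreme depth", {
  cfg <- simulation_config(seed = 34, n_snps = 1500, purity = 0.4,
                           mean_depth = 10000, depth_dispersion = 1,
                           cnloh_breakpoint = 30e6)
  sim <- simulate_snp_track(cfg)
  af <- sim$track$tumor_alt / (sim$track$tumor_alt + sim$track$tumor_ref)
  retained <- sim$truth$in_loh & sim$truth$phase_retained
  lost <- sim$truth$in_loh & !sim$truth$phase_retained
  expect_lt(abs(mean(af[retained]) - 0.7), 0.005)
  expect_lt(abs(mean(af[lost]) - 0.3), 0.005)
  expect_lt(abs(mean(af[!sim$truth$in_loh]) - 0.5), 0.005)
})

test_that("patient presets carry the documented architecture", {
  sim <- simulate_patient(patient_preset("p13_like", seed = 41,
                                         n_snps = 200))
  expect_equal(length(sim$tumors), 16)
  expect_equal(as.integer(table(sim$truth$mechanisms)[c(
    "mutation_plus_cnloh", "none", "two_mutation")]), c(12L, 2L, 2L))
  expect_equal(length(sim$truth$truncal_partition), 1)
  expect_equal(sim$truth$truncal_partition[[1]], c("T01", "T02", "T03"))
  # germline variant present in every tumor's table
  for (tm in sim$tumors)
    expect_true(any(tm$variants$origin == "germline"))
  # the truncal trio shares one breakpoint; other CN-LOH breakpoints differ
  bp <- sim$truth$breakpoints
  expect_equal(length(unique(bp[1:3])), 1)
  expect_equal(anyDuplicated(na.omit(bp[-(1:3)])), 0)
  # sporadic two-hit preset: two somatic TSC2 variants, no LOH
  s2 <- simulate_patient(patient_preset("sporadic_two_hit", seed = 42,
                                        n_snps = 200))
  v <- s2$tumors[[1]]$variants
  expect_equal(sum(v$gene == "TSC2" & v$origin == "somatic"), 2)
  expect_equal(unname(s2$truth$mechanisms), "two_mutation")
  expect_false(any(s2$tumors[[1]]$track_truth$in_loh))
})

test_that("the nested-deletion preset is recovered by the coverage scan", {
  sim <- simulate_patient(patient_preset("homozygous_del", seed = 43,
                                         n_snps = 200))
  cov <- sim$tumors[[1]]$coverage
  dels <- detect_homozygous_deletion(cov)
  hom <- dels[dels$copy_status == "homozygous_loss", ]
  loss <- dels[dels$copy_status == "single_loss", ]
  expect_equal(nrow(hom), 1)
  expect_equal(nrow(loss), 1)
  # the 50 kb dip nests inside the 150 kb single-loss interval
  expect_true(hom$start >= loss$start && hom$end <= loss$end)
  expect_lt(abs((hom$end - hom$start) - 50e3), 2e4)
  expect_lt(abs((loss$end - loss$start) - 150e3), 3e4)
  res <- suppressWarnings(analyze_simulated_patient(sim))
  expect_equal(res$statuses$mechanism, "homozygous_deletion")
})

test_that("simulations round-trip through the file interface", {
  sim <- simulate_patient(patient_preset("sporadic_two_hit", seed = 44,
                                         n_snps = 150))
  dir <- file.path(tempdir(), "simexport")
  paths <- export_simulation(sim, dir)
  tr <- read_snp_track(paths$track_T01)
  expect_equal(nrow(tr), 150)
  expect_equal(tr$tumor_alt, sim$tumors[[1]]$track$tumor_alt)
  v <- read_variant_table(paths$variants)
  expect_equal(nrow(v), nrow(sim$variants))
  expect_equal(v$mutant_reads, sim$variants$mutant_reads)
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(unlist(truth$mechanisms), sim$truth$mechanisms)
})
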