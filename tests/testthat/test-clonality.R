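p13_t2 <- cohort$table2[cohort$table2$patient_id == "P13", ]

test_that("shared-mutation grouping recovers the truncal trio", {
  gr <- shared_mutation_groups(p13_t2)
  expect_equal(length(gr$groups), 1)
  expect_setequal(gr$groups[[1]]$samples, c("S20", "S23", "S24"))
  expect_setequal(gr$groups[[1]]$shared_mutations,
                  c("MAATS1 c.743G>A", "NCF1 c.568G>A"))
  expect_false(gr$groups[[1]]$conflict)
  # row order must not matter
  set.seed(2)
  gr2 <- shared_mutation_groups(p13_t2[sample(nrow(p13_t2)), ])
  expect_equal(lapply(gr2$groups, function(g) sort(g$samples)),
               lapply(gr$groups, function(g) sort(g$samples)))
})

test_that("a single shared mutation is a possible link, never a group", {
  calls <- rbind(
    make_call(sample_id = "A", gene = "G1", cdna_change = "c.1A>G"),
    make_call(sample_id = "B", gene = "G1", cdna_change = "c.1A>G"),
    make_call(sample_id = "B", gene = "G2", cdna_change = "c.9C>T"))
  gr <- shared_mutation_groups(calls)
  expect_equal(length(gr$groups), 0)
  expect_equal(nrow(gr$possible_links), 1)
  expect_setequal(c(gr$possible_links$sample_a, gr$possible_links$sample_b),
                  c("A", "B"))
  # no shared mutations at all -> singletons only
  solo <- shared_mutation_groups(calls[c(1, 3), ])
  expect_equal(length(solo$groups), 0)
  expect_equal(nrow(solo$possible_links), 0)
})

test_that("LOH boundary matching distinguishes same, different, indeterminate", {
  reg <- function(ce, ue, cs = 5e4, us = 5e4, start_cens = TRUE,
                  end_cens = FALSE)
    data.frame(chrom = "chr16", uncertain_start = us, confident_start = cs,
               confident_end = ce, uncertain_end = ue,
               telomere_anchored = start_cens, start_censored = start_cens,
               end_censored = end_cens)
  a <- reg(10e6, 10.4e6)
  expect_equal(loh_boundary_match(a, a), "same")
  # overlapping breakpoint-uncertainty intervals
  expect_equal(loh_boundary_match(a, reg(10.2e6, 10.6e6)), "same")
  # 10 Mb apart with tight flanks
  expect_equal(loh_boundary_match(a, reg(20e6, 20.3e6)), "different")
  # censored end flank cannot be judged
  expect_equal(loh_boundary_match(a, reg(12e6, 36e6, end_cens = TRUE)),
               "indeterminate")
  expect_error(
    loh_boundary_match(a, transform(a, chrom = "chr9")), "chromosome")
})

test_that("boundary matching calls same-breakpoint regions same under noise", {
  set.seed(77)
  n_same <- 0; n_runs <- 50
  for (i in seq_len(n_runs)) {
    regs <- lapply(1:2, function(j) {
      sim <- simulate_snp_track(simulation_config(
        seed = NULL, purity = 0.5, mean_depth = 80,
        cnloh_breakpoint = 10e6))
      ana <- analyze_tumor_track(sim$track, 2.1e6)
      ana$regions[ana$locus_region, , drop = FALSE]
    })
    if (loh_boundary_match(regs[[1]], regs[[2]]) == "same")
      n_same <- n_same + 1
  }
  expect_gte(n_same / n_runs, 0.9)
})

test_that("the P13 clone tree reproduces the published classes", {
  rep <- run_pipeline()
  tree <- rep$trees[["P13"]]
  expect_equal(length(tree$groups), 1)
  expect_setequal(tree$groups[[1]]$samples, c("S20", "S23", "S24"))
  cl <- tree$classes
  expect_true(all(cl[c("S20", "S23", "S24")] == "definite_shared"))
  expect_true(all(cl[c("S14", "S15", "S17", "S18", "S19")] ==
                    "possible_shared"))
  # unique LOH regions and unique TSC2 second hits
  expect_true(all(cl[c("S21", "S25", "S29", "S26", "S27")] ==
                    "independent"))
  expect_gte(sum(cl == "independent"), 5)
  expect_true(all(cl[c("S16", "S28", "S22")] == "unresolved"))
  # every sample in exactly one leaf
  expect_setequal(names(cl), sprintf("S%d", 14:29))
  # the P1 LAM pair is definitely clonal
  expect_true(all(rep$trees[["P1"]]$classes == "definite_shared"))
})

test_that("mutation groups outrank LOH evidence and conflicts are flagged", {
  st <- data.frame(sample_id = c("A", "B"), locus = "TSC2",
                   mechanism = "mutation_plus_cnloh", biallelic = TRUE,
                   n_hits = 1, loh = TRUE, stringsAsFactors = FALSE)
  gr <- list(groups = list(list(samples = c("A", "B"),
                                shared_mutations = c("G1 c.1A>G",
                                                     "G2 c.9C>T"),
                                conflict = FALSE)),
             possible_links = data.frame())
  # members sit in two non-matching LOH groups -> conflict flag + warning
  expect_warning(
    tree <- build_clone_tree("PX", st, gr,
                             loh_groups = list("A", "B")),
    "conflict")
  expect_true(tree$groups[[1]]$conflict)
  # the mutation evidence still wins the class
  expect_true(all(tree$classes == "definite_shared"))
})

test_that("newick export round-trips through ape", {
  rep <- run_pipeline()
  ex <- export_tree(rep$trees[["P13"]])
  phy <- ape::read.tree(text = ex$newick)
  expect_equal(sort(phy$tip.label), sprintf("S%d", 14:29))
  expect_equal(phy$Nnode, 2)  # root + one truncal node
  expect_true(grepl("shared2", ex$newick))
  js <- jsonlite::fromJSON(ex$json)
  expect_equal(js$patient_id, "P13")
  expect_setequal(unlist(js$groups$samples), c("S20", "S23", "S24"))
  # single-sample patient: trivial one-leaf tree
  st <- data.frame(sample_id = "A", locus = "TSC2",
                   mechanism = "two_mutation", biallelic = TRUE,
                   n_hits = 2, loh = FALSE, stringsAsFactors = FALSE)
  t1 <- build_clone_tree("PY", st, list(groups = list(),
                                        possible_links = data.frame()))
  e1 <- export_tree(t1)
  expect_equal(length(ape::read.tree(text = e1$newick)$tip.label), 1)
  # empty patient is an error
  t0 <- t1; t0$samples <- character(0)
  expect_error(export_tree(t0), "empty")
  expect_error(build_clone_tree("PZ", st[0, ], list(groups = list())),
               "no samples")
})

test_that("simulated truncal partitions are recovered", {
  ok <- 0; n_runs <- 10
  for (s in seq_len(n_runs)) {
    cfgp <- patient_preset("p13_like", seed = 300 + s)
    cfgp$n_tumors <- 6L
    cfgp$second_hit <- c("cnloh", "cnloh", "cnloh", "cnloh",
                         "point_mutation", "none")
    cfgp$breakpoints <- c(8e6, 8e6, 15e6, 25e6, NA, NA)
    cfgp$truncal_groups <- list(list(members = 1:2, n_shared = 2))
    sim <- simulate_patient(cfgp)
    res <- suppressWarnings(analyze_simulated_patient(sim))
    got <- lapply(res$tree$groups, function(g) sort(g$samples))
    want <- lapply(sim$truth$truncal_partition, sort)
    if (identical(got, want)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
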