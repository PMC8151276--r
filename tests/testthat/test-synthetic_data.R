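test_that("interaction generator does the count bookkeeping and is deterministic", {
  cfg <- synthetic_chem_config(n_families = 2, compounds_per_family = 10,
                               promiscuous_fraction = 0, duplicate_rate = 0,
                               nonhuman_rate = 0, seed = 11)
  tab <- generate_interaction_table(cfg)
  expect_equal(nrow(tab), 20)
  expect_setequal(unique(tab$family), c("FAM01", "FAM02"))
  expect_false(any(is.na(canonical_smiles(tab$smiles))))
  expect_identical(tab, generate_interaction_table(cfg))

  # artifact knobs add records on top of the base table
  cfg2 <- synthetic_chem_config(n_families = 2, compounds_per_family = 10,
                                promiscuous_fraction = 0.2, duplicate_rate = 0.1,
                                nonhuman_rate = 0.1, seed = 11)
  tab2 <- generate_interaction_table(cfg2)
  base <- 20; prom <- floor(0.2 * base)
  dup <- round(0.1 * (base + prom))
  nh <- round(0.1 * (base + prom + dup))
  expect_equal(nrow(tab2), base + prom + dup + nh)
  expect_equal(sum(tab2$species != "human"), nh)
})

test_that("generator rejects invalid configurations", {
  expect_error(synthetic_chem_config(n_families = 1),
               class = "gpcrtracer_config_error")
  expect_error(synthetic_chem_config(promiscuous_fraction = 1.2),
               class = "gpcrtracer_config_error")
  expect_error(synthetic_chem_config(n_families = 2, compounds_per_family = 1e6),
               class = "gpcrtracer_config_error")
  expect_error(synthetic_bret_config(concentrations = c(10, 5)),
               class = "gpcrtracer_config_error")
  expect_error(synthetic_bret_config(noise_sd = -1),
               class = "gpcrtracer_config_error")
})

test_that("within-family similarity exceeds between-family similarity (brute force)", {
  cfg <- synthetic_chem_config(n_families = 4, compounds_per_family = 50,
                               promiscuous_fraction = 0, duplicate_rate = 0,
                               nonhuman_rate = 0, seed = 23)
  tab <- generate_interaction_table(cfg)
  fp <- fingerprint_matrix(tab$smiles, tab$compound_id)
  maccs <- fp[, fp_blocks()$maccs]
  n <- nrow(maccs)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- naive_tanimoto(maccs[i, ], maccs[j, ])
      if (tab$family[i] == tab$family[j]) within <- c(within, s)
      else between <- c(between, s)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("noise-free plates hit the stated BRET values exactly", {
  cfg <- synthetic_bret_config(true_fold_response = 2.0, background_bret = 0.1,
                               noise_sd = 0, n_replicates = 2,
                               concentrations = c(100, 1000), seed = 1)
  truth <- data.frame(construct = c("B", "U"), tracer = "T",
                      bound = c(TRUE, FALSE))
  plate <- generate_bret_plate(cfg, truth)
  bret <- plate$acceptor_em / plate$donor_em
  bound_alone <- bret[plate$construct == "B" & plate$condition == "tracer_alone"]
  bound_ctrl <- bret[plate$construct == "B" &
                       plate$condition == "tracer_plus_competitor"]
  expect_equal(unique(bound_alone), 0.2)
  expect_equal(unique(bound_ctrl), 0.1)
  unbound <- bret[plate$construct == "U"]
  expect_equal(unique(unbound), 0.1)
})

test_that("empirical fold response matches truth within Monte-Carlo error", {
  cfg <- synthetic_bret_config(true_fold_response = 2.0, background_bret = 0.1,
                               noise_sd = 0.005, n_replicates = 100,
                               concentrations = 1000, seed = 42)
  truth <- data.frame(construct = c("B", "U"), tracer = "T",
                      bound = c(TRUE, FALSE))
  plate <- generate_bret_plate(cfg, truth)
  bret <- plate$acceptor_em / plate$donor_em
  for (cons in c("B", "U")) {
    alone <- bret[plate$construct == cons & plate$condition == "tracer_alone"]
    ctrl <- bret[plate$construct == cons &
                   plate$condition == "tracer_plus_competitor"]
    emp <- mean(alone) / mean(ctrl)
    tru <- if (cons == "B") 2.0 else 1.0
    # delta-method SE of the ratio of two means of 100 wells
    se <- tru * sqrt(sd(alone)^2 / (mean(alone)^2) +
                     sd(ctrl)^2 / (mean(ctrl)^2)) / sqrt(100)
    expect_lt(abs(emp - tru), 3 * se)
  }
})

test_that("saturation series obeys half-saturation and asymptote identities", {
  cfg <- synthetic_bret_config(noise_sd = 0, bmax = 0.2, ec50 = 50,
                               background_bret = 0.1, n_replicates = 1,
                               concentrations = c(25, 50, 100, 1e7), seed = 1)
  ser <- generate_saturation_series(cfg)
  bret <- ser$acceptor_em / ser$donor_em
  spec <- function(cc) {
    bret[ser$concentration_nM == cc & ser$condition == "tracer_alone"] -
      bret[ser$concentration_nM == cc & ser$condition == "tracer_plus_competitor"]
  }
  expect_equal(spec(50), 0.1)            # bmax/2 at c = ec50
  expect_equal(spec(1e7), 0.2, tolerance = 1e-4)  # approaches bmax
  expect_identical(ser, generate_saturation_series(cfg))
})
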