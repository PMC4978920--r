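test_that("noiseless null screens sit exactly at their baselines", {
  cfg <- sim_config(n_genes = 30, noise_cv = 0, plate_effect_sd = 0,
                    fraction_regulators = c(joint_positive = 0),
                    include_tp53_gene = FALSE, n_plates = 2, seed = 1)
  sim <- simulate_screen(cfg)
  lib <- sim$matrix$role == "library"
  for (j in seq_along(CONDS)) {
    expect_true(all(sim$matrix$values[lib, j] == cfg$baseline[CONDS[j]]))
  }
  expect_true(all(sim$truth$category == "null"))
})

test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(n_genes = 40, n_plates = 2, emit_ct = TRUE, seed = 99)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth$effect, s2$truth$effect)
  expect_identical(s1$ct$ct, s2$ct$ct)
  s3 <- simulate_screen(sim_config(n_genes = 40, n_plates = 2, seed = 100))
  expect_false(identical(s1$matrix$values, s3$matrix$values))
})

test_that("technical noise has the configured coefficient of variation", {
  cfg <- sim_config(n_genes = 589, noise_cv = 0.15, plate_effect_sd = 0,
                    fraction_regulators = c(joint_positive = 0),
                    include_tp53_gene = FALSE, seed = 12)
  sim <- simulate_screen(cfg)
  lib <- sim$matrix$role == "library"
  for (j in 1:6) {
    v <- sim$matrix$values[lib, j]
    cv_emp <- sd(v) / mean(v)
    expect_lt(abs(cv_emp - 0.15) / 0.15, 0.2)  # 20% relative error at n = 589
  }
})

test_that("control wells carry their designed biology", {
  cfg <- sim_config(n_genes = 30, noise_cv = 0, plate_effect_sd = 0,
                    fraction_regulators = c(joint_positive = 0),
                    include_tp53_gene = FALSE, n_plates = 2, seed = 3)
  sim <- simulate_screen(cfg)
  m <- sim$matrix
  nt <- m$values[m$role == "nontargeting_control", , drop = FALSE]
  tp <- m$values[m$role == "tp53_control", , drop = FALSE]
  md <- m$values[m$role == "mdm2_control", , drop = FALSE]
  base <- matrix(cfg$baseline, nrow(nt), 6, byrow = TRUE)
  # nontargeting: indistinguishable from the library baseline
  expect_equal(unname(nt), unname(base))
  # TP53 control: strong knockdown of all readouts in both treatments
  expect_equal(unname(tp), unname(base * 2^(-2 * cfg$effect_log2)))
  # MDM2 control: raises basal CDKN1A and BBC3 only, TP53 untouched
  expect_equal(unname(md[, c(1, 3)]),
               unname(base[, c(1, 3)] * 2^cfg$effect_log2))
  expect_equal(unname(md[, c(2, 4, 5, 6)]), unname(base[, c(2, 4, 5, 6)]))
})

test_that("every plate carries all three control roles alongside the library", {
  sim <- simulate_screen(sim_config(n_genes = 60, n_plates = 3, seed = 8))
  m <- sim$matrix
  for (pl in unique(m$plate)) {
    roles <- m$role[m$plate == pl]
    expect_true(all(c("library", "nontargeting_control", "tp53_control",
                      "mdm2_control") %in% roles))
  }
})

test_that("secondary rescreen covers the requested pool and removed effects vanish", {
  sim <- simulate_screen(sim_config(n_genes = 100, noise_cv = 0.02,
                                    plate_effect_sd = 0, seed = 41))
  # full-library rescreen
  full <- simulate_secondary(sim$truth, subset_size = 100, seed = 2)
  expect_setequal(full$genes, sim$truth$genes)
  expect_true(all(is.na(full$values[, c(2, 4, 5, 6)])))
  expect_true(all(!is.na(full$values[, c(1, 3)])))
  expect_error(simulate_secondary(sim$truth, subset_size = 101), "exceeds")

  # a joint regulator whose effect is dropped in the rescreen is not confirmed
  jp <- sim$truth$genes[sim$truth$category == "joint_positive"][1]
  zt <- compute_zscores(sim$matrix)
  cl <- classify_regulators(call_hits(zt), genes = sim$truth$genes)
  sec <- simulate_secondary(sim$truth, subset_size = 100, seed = 2,
                            drop_effect_genes = jp)
  out <- validate_secondary(cl, sec)
  tab <- out$table
  expect_equal(unique(tab$secondary_status[tab$gene == jp]), "not_confirmed")
  # with effects preserved and low noise, >= 90% of retested CDKN1A/BBC3
  # regulators confirm at the relaxed 1-SD cut-off
  out2 <- validate_secondary(cl, simulate_secondary(sim$truth,
                                                    subset_size = 100, seed = 3))
  st <- out2$table$secondary_status[out2$table$category %in%
                                      c("joint", "CDKN1A_specific", "BBC3_specific")]
  expect_gte(mean(st == "confirmed"), 0.9)
})

test_that("recovery scoring agrees with direct set arithmetic on small screens", {
  for (seed in c(5, 15)) {
    sim <- simulate_screen(sim_config(n_genes = 20, n_plates = 2,
                                      fraction_regulators = c(
                                        joint_positive = 0.1, joint_negative = 0.1,
                                        CDKN1A_specific = 0.1),
                                      noise_cv = 0.05, seed = seed))
    zt <- compute_zscores(sim$matrix)
    cl <- classify_regulators(call_hits(zt), genes = sim$truth$genes)
    rec <- score_recovery(sim$truth, cl)
    planted <- sim$truth$genes[sim$truth$category != "null"]
    called <- intersect(unique(cl$table$gene), sim$truth$genes)
    tp <- length(intersect(called, planted))
    expect_equal(rec$recall, tp / length(planted))
    expect_equal(rec$precision, tp / length(called))
    expect_equal(sum(rec$per_category$n), length(planted))
  }
})

test_that("degenerate classifications are scored as missing, not crashes", {
  sim <- simulate_screen(sim_config(n_genes = 20, n_plates = 2, seed = 2))
  empty_z <- compute_zscores(sim$matrix)
  no_hits <- call_hits(empty_z, threshold = 50)
  cl <- classify_regulators(no_hits, genes = sim$truth$genes)
  rec <- score_recovery(sim$truth, cl)
  expect_equal(rec$recall, 0)
  expect_true(is.na(rec$precision))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fraction_regulators = c(joint_positive = 0.9,
                                                  joint_negative = 0.2)),
               "invalid regulator fractions")
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(noise_cv = -0.1), "negative noise")
})
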