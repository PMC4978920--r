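test_that("z-scores match the closed form and standardize each condition", {
  # two values {0, 2}: sample SD sqrt(2), z = -/+ 1/sqrt(2)
  vals <- matrix(rep(c(0, 2), 6), 2, 6, dimnames = list(NULL, CONDS))
  sm <- screen_matrix(vals, genes = c("A", "B"))
  zt <- compute_zscores(sm)
  expect_equal(unname(zt$z[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(zt$theta[1]), sqrt(2))

  # property: 200 random lognormal values per condition -> mean 0, SD 1
  sm <- random_screen(n = 200, seed = 11)
  zt <- compute_zscores(sm)
  expect_equal(unname(colMeans(zt$z)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(zt$z, 2, sd)), rep(1, 6), tolerance = 1e-9)
})

test_that("degenerate and undersized conditions raise errors", {
  vals <- matrix(1, 5, 6, dimnames = list(NULL, CONDS))
  sm <- screen_matrix(vals, genes = sprintf("G%d", 1:5))
  expect_error(compute_zscores(sm), "degenerate condition.*CDKN1A.DMSO")

  vals2 <- matrix(rlnorm(12), 2, 6, dimnames = list(NULL, CONDS))
  vals2[2, 1] <- NA
  sm2 <- screen_matrix(vals2, genes = c("A", "B"))
  expect_error(compute_zscores(sm2), "fewer than 2")
})

test_that("control wells are excluded from mu/theta but still scored", {
  sm <- random_screen(n = 30, seed = 2)
  sm$role[1:5] <- "tp53_control"
  zt <- compute_zscores(sm)
  expect_equal(unname(zt$n_used), rep(25, 6))
  # library parameters come from library rows only
  lib_vals <- sm$values[sm$role == "library", 1]
  expect_equal(unname(zt$mu[1]), mean(lib_vals))
  expect_equal(unname(zt$theta[1]), sd(lib_vals))
  # controls are scored against those parameters
  expect_equal(zt$z[1, 1], (sm$values[1, 1] - mean(lib_vals)) / sd(lib_vals))
  # include_controls switches the convention
  zt_all <- compute_zscores(sm, include_controls = TRUE)
  expect_equal(unname(zt_all$n_used), rep(30, 6))
  expect_equal(unname(zt_all$mu[1]), mean(sm$values[, 1]))
})

test_that("hit calling is strict at the boundary and direction follows sign", {
  z <- matrix(0, 3, 6)
  z[1, 1] <- 2.0    # exactly on the window edge: not a hit
  z[2, 2] <- -2.5   # below: knockdown reduced expression -> positive regulator
  z[3, 3] <- 2.0001
  zt <- ztable_from_z(z, genes = c("EDGE", "POS", "JUST"))
  hits <- call_hits(zt, threshold = 2)
  expect_false("EDGE" %in% hits$gene)
  expect_true("JUST" %in% hits$gene)
  expect_equal(hits$direction[hits$gene == "POS"], "positive_regulator")
  expect_equal(hits$condition[hits$gene == "POS"], "CDKN1A.etoposide")
})

test_that("hit calls are affine-invariant and monotone in the threshold", {
  sm <- random_screen(n = 50, seed = 13)
  base_hits <- call_hits(compute_zscores(sm))
  # positive affine rescaling of a column leaves z (hence hits) unchanged;
  # shift chosen to keep values non-negative
  sm2 <- sm
  sm2$values[, 4] <- 3.7 * sm2$values[, 4] + 1.2
  hits2 <- call_hits(compute_zscores(sm2))
  key <- function(h) sort(paste(h$gene, h$condition))
  expect_identical(key(hits2), key(base_hits))

  # monotonicity: every hit at tau = 2.5 is a hit at tau = 2
  zt <- compute_zscores(sm)
  strict <- call_hits(zt, threshold = 2.5)
  loose <- call_hits(zt, threshold = 2)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("hit calls agree with a brute-force enumeration on small screens", {
  for (seed in 1:5) {
    sm <- random_screen(n = 20, seed = seed, cv = 0.5)
    zt <- compute_zscores(sm)
    hits <- call_hits(zt, threshold = 1.5)
    # independent direct enumeration over all (gene, condition) pairs
    expected <- character(0)
    for (i in 1:20) for (j in 1:6) {
      mu <- mean(sm$values[, j]); th <- sd(sm$values[, j])
      zij <- (sm$values[i, j] - mu) / th
      if (abs(zij) > 1.5) expected <- c(expected, paste(sm$genes[i], CONDS[j]))
    }
    expect_setequal(paste(hits$gene, hits$condition), expected)
  }
})

test_that("classification reproduces joint, specific and dual-label profiles", {
  z <- matrix(0, 5, 6)
  # SETD3-like: joint positive regulator, DMSO only
  z[1, c(1, 3)] <- c(-2.6, -2.2)
  # CDKN1A-specific negative regulator under etoposide only
  z[2, 2] <- 2.3
  # PLK1-like: joint + TP53 hit in the same treatment (dual label allowed)
  z[3, c(2, 4, 6)] <- c(-2.8, -2.4, -2.9)
  # opposite directions on CDKN1A and BBC3: neither joint nor specific
  # (the partner readout IS a hit in that treatment, just oppositely)
  z[4, c(1, 3)] <- c(-2.5, 2.5)
  # gene 5: no hits anywhere
  zt <- ztable_from_z(z, genes = c("SETD3L", "NEGREG", "PLK1L", "MIXED", "QUIET"))
  cl <- classify_regulators(call_hits(zt))
  tab <- cl$table

  s <- tab[tab$gene == "SETD3L", ]
  expect_equal(s$category, "joint")
  expect_equal(s$direction, "positive_regulator")
  expect_equal(s$treatment, "DMSO")
  expect_equal(s$z, -2.6)  # strongest contributing readout

  n <- tab[tab$gene == "NEGREG", ]
  expect_equal(n$category, "CDKN1A_specific")
  expect_equal(n$direction, "negative_regulator")
  expect_equal(n$treatment, "etoposide")

  p <- tab[tab$gene == "PLK1L", ]
  expect_setequal(p$category, c("joint", "TP53_specific"))

  expect_false("MIXED" %in% tab$gene)

  expect_false("QUIET" %in% tab$gene)
})

test_that("joint status in one treatment suppresses specific labels in the other", {
  z <- matrix(0, 2, 6)
  z[1, c(1, 3)] <- c(-2.6, -2.2)  # joint in DMSO
  z[1, 2] <- -2.4                 # CDKN1A-only hit under etoposide
  zt <- ztable_from_z(z, genes = c("G1", "G2"))
  tab <- classify_regulators(call_hits(zt))$table
  g1 <- tab[tab$gene == "G1", ]
  expect_true("joint" %in% g1$category)
  expect_false("CDKN1A_specific" %in% g1$category)
})

test_that("zero-noise synthetic screen is classified exactly as planted", {
  cfg <- sim_config(n_genes = 200, noise_cv = 0, plate_effect_sd = 0,
                    n_plates = 2, seed = 21)
  sim <- simulate_screen(cfg)
  zt <- compute_zscores(sim$matrix)
  cl <- classify_regulators(call_hits(zt), genes = sim$truth$genes)
  tab <- cl$table
  tr <- sim$truth
  for (i in seq_along(tr$genes)) {
    g <- tr$genes[i]
    rows <- tab[tab$gene == g, ]
    planted <- tr$category[i]
    if (planted == "null") {
      expect_equal(nrow(rows), 0)
    } else if (planted %in% c("joint_positive", "joint_negative")) {
      expect_true("joint" %in% rows$category)
      want <- if (planted == "joint_positive") "positive_regulator" else "negative_regulator"
      expect_true(all(rows$direction[rows$category == "joint"] == want))
    } else if (planted == "tp53_library") {
      expect_setequal(unique(rows$category), c("joint", "TP53_specific"))
    } else {
      expect_true(planted %in% rows$category)
    }
  }
  rec <- score_recovery(tr, cl)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})

test_that("secondary validation confirms, rejects and skips as designed", {
  # primary: three CDKN1A/BBC3 regulators
  z <- matrix(0, 3, 6)
  z[1, c(1, 3)] <- c(-3, -2.5)  # joint positive
  z[2, 1] <- 2.6                # CDKN1A-specific negative
  z[3, 3] <- -2.7               # BBC3-specific positive
  zt <- ztable_from_z(z, genes = c("JP", "CN", "BP"))
  cl <- classify_regulators(call_hits(zt))

  # secondary pool: JP reproduces, CN flat (z = 0), BP absent
  vals <- matrix(NA_real_, 12, 6, dimnames = list(NULL, CONDS))
  set.seed(4)
  vals[, "CDKN1A.DMSO"] <- rlnorm(12, 0, 0.1)
  vals[, "BBC3.DMSO"] <- rlnorm(12, 0, 0.1)
  vals[1, c("CDKN1A.DMSO", "BBC3.DMSO")] <- 0.2   # strong knockdown persists
  vals[2, "CDKN1A.DMSO"] <- 1.0                   # sits at the pool centre
  sec <- screen_matrix(vals, genes = c("JP", "CN", sprintf("X%02d", 1:10)))
  out <- validate_secondary(cl, sec)
  tab <- out$table
  expect_equal(tab$secondary_status[tab$gene == "JP"], "confirmed")
  expect_equal(tab$secondary_status[tab$gene == "CN"], "not_confirmed")
  expect_equal(tab$secondary_status[tab$gene == "BP"], "not_retested")
  # TP53-specific rows are never retested by a CDKN1A/BBC3 rescreen
  z2 <- matrix(0, 2, 6); z2[1, 5] <- -2.5
  cl2 <- classify_regulators(call_hits(ztable_from_z(z2, genes = c("T1", "T2"))))
  out2 <- validate_secondary(cl2, sec)
  expect_equal(out2$table$secondary_status, "not_retested")
})

test_that("direction agreement is required by default but can be relaxed", {
  z <- matrix(0, 1, 6)
  z[1, 1] <- -2.6  # primary: positive regulator of CDKN1A
  cl <- classify_regulators(call_hits(ztable_from_z(z, genes = "FLIP")))
  # secondary: same gene goes UP strongly instead
  vals <- matrix(NA_real_, 10, 6, dimnames = list(NULL, CONDS))
  set.seed(8)
  vals[, "CDKN1A.DMSO"] <- rlnorm(10, 0, 0.1)
  vals[, "BBC3.DMSO"] <- rlnorm(10, 0, 0.1)
  vals[1, "CDKN1A.DMSO"] <- 5
  sec <- screen_matrix(vals, genes = c("FLIP", sprintf("X%02d", 1:9)))
  strict <- validate_secondary(cl, sec)
  expect_equal(strict$table$secondary_status, "not_confirmed")
  loose <- validate_secondary(cl, sec, require_direction = FALSE)
  expect_equal(loose$table$secondary_status, "confirmed")
})

test_that("expression of exactly zero flags a putative false positive", {
  z <- matrix(0, 3, 6)
  z[1, 1] <- -2.5; z[2, 3] <- 2.5; z[3, 5] <- -2.5
  cl <- classify_regulators(call_hits(
    ztable_from_z(z, genes = c("MBD3L1L", "Dlx2l", "KEPT"))))
  expr <- data.frame(gene = c("MBD3L1L", "DLX2L"), value = c(0, 0))
  out <- flag_low_expression(cl, expr)
  tab <- out$table
  expect_true(tab$low_expression_flag[tab$gene == "MBD3L1L"])
  # join is case-insensitive
  expect_true(tab$low_expression_flag[tab$gene == "Dlx2l"])
  expect_false(tab$low_expression_flag[tab$gene == "KEPT"])
  expect_equal(attr(tab, "unmatched"), "KEPT")
  # a secondary-confirmed gene keeps its expression flag (flags are independent)
  out$table$secondary_status[out$table$gene == "Dlx2l"] <- "confirmed"
  expect_true(out$table$low_expression_flag[out$table$gene == "Dlx2l"])
  # nonzero expression never flags
  out2 <- flag_low_expression(cl, c(KEPT = 3.7))
  expect_false(any(out2$table$low_expression_flag))
})
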