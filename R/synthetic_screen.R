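#' Synthetic screen configuration
#'
#' Parameters of the seeded screen simulator. The defaults emulate the study
#' conditions of a chromatin-focused arrayed siRNA screen: a 589-gene
#' library (including TP53 itself) plated with nontargeting, TP53 and MDM2
#' control siRNAs on every plate, three p53 target readouts under DMSO and
#' etoposide, planted knockdown effects of 1.5 log2 units, multiplicative
#' lognormal technical noise with 15% coefficient of variation, and mild
#' per-plate multiplicative offsets.
#'
#' @param n_genes Library size (default 589; must be >= 10).
#' @param fraction_regulators Named fractions of library genes planted per
#'   regulator category (`joint_positive`, `joint_negative`,
#'   `CDKN1A_specific`, `BBC3_specific`, `TP53_specific`); must sum to <= 1.
#' @param effect_log2 Magnitude of planted log2 fold-changes (default 1.5).
#' @param condition_of_effect `"DMSO"`, `"etoposide"`, or `"both"` (default):
#'   treatment(s) in which planted effects act.
#' @param baseline Named numeric vector of mean normalized expression per
#'   condition. Defaults encode etoposide induction of the p53 targets
#'   CDKN1A and BBC3 with near-flat TP53 mRNA.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (default 0.15).
#' @param plate_effect_sd SD of the per-plate multiplicative log-offset
#'   (default 0.05).
#' @param n_plates Number of plates the library is distributed over
#'   (default 8).
#' @param controls_per_plate Named counts of control wells per role per plate
#'   (default one of each).
#' @param include_tp53_gene Include TP53 as the first library gene with a
#'   strong self-knockdown effect on all readouts (default `TRUE`),
#'   mirroring a library that contains its own pathway master regulator.
#' @param emit_ct Also emit raw Ct triplicates through planted standard
#'   curves (default `FALSE`).
#' @param ct_noise_sd SD of Ct measurement noise in cycles when `emit_ct`
#'   (default 0.1).
#' @param toxic_fraction Fraction of library genes whose knockdown kills the
#'   well (no reference signal; exercises the missing-value path; default 0).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 589,
                       fraction_regulators = c(joint_positive = 0.015,
                                               joint_negative = 0.015,
                                               CDKN1A_specific = 0.015,
                                               BBC3_specific = 0.015,
                                               TP53_specific = 0.015),
                       effect_log2 = 1.5,
                       condition_of_effect = c("both", "DMSO", "etoposide"),
                       baseline = c(CDKN1A.DMSO = 1.0, CDKN1A.etoposide = 3.0,
                                    BBC3.DMSO = 0.5, BBC3.etoposide = 1.5,
                                    TP53.DMSO = 1.0, TP53.etoposide = 1.2),
                       noise_cv = 0.15, plate_effect_sd = 0.05, n_plates = 8,
                       controls_per_plate = c(nontargeting_control = 1,
                                              tp53_control = 1,
                                              mdm2_control = 1),
                       include_tp53_gene = TRUE,
                       emit_ct = FALSE, ct_noise_sd = 0.1,
                       toxic_fraction = 0, seed = 1L) {
  condition_of_effect <- match.arg(condition_of_effect)
  cats <- c("joint_positive", "joint_negative", "CDKN1A_specific",
            "BBC3_specific", "TP53_specific")
  fr <- stats::setNames(rep(0, length(cats)), cats)
  fr[names(fraction_regulators)] <- fraction_regulators
  if (any(fr < 0) || sum(fr) > 1) stop("config error: invalid regulator fractions")
  if (n_genes < 10) stop("config error: n_genes must be >= 10")
  if (noise_cv < 0 || plate_effect_sd < 0 || ct_noise_sd < 0) {
    stop("config error: negative noise parameter")
  }
  stopifnot(identical(sort(names(baseline)), sort(CONDITIONS)))
  structure(list(n_genes = n_genes, fraction_regulators = fr,
                 effect_log2 = effect_log2,
                 condition_of_effect = condition_of_effect,
                 baseline = baseline[CONDITIONS], noise_cv = noise_cv,
                 plate_effect_sd = plate_effect_sd, n_plates = n_plates,
                 controls_per_plate = controls_per_plate,
                 include_tp53_gene = include_tp53_gene,
                 emit_ct = emit_ct, ct_noise_sd = ct_noise_sd,
                 toxic_fraction = toxic_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# lognormal multiplier with unit mean and the requested CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# columns of the effect matrix touched by each category
effect_columns <- function(category, condition_of_effect) {
  treatments <- if (condition_of_effect == "both") TREATMENTS else condition_of_effect
  readouts <- switch(category,
                     joint_positive = , joint_negative = c("CDKN1A", "BBC3"),
                     CDKN1A_specific = "CDKN1A",
                     BBC3_specific = "BBC3",
                     TP53_specific = "TP53")
  as.vector(outer(readouts, treatments, condition_label))
}

#' Simulate a screen with planted regulator effects
#'
#' Generates a full synthetic screen: library genes (a seeded subset planted
#' as regulators), per-plate control wells, and expression values
#' `baseline * 2^effect * plate_factor * lognormal_noise`. Control wells
#' behave as their biology dictates: nontargeting controls carry no effect;
#' TP53 controls strongly reduce all three readouts in both treatments
#' (twice `effect_log2`); MDM2 controls raise basal (DMSO) CDKN1A and BBC3
#' but leave TP53 mRNA untouched. With `emit_ct`, raw Ct triplicates are
#' additionally generated by inverting planted standard curves (including a
#' 5-point 4-fold dilution series per readout with `role = "standard"`), so
#' the quantification stage can be exercised end-to-end.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (a [screen_matrix()] including control
#'   wells), `truth` (a `simulation_truth` holding the planted categories,
#'   directions, per-condition log2 effects, plate factors, and the standard
#'   curves when `emit_ct`), and `ct` (a `ct_records` data frame, or `NULL`).
#' @examples
#' sim <- simulate_screen(sim_config(n_genes = 50, n_plates = 2, seed = 7))
#' table(sim$truth$category)
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("GENE%04d", seq_len(n))
  category <- rep("null", n)
  direction <- rep(0, n)  # sign of the planted log2 effect
  if (config$include_tp53_gene) {
    genes[1] <- "TP53"
    category[1] <- "tp53_library"
  }
  assignable <- which(category == "null")
  for (cat_name in names(config$fraction_regulators)) {
    k <- round(config$fraction_regulators[[cat_name]] * n)
    if (k == 0) next
    pick <- sample(assignable, k)
    category[pick] <- cat_name
    assignable <- setdiff(assignable, pick)
  }
  direction[category == "joint_positive"] <- -1
  direction[category == "joint_negative"] <- +1
  for (cat_name in c("CDKN1A_specific", "BBC3_specific", "TP53_specific")) {
    idx <- which(category == cat_name)
    if (length(idx)) direction[idx] <- sample(c(-1, 1), length(idx), replace = TRUE)
  }
  direction[category == "tp53_library"] <- -1

  effect <- matrix(0, n, length(CONDITIONS), dimnames = list(NULL, CONDITIONS))
  for (i in which(category != "null")) {
    if (category[i] == "tp53_library") {
      effect[i, ] <- -2 * config$effect_log2
    } else {
      cols <- effect_columns(category[i], config$condition_of_effect)
      effect[i, cols] <- direction[i] * config$effect_log2
    }
  }

  toxic <- rep(FALSE, n)
  if (config$toxic_fraction > 0) {
    k <- round(config$toxic_fraction * n)
    toxic[sample.int(n, k)] <- TRUE
  }

  # plate layout: library round-robin, then control wells appended per plate
  plates <- sprintf("P%02d", seq_len(config$n_plates))
  plate <- plates[((seq_len(n) - 1L) %% config$n_plates) + 1L]
  ctrl <- list()
  for (pl in plates) {
    for (role in names(config$controls_per_plate)) {
      k <- config$controls_per_plate[[role]]
      if (k < 1) next
      stem <- switch(role, nontargeting_control = "NT_ctrl",
                     tp53_control = "TP53_ctrl", mdm2_control = "MDM2_ctrl")
      ctrl[[length(ctrl) + 1L]] <- data.frame(
        gene = sprintf("%s_%s_%d", stem, pl, seq_len(k)),
        role = role, plate = pl, stringsAsFactors = FALSE
      )
    }
  }
  ctrl <- do.call(rbind, ctrl)
  ctrl_effect <- matrix(0, nrow(ctrl), length(CONDITIONS),
                        dimnames = list(NULL, CONDITIONS))
  ctrl_effect[ctrl$role == "tp53_control", ] <- -2 * config$effect_log2
  mdm2_cols <- c("CDKN1A.DMSO", "BBC3.DMSO")
  ctrl_effect[ctrl$role == "mdm2_control", mdm2_cols] <- config$effect_log2

  all_genes <- c(genes, ctrl$gene)
  all_role <- c(rep("library", n), ctrl$role)
  all_plate <- c(plate, ctrl$plate)
  all_effect <- rbind(effect, ctrl_effect)
  n_all <- length(all_genes)

  plate_factor <- stats::setNames(exp(stats::rnorm(config$n_plates, 0,
                                                   config$plate_effect_sd)),
                                  plates)
  values <- matrix(rep(config$baseline, each = n_all), n_all,
                   length(CONDITIONS), dimnames = list(NULL, CONDITIONS))
  values <- values * 2^all_effect * plate_factor[all_plate] *
    matrix(lognormal_noise(n_all * length(CONDITIONS), config$noise_cv),
           n_all, length(CONDITIONS))
  values[c(toxic, rep(FALSE, nrow(ctrl))), ] <- NA_real_

  wells <- sprintf("%s%02d", LETTERS[rep(1:8, each = 12)], rep(1:12, times = 8))
  well <- character(n_all)
  for (pl in plates) {
    sel <- all_plate == pl
    well[sel] <- wells[seq_len(sum(sel))]
  }

  mat <- screen_matrix(values, genes = all_genes, role = all_role,
                       plate = all_plate, well = well)

  ct <- NULL
  curves <- NULL
  if (config$emit_ct) {
    slope <- -1 / log10(2)
    intercepts <- c(CDKN1A = 26, BBC3 = 28, TP53 = 25, LMNA = 22)
    curves <- lapply(intercepts, function(b0) {
      structure(list(slope = slope, intercept = b0, r_squared = 1,
                     efficiency = 1, positive_slope_warning = FALSE),
                class = "standard_curve")
    })
    ct <- emit_ct_records(all_genes, all_role, all_plate, values, toxic,
                          curves, config)
  }

  truth <- structure(
    list(config = config, genes = genes, category = category,
         direction = direction, effect = effect, plate = plate,
         plate_factor = plate_factor, toxic = toxic, curves = curves),
    class = "simulation_truth"
  )
  list(matrix = mat, truth = truth, ct = ct)
}

# Raw Ct triplicates: reference quantity varies per well, target quantity is
# the normalized value times the reference, both inverted through the curve.
emit_ct_records <- function(genes, role, plate, values, toxic, curves, config) {
  n_all <- length(genes)
  rows <- vector("list", 2 * n_all * 4)
  k <- 0L
  toxic_all <- c(toxic, rep(FALSE, n_all - length(toxic)))
  for (tr in TREATMENTS) {
    ref_q <- lognormal_noise(n_all, 0.1)  # per-well template amount
    ref_q[toxic_all] <- 0
    for (i in seq_len(n_all)) {
      for (ro in c(READOUTS, REFERENCE_GENE)) {
        q <- if (ro == REFERENCE_GENE) ref_q[i] else {
          v <- values[i, condition_label(ro, tr)]
          if (is.na(v)) if (toxic_all[i]) 0 else NA_real_ else v * ref_q[i]
        }
        base_ct <- ct_of_quantity(q, curves[[ro]])
        ct_reps <- base_ct + stats::rnorm(3, 0, config$ct_noise_sd)
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene = genes[i], role = role[i], plate = plate[i], readout = ro,
          treatment = tr, replicate = 1:3, ct = ct_reps,
          quantity = NA_real_, stringsAsFactors = FALSE
        )
      }
    }
  }
  # embedded 5-point 4-fold dilution series per readout
  dil <- 4^-(0:4)
  for (ro in c(READOUTS, REFERENCE_GENE)) {
    base_ct <- ct_of_quantity(dil, curves[[ro]])
    k <- k + 1L
    rows[[k]] <- data.frame(
      gene = paste0("STD_", ro), role = "standard", plate = NA_character_,
      readout = ro, treatment = "DMSO", replicate = seq_along(dil),
      ct = base_ct + stats::rnorm(length(dil), 0, config$ct_noise_sd),
      quantity = dil, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[seq_len(k)])
  class(out) <- c("ct_records", "data.frame")
  out
}

#' Simulate a secondary (validation) rescreen
#'
#' Regenerates DMSO-condition CDKN1A and BBC3 values for a seeded random
#' subset of the library from the same planted truth with fresh technical
#' noise — the design of a validation rescreen run in the basal condition
#' only. Genes named in `drop_effect_genes` have their planted effect
#' removed in the rescreen, emulating primary-screen false positives that
#' fail to reproduce.
#'
#' @param truth A `simulation_truth` from [simulate_screen()].
#' @param subset_size Number of library genes rescreened (default 81).
#' @param seed Seed for subset selection and rescreen noise.
#' @param drop_effect_genes Character vector of genes whose effect is zeroed
#'   in the rescreen.
#' @return A [screen_matrix()] with the CDKN1A.DMSO and BBC3.DMSO columns
#'   populated and the remaining conditions missing.
#' @export
simulate_secondary <- function(truth, subset_size = 81, seed = 1L,
                               drop_effect_genes = character(0)) {
  stopifnot(inherits(truth, "simulation_truth"))
  config <- truth$config
  n <- length(truth$genes)
  if (subset_size > n) stop("subset_size exceeds library size")
  set.seed(as.integer(seed))
  pick <- sort(sample.int(n, subset_size))
  cols <- c("CDKN1A.DMSO", "BBC3.DMSO")
  eff <- truth$effect[pick, cols, drop = FALSE]
  eff[truth$genes[pick] %in% drop_effect_genes, ] <- 0
  vals <- matrix(NA_real_, subset_size, length(CONDITIONS),
                 dimnames = list(NULL, CONDITIONS))
  vals[, cols] <- matrix(rep(config$baseline[cols], each = subset_size),
                         subset_size, 2) * 2^eff *
    matrix(lognormal_noise(subset_size * 2, config$noise_cv), subset_size, 2)
  screen_matrix(vals, genes = truth$genes[pick], role = "library")
}

#' Score recovery of planted regulators
#'
#' Compares a classification against the simulation truth at the gene level:
#' a gene counts as called when it holds any regulator category, and as
#' planted when the truth assigned it any non-null category (including the
#' TP53 library entry). Reports overall precision and recall, per-truth-
#' category recall, and a truth-by-predicted confusion table.
#'
#' @param truth A `simulation_truth`.
#' @param classification A [classify_regulators()] result on the same gene
#'   universe.
#' @return A list with `precision` (`NA` when nothing is called), `recall`,
#'   `per_category` (data frame), and `confusion` (table).
#' @export
score_recovery <- function(truth, classification) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(classification, "regulator_classification"))
  planted <- truth$genes[truth$category != "null"]
  called <- unique(classification$table$gene)
  called <- intersect(called, truth$genes)
  tp <- intersect(called, planted)
  precision <- if (length(called)) length(tp) / length(called) else NA_real_
  recall <- if (length(planted)) length(tp) / length(planted) else NA_real_

  predicted_label <- function(g) {
    rows <- classification$table[classification$table$gene == g, , drop = FALSE]
    if (!nrow(rows)) return("none")
    if ("joint" %in% rows$category) {
      d <- rows$direction[rows$category == "joint"][1]
      return(if (d == "positive_regulator") "joint_positive" else "joint_negative")
    }
    for (cat_name in c("CDKN1A_specific", "BBC3_specific", "TP53_specific")) {
      if (cat_name %in% rows$category) return(cat_name)
    }
    "none"
  }
  pred <- vapply(truth$genes, predicted_label, character(1))
  confusion <- table(truth = truth$category, predicted = pred)

  cats <- setdiff(unique(truth$category), "null")
  per_category <- do.call(rbind, lapply(cats, function(cat_name) {
    g <- truth$genes[truth$category == cat_name]
    data.frame(category = cat_name, n = length(g),
               recalled = sum(g %in% called),
               recall = mean(g %in% called), stringsAsFactors = FALSE)
  }))
  list(precision = precision, recall = recall,
       per_category = per_category, confusion = confusion)
}
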