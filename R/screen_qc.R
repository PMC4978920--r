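#' Z'-factor assay-window statistic
#'
#' The standard separability statistic for screen pilots:
#' Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|, computed with sample
#' standard deviations. Z' = 1 only for a noiseless assay; values above ~0.5
#' are conventionally taken as an excellent assay window, and 0 to 0.5 as
#' workable for a screen. Z' is invariant under common affine rescaling of
#' both groups.
#'
#' @param positive_values Numeric vector of positive-control measurements
#'   (>= 2 values).
#' @param negative_values Numeric vector of negative-control measurements
#'   (>= 2 values).
#' @return A list with `z_prime`, `mu_p`, `sd_p`, `mu_n`, `sd_n`.
#' @examples
#' z_prime_factor(rnorm(80, 10, 1), rnorm(80, 0, 1))$z_prime
#' @export
z_prime_factor <- function(positive_values, negative_values) {
  positive_values <- positive_values[!is.na(positive_values)]
  negative_values <- negative_values[!is.na(negative_values)]
  if (length(positive_values) < 2 || length(negative_values) < 2) {
    stop("need >= 2 values in each control group")
  }
  mu_p <- mean(positive_values); sd_p <- stats::sd(positive_values)
  mu_n <- mean(negative_values); sd_n <- stats::sd(negative_values)
  if (mu_p == mu_n) stop("undefined assay window: control means are equal")
  list(z_prime = 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n),
       mu_p = mu_p, sd_p = sd_p, mu_n = mu_n, sd_n = sd_n)
}

# Per-plate mean of each role x condition; returns long data frame.
per_plate_means <- function(x) {
  validate_screen_matrix(x)
  if (all(is.na(x$plate))) stop("screen matrix carries no plate assignments")
  out <- list()
  for (pl in unique(x$plate[!is.na(x$plate)])) {
    sel_p <- !is.na(x$plate) & x$plate == pl
    for (role in unique(x$role[sel_p])) {
      sel <- sel_p & x$role == role
      m <- colMeans(x$values[sel, , drop = FALSE], na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        plate = pl, role = role, condition = CONDITIONS,
        mean_value = as.numeric(m), n_wells = sum(sel),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Compare control siRNAs against the per-plate screen average
#'
#' For each dedicated control role (nontargeting, TP53, MDM2) and each of the
#' six conditions, tests whether the per-plate control means differ from the
#' per-plate library averages. By default an unpaired Welch two-sample t-test
#' (unequal variances, Welch-Satterthwaite degrees of freedom) is used; with
#' `paired = TRUE` plates are matched and a paired t-test is run on the
#' per-plate differences.
#'
#' @param x A [screen_matrix()] with plate assignments and control roles.
#' @param paired Pair control and library means by plate (default `FALSE`).
#' @return An object of class `qc_ttests`: data frame with columns `role`,
#'   `condition`, `t`, `df`, `p_value`, `n_control_plates`,
#'   `n_library_plates`.
#' @export
control_vs_average_tests <- function(x, paired = FALSE) {
  pm <- per_plate_means(x)
  lib <- pm[pm$role == "library", , drop = FALSE]
  rows <- list()
  for (role in setdiff(ROLES, "library")) {
    ctrl <- pm[pm$role == role, , drop = FALSE]
    if (!nrow(ctrl)) next
    for (cond in CONDITIONS) {
      a <- ctrl$mean_value[ctrl$condition == cond]
      b <- lib$mean_value[lib$condition == cond]
      if (paired) {
        common <- intersect(ctrl$plate[ctrl$condition == cond],
                            lib$plate[lib$condition == cond])
        a <- ctrl$mean_value[ctrl$condition == cond][match(common, ctrl$plate[ctrl$condition == cond])]
        b <- lib$mean_value[lib$condition == cond][match(common, lib$plate[lib$condition == cond])]
      }
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) {
        stop("insufficient replication: need >= 2 plates per group for ", role,
             " in ", cond)
      }
      tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        role = role, condition = cond,
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value,
        n_control_plates = length(a), n_library_plates = length(b),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(do.call(rbind, rows), class = c("qc_ttests", "data.frame"))
}

#' Screen QC report
#'
#' Bundles the per-plate control summaries and control-versus-average t-tests
#' into one object; optionally includes a Z'-factor when dedicated positive
#' and negative control roles are present with enough wells (the TP53
#' control, which strongly suppresses all three readouts, serves as the
#' positive control; the nontargeting control as negative).
#'
#' @param x A [screen_matrix()] with plates and roles.
#' @param z_prime_condition Condition used for the Z'-factor (default
#'   `"CDKN1A.etoposide"`, the induced readout with the widest window).
#' @param paired Passed to [control_vs_average_tests()].
#' @return A list with `per_plate`, `ttests`, and `z_prime` (or `NULL` if
#'   not computable), of class `screen_qc`.
#' @export
screen_qc_report <- function(x, z_prime_condition = "CDKN1A.etoposide",
                             paired = FALSE) {
  pm <- per_plate_means(x)
  tt <- control_vs_average_tests(x, paired = paired)
  zp <- NULL
  pos <- x$values[x$role == "tp53_control", z_prime_condition]
  neg <- x$values[x$role == "nontargeting_control", z_prime_condition]
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) >= 2 && length(neg) >= 2 && mean(pos) != mean(neg)) {
    zp <- z_prime_factor(pos, neg)
  }
  structure(list(per_plate = pm, ttests = tt, z_prime = zp,
                 z_prime_condition = z_prime_condition),
            class = "screen_qc")
}

#' @export
print.screen_qc <- function(x, ...) {
  cat("screen_qc:", length(unique(x$per_plate$plate)), "plates\n")
  if (!is.null(x$z_prime)) {
    cat(sprintf("  Z'-factor (%s): %.3f\n", x$z_prime_condition,
                x$z_prime$z_prime))
  }
  sig <- x$ttests[x$ttests$p_value < 0.05, c("role", "condition", "p_value")]
  cat("  control-vs-average tests with p < 0.05:", nrow(sig), "\n")
  invisible(x)
}
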