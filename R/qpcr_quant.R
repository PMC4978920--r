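#' Fit a relative standard curve
#'
#' Ordinary least squares of Ct against log10(template quantity) over a
#' dilution series. The fitted slope and intercept convert Ct values of
#' unknowns to relative template amounts ([relative_quantity()]); the
#' amplification efficiency is derived from the slope as
#' E = 10^(-1/slope) - 1, so a perfect doubling per cycle gives slope
#' -1/log10(2) = -3.3219 and E = 1.
#'
#' @param quantity Numeric vector of template quantities (arbitrary units,
#'   > 0), one per point.
#' @param ct Numeric vector of Ct values (cycles), same length.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, and `positive_slope_warning`
#'   (TRUE when the fitted slope is non-negative, which is chemically
#'   nonsensical and usually means swapped columns).
#' @examples
#' sc <- fit_standard_curve(c(1, 0.5, 0.25, 0.125),
#'                          30 - 1 / log10(2) * log10(c(1, 0.5, 0.25, 0.125)))
#' sc$efficiency
#' @export
fit_standard_curve <- function(quantity, ct) {
  ok <- !is.na(quantity) & !is.na(ct)
  quantity <- quantity[ok]
  ct <- ct[ok]
  if (length(quantity) < 3 || length(unique(quantity)) < 2) {
    stop("insufficient standard curve: need >= 3 points spanning >= 2 quantities")
  }
  if (any(quantity <= 0)) stop("standard quantities must be > 0")
  lq <- log10(quantity)
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless series are legal
  warn <- slope >= 0
  if (warn) warning("fitted standard curve has non-negative slope")
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = if (warn) NA_real_ else 10^(-1 / slope) - 1,
         positive_slope_warning = warn),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, intercept %.4f, R^2 %.4f, efficiency %.3f\n",
              x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Convert a Ct value to a relative quantity
#'
#' Inverts the standard curve: quantity = 10^((ct - intercept) / slope).
#' Strictly decreasing in Ct for any valid (negative-slope) curve. Missing Ct
#' values propagate as missing quantities rather than raising errors, since
#' undetermined wells are routine in a screen.
#'
#' @param ct Numeric vector of Ct values (cycles); `NA` allowed.
#' @param curve A `standard_curve`.
#' @return Numeric vector of relative quantities (arbitrary units).
#' @export
relative_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("cannot quantify against a non-negative-slope curve")
  10^((ct - curve$intercept) / curve$slope)
}

#' Ct value corresponding to a quantity on a standard curve
#'
#' The forward direction of the curve, used by the synthetic generator to
#' emit raw Ct triplicates: ct = intercept + slope * log10(quantity).
#'
#' @param quantity Numeric vector of quantities (> 0); 0 or `NA` gives `NA`
#'   (no amplification).
#' @param curve A `standard_curve`.
#' @return Numeric vector of Ct values.
#' @export
ct_of_quantity <- function(quantity, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  out <- rep(NA_real_, length(quantity))
  ok <- !is.na(quantity) & quantity > 0
  out[ok] <- curve$intercept + curve$slope * log10(quantity[ok])
  out
}

#' Aggregate replicate Ct measurements into one quantity
#'
#' Converts each replicate Ct to a relative quantity and averages on the
#' quantity scale (the scale on which the relative standard curve method
#' reports). A QC flag is raised — not an exclusion — when the replicate Ct
#' standard deviation exceeds `sd_cycles_flag` cycles or fewer than two
#' replicates are present.
#'
#' @param ct Numeric vector of replicate Ct values; `NA` for undetermined.
#' @param curve A `standard_curve` for this readout.
#' @param sd_cycles_flag QC threshold on replicate Ct SD, in cycles
#'   (default 0.5).
#' @return A list with `quantity` (mean replicate quantity, `NA` if all
#'   replicates missing), `qc_flag` (logical), and `reason` (character,
#'   `NA` when unflagged).
#' @export
aggregate_replicates <- function(ct, curve, sd_cycles_flag = 0.5) {
  ct_ok <- ct[!is.na(ct)]
  if (length(ct_ok) == 0) {
    return(list(quantity = NA_real_, qc_flag = TRUE, reason = "all_replicates_missing"))
  }
  q <- mean(relative_quantity(ct_ok, curve))
  flag <- FALSE
  reason <- NA_character_
  if (length(ct_ok) < 2) {
    flag <- TRUE
    reason <- "single_replicate"
  } else if (stats::sd(ct_ok) > sd_cycles_flag) {
    flag <- TRUE
    reason <- "replicate_sd_exceeded"
  }
  list(quantity = q, qc_flag = flag, reason = reason)
}

#' Normalize a target quantity to the reference gene
#'
#' The per-sample ratio target/reference that puts all wells on a common
#' scale. A missing or non-positive reference (e.g. a toxic knockdown with no
#' LMNA signal) yields a missing normalized value with a reason code rather
#' than an error, so single wells cannot crash a screen.
#'
#' @param target_quantity Numeric vector of target-gene quantities.
#' @param reference_quantity Numeric vector of reference-gene quantities,
#'   recycled if length one.
#' @return A list with `value` (numeric vector, `NA` where undefined) and
#'   `reason` (character vector, `NA` where defined).
#' @export
normalize_to_reference <- function(target_quantity, reference_quantity) {
  n <- max(length(target_quantity), length(reference_quantity))
  target_quantity <- rep_len(target_quantity, n)
  reference_quantity <- rep_len(reference_quantity, n)
  value <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  bad_ref <- is.na(reference_quantity) | reference_quantity <= 0
  reason[bad_ref & is.na(reference_quantity)] <- "reference_missing"
  reason[bad_ref & !is.na(reference_quantity)] <- "reference_nonpositive"
  bad_tgt <- !bad_ref & is.na(target_quantity)
  reason[bad_tgt] <- "target_missing"
  ok <- !bad_ref & !bad_tgt
  value[ok] <- target_quantity[ok] / reference_quantity[ok]
  list(value = value, reason = reason)
}

#' Quantify a full screen from Ct records
#'
#' Runs the relative standard curve method over a long table of Ct records:
#' per (gene, readout, treatment), replicates are converted to quantities and
#' averaged ([aggregate_replicates()]); each target readout is then
#' normalized to the LMNA reference quantity from the same gene and treatment
#' ([normalize_to_reference()]).
#'
#' @param records A `ct_records` data frame (see [read_screen_table()] with
#'   `schema = "ct_long"`). Rows with `role == "standard"` are used to fit
#'   curves when `curves` is not supplied; they carry a `quantity` column.
#' @param curves Optional named list of `standard_curve` objects, one per
#'   readout gene including `LMNA`. Fitted from embedded standard rows when
#'   omitted.
#' @param sd_cycles_flag Replicate-SD QC threshold passed to
#'   [aggregate_replicates()].
#' @return A list with `matrix` (a [screen_matrix()]), `qc` (data frame of
#'   per-cell QC flags), and `curves` (the curves used).
#' @export
quantify_screen <- function(records, curves = NULL, sd_cycles_flag = 0.5) {
  stopifnot(is.data.frame(records))
  has_role <- "role" %in% names(records)
  is_std <- if (has_role) !is.na(records$role) & records$role == "standard" else
    rep(FALSE, nrow(records))
  if (is.null(curves)) {
    std <- records[is_std, , drop = FALSE]
    if (!nrow(std)) stop("no curves supplied and no standard-role rows present")
    require_columns(std, "quantity")
    curves <- lapply(split(std, std$readout), function(s) {
      fit_standard_curve(s$quantity, s$ct)
    })
  }
  samp <- records[!is_std, , drop = FALSE]
  need <- setdiff(unique(samp$readout), names(curves))
  if (length(need)) stop("no standard curve for readout(s): ", paste(need, collapse = ", "))

  genes <- unique(samp$gene)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(CONDITIONS),
                 dimnames = list(NULL, CONDITIONS))
  qc_list <- list()
  chunks <- split(seq_len(nrow(samp)),
                  list(gene = samp$gene, treatment = samp$treatment), drop = TRUE)
  for (key in names(chunks)) {
    gt <- samp[chunks[[key]], , drop = FALSE]
    g <- gt$gene[1]
    tr <- gt$treatment[1]
    g_idx <- match(g, genes)
    {
      ref_rows <- gt[gt$readout == REFERENCE_GENE, , drop = FALSE]
      ref <- if (nrow(ref_rows)) {
        aggregate_replicates(ref_rows$ct, curves[[REFERENCE_GENE]], sd_cycles_flag)
      } else list(quantity = NA_real_, qc_flag = TRUE, reason = "reference_missing")
      for (ro in intersect(READOUTS, unique(gt$readout))) {
        tr_rows <- gt[gt$readout == ro, , drop = FALSE]
        agg <- aggregate_replicates(tr_rows$ct, curves[[ro]], sd_cycles_flag)
        norm <- normalize_to_reference(agg$quantity, ref$quantity)
        vals[g_idx, condition_label(ro, tr)] <- norm$value
        qc_list[[length(qc_list) + 1L]] <- data.frame(
          gene = g, readout = ro, treatment = tr,
          target_flag = agg$qc_flag, reference_flag = ref$qc_flag,
          reason = if (!is.na(norm$reason[1])) norm$reason[1] else agg$reason,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  qc <- if (length(qc_list)) do.call(rbind, qc_list) else NULL
  role <- if (has_role) {
    r <- samp$role[match(genes, samp$gene)]
    r[is.na(r)] <- "library"
    r
  } else "library"
  plate <- if ("plate" %in% names(samp)) samp$plate[match(genes, samp$gene)] else NA_character_
  list(matrix = screen_matrix(vals, genes = genes, role = role, plate = plate),
       qc = qc, curves = curves)
}
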