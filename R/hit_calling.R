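#' Compute per-condition standard scores
#'
#' For each of the six readout-by-treatment conditions, computes
#' z = (X - mu) / theta, where mu and theta are the mean and sample standard
#' deviation (n - 1) of normalized expression across the screened siRNA
#' library for that condition. By default the per-plate dedicated control
#' wells are excluded from mu and theta (they recur on every plate and would
#' bias the location estimate) but still receive z-scores against the library
#' parameters, so control behavior can be assessed on the library scale.
#'
#' @param x A [screen_matrix()].
#' @param include_controls If `TRUE`, control wells contribute to mu/theta as
#'   well. Default `FALSE`.
#' @return An object of class `zscore_table`: list with `genes`, `role`, `z`
#'   (gene x 6 matrix), `mu`, `theta`, `n_used` (per condition), and
#'   `include_controls`.
#' @examples
#' sm <- screen_matrix(matrix(rlnorm(60), 10), genes = paste0("G", 1:10))
#' zt <- compute_zscores(sm)
#' round(colMeans(zt$z), 10)
#' @export
compute_zscores <- function(x, include_controls = FALSE) {
  validate_screen_matrix(x)
  included <- if (include_controls) rep(TRUE, length(x$genes)) else x$role == "library"
  if (!any(included)) stop("no included entries to estimate mu/theta from")
  mu <- theta <- n_used <- stats::setNames(numeric(length(CONDITIONS)), CONDITIONS)
  z <- x$values
  for (j in seq_along(CONDITIONS)) {
    v <- x$values[included, j]
    v <- v[!is.na(v)]
    n_used[j] <- length(v)
    if (length(v) < 2) {
      stop("fewer than 2 non-missing values in condition ", CONDITIONS[j])
    }
    mu[j] <- mean(v)
    theta[j] <- stats::sd(v)
    if (theta[j] == 0) {
      stop("degenerate condition (zero variance): ", CONDITIONS[j])
    }
    z[, j] <- (x$values[, j] - mu[j]) / theta[j]
  }
  structure(
    list(genes = x$genes, role = x$role, z = z, mu = mu, theta = theta,
         n_used = n_used, include_controls = include_controls),
    class = "zscore_table"
  )
}

#' @export
print.zscore_table <- function(x, ...) {
  cat("zscore_table:", length(x$genes), "entries;",
      "library n per condition:", paste(x$n_used, collapse = "/"), "\n")
  invisible(x)
}

#' Call hits from a z-score table
#'
#' A (gene, condition) pair is a hit when its z-score lies strictly outside
#' the threshold window: z < -threshold or z > +threshold. Values exactly on
#' the boundary fall inside the window and are not hits. Direction follows
#' the knockdown logic of an RNAi screen: expression reduced by the
#' knockdown (z below the window) means the targeted gene is a
#' `positive_regulator` of the readout; expression increased means
#' `negative_regulator`.
#'
#' @param ztable A [compute_zscores()] result.
#' @param threshold Positive z cut-off (default 2).
#' @return An object of class `hit_calls`: data frame with columns `gene`,
#'   `role`, `condition`, `readout`, `treatment`, `z`, `direction`; the
#'   threshold is stored in `attr(, "threshold")`.
#' @export
call_hits <- function(ztable, threshold = 2) {
  stopifnot(inherits(ztable, "zscore_table"), threshold > 0)
  idx <- which(!is.na(ztable$z) & abs(ztable$z) > threshold, arr.ind = TRUE)
  cp <- condition_parts(CONDITIONS)
  hits <- data.frame(
    gene = ztable$genes[idx[, 1]],
    role = ztable$role[idx[, 1]],
    condition = CONDITIONS[idx[, 2]],
    readout = cp$readout[idx[, 2]],
    treatment = cp$treatment[idx[, 2]],
    z = ztable$z[idx],
    stringsAsFactors = FALSE
  )
  hits$direction <- ifelse(hits$z < 0, "positive_regulator", "negative_regulator")
  hits <- hits[order(-abs(hits$z)), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, threshold = threshold, class = c("hit_calls", "data.frame"))
}

#' Classify regulators from hit calls
#'
#' Maps per-condition hits onto regulator categories:
#' \describe{
#'   \item{joint}{same-direction hits for both CDKN1A and BBC3 within the
#'     same treatment.}
#'   \item{CDKN1A_specific / BBC3_specific}{a hit for that readout in a
#'     treatment where the partner readout is not a hit, for a gene that is
#'     not joint in any treatment (joint status takes precedence).}
#'   \item{TP53_specific}{a hit on the TP53 readout; assigned independently,
#'     so a gene may be both joint and TP53-specific (a TP53-knockdown-like
#'     profile).}
#' }
#' One classification row is produced per (gene, category, treatment,
#' direction); the representative `z` is the strongest contributing readout's
#' z-score. Only library entries are classified; dedicated control wells are
#' excluded.
#'
#' @param hits A [call_hits()] result.
#' @param genes Optional character vector giving the full gene universe (for
#'   reporting genes with no category); defaults to the genes present in
#'   `hits`.
#' @return An object of class `regulator_classification`: list with `table`
#'   (the classification rows, including `secondary_status`, initialized to
#'   `"not_retested"`, and `low_expression_flag`, initialized to `FALSE`)
#'   and `genes` (the universe).
#' @export
classify_regulators <- function(hits, genes = NULL) {
  stopifnot(inherits(hits, "hit_calls"))
  lib <- hits[hits$role == "library", , drop = FALSE]
  if (is.null(genes)) genes <- unique(lib$gene)
  rows <- list()
  add_row <- function(gene, category, direction, treatment, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, category = category, direction = direction,
      treatment = treatment, z = z, stringsAsFactors = FALSE
    )
  }
  for (g in unique(lib$gene)) {
    gh <- lib[lib$gene == g, , drop = FALSE]
    joint_any <- FALSE
    joint_rows <- list()
    for (tr in TREATMENTS) {
      hC <- gh[gh$readout == "CDKN1A" & gh$treatment == tr, , drop = FALSE]
      hB <- gh[gh$readout == "BBC3" & gh$treatment == tr, , drop = FALSE]
      if (nrow(hC) && nrow(hB) && hC$direction == hB$direction) {
        joint_any <- TRUE
        zrep <- c(hC$z, hB$z)[which.max(abs(c(hC$z, hB$z)))]
        joint_rows[[tr]] <- list(dir = hC$direction, z = zrep)
      }
    }
    for (tr in names(joint_rows)) {
      add_row(g, "joint", joint_rows[[tr]]$dir, tr, joint_rows[[tr]]$z)
    }
    if (!joint_any) {
      for (tr in TREATMENTS) {
        hC <- gh[gh$readout == "CDKN1A" & gh$treatment == tr, , drop = FALSE]
        hB <- gh[gh$readout == "BBC3" & gh$treatment == tr, , drop = FALSE]
        if (nrow(hC) && !nrow(hB)) {
          add_row(g, "CDKN1A_specific", hC$direction, tr, hC$z)
        }
        if (nrow(hB) && !nrow(hC)) {
          add_row(g, "BBC3_specific", hB$direction, tr, hB$z)
        }
      }
    }
    for (tr in TREATMENTS) {
      hT <- gh[gh$readout == "TP53" & gh$treatment == tr, , drop = FALSE]
      if (nrow(hT)) add_row(g, "TP53_specific", hT$direction, tr, hT$z)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), category = character(0),
               direction = character(0), treatment = character(0),
               z = numeric(0), stringsAsFactors = FALSE)
  tab$secondary_status <- rep("not_retested", nrow(tab))
  tab$low_expression_flag <- rep(FALSE, nrow(tab))
  structure(list(table = tab, genes = genes,
                 threshold = attr(hits, "threshold")),
            class = "regulator_classification")
}

#' @export
print.regulator_classification <- function(x, ...) {
  tab <- x$table
  cat("regulator_classification:", nrow(tab), "category rows over",
      length(unique(tab$gene)), "genes (universe", length(x$genes), ")\n")
  if (nrow(tab)) print(table(tab$category, tab$direction))
  invisible(x)
}

#' Summarize a regulator classification
#'
#' Tallies each category in two conventions: `entries` counts classification
#' rows (a gene appearing under both treatments counts twice, the convention
#' of per-treatment hit tables), while `genes` counts unique gene symbols.
#'
#' @param object A `regulator_classification`.
#' @param ... Unused.
#' @return Data frame with columns `category`, `direction`, `entries`,
#'   `genes`.
#' @export
summary.regulator_classification <- function(object, ...) {
  tab <- object$table
  if (!nrow(tab)) {
    return(data.frame(category = character(0), direction = character(0),
                      entries = integer(0), genes = integer(0)))
  }
  agg <- aggregate(gene ~ category + direction, data = tab,
                   FUN = function(g) c(entries = length(g), genes = length(unique(g))))
  data.frame(category = agg$category, direction = agg$direction,
             entries = agg$gene[, "entries"], genes = agg$gene[, "genes"],
             stringsAsFactors = FALSE)
}

#' Validate primary regulators against a secondary screen
#'
#' Re-tests CDKN1A/BBC3 regulators against a rescreen of a gene subset,
#' conventionally run in the basal (DMSO) condition with a relaxed 1-SD
#' cut-off. z-scores are computed internally over the rescreened pool (its
#' own mean and SD). A primary regulator present in the pool is `confirmed`
#' when at least one of its category's readouts has |secondary z| strictly
#' greater than `threshold` (with matching direction when
#' `require_direction`); present but unconfirmed regulators are putative
#' false positives (`not_confirmed`); absent genes stay `not_retested`.
#' TP53-specific rows are not retested (the rescreen measures CDKN1A/BBC3
#' only).
#'
#' @param classification A [classify_regulators()] result.
#' @param secondary A [screen_matrix()] for the rescreened pool with at least
#'   the CDKN1A.DMSO and/or BBC3.DMSO columns populated.
#' @param threshold Secondary z cut-off (default 1).
#' @param require_direction Require the secondary effect direction to match
#'   the primary call (default `TRUE`).
#' @return The classification with `secondary_status` updated.
#' @export
validate_secondary <- function(classification, secondary, threshold = 1,
                               require_direction = TRUE) {
  stopifnot(inherits(classification, "regulator_classification"))
  validate_screen_matrix(secondary)
  if (!length(secondary$genes)) {
    warning("empty secondary pool: all regulators not_retested")
    return(classification)
  }
  sec_cols <- c("CDKN1A.DMSO", "BBC3.DMSO")
  zsec <- matrix(NA_real_, nrow = length(secondary$genes), ncol = 2,
                 dimnames = list(NULL, c("CDKN1A", "BBC3")))
  for (k in seq_along(sec_cols)) {
    v <- secondary$values[, sec_cols[k]]
    ok <- !is.na(v)
    if (sum(ok) >= 2 && stats::sd(v[ok]) > 0) {
      zsec[, k] <- (v - mean(v[ok])) / stats::sd(v[ok])
    }
  }
  pool <- toupper(secondary$genes)
  tab <- classification$table
  for (i in seq_len(nrow(tab))) {
    if (!tab$category[i] %in% c("joint", "CDKN1A_specific", "BBC3_specific")) next
    j <- match(toupper(tab$gene[i]), pool)
    if (is.na(j)) next  # not in the rescreened pool
    readouts <- switch(tab$category[i],
                       joint = c("CDKN1A", "BBC3"),
                       CDKN1A_specific = "CDKN1A",
                       BBC3_specific = "BBC3")
    zvals <- zsec[j, readouts]
    passed <- abs(zvals) > threshold
    if (require_direction) {
      want_neg <- tab$direction[i] == "positive_regulator"
      passed <- passed & ((zvals < 0) == want_neg)
    }
    tab$secondary_status[i] <- if (any(passed, na.rm = TRUE)) "confirmed" else "not_confirmed"
  }
  classification$table <- tab
  classification
}

#' Flag regulators not expressed in the screened cell line
#'
#' Joins an external per-gene expression table (e.g. published RNA-seq
#' quantification of the screened cell line) onto the classification,
#' case-insensitively on gene symbol, and flags any regulator whose
#' expression value equals exactly 0 (not expressed) as a putative false
#' positive: an siRNA cannot produce an on-target phenotype by depleting a
#' transcript the cell does not express. Genes absent from the table are
#' left untouched and reported via the `"unmatched"` attribute.
#'
#' @param classification A [classify_regulators()] result.
#' @param expression Either a data frame with columns `gene` and `value`, or
#'   a named numeric vector.
#' @return The classification with `low_expression_flag` updated; unmatched
#'   gene symbols in `attr(result$table, "unmatched")`.
#' @export
flag_low_expression <- function(classification, expression) {
  stopifnot(inherits(classification, "regulator_classification"))
  if (is.data.frame(expression)) {
    require_columns(expression, c("gene", "value"))
    expr <- stats::setNames(expression$value, expression$gene)
  } else {
    expr <- expression
  }
  names(expr) <- toupper(names(expr))
  tab <- classification$table
  j <- match(toupper(tab$gene), names(expr))
  matched <- !is.na(j)
  tab$low_expression_flag[matched] <- expr[j[matched]] == 0
  attr(tab, "unmatched") <- unique(tab$gene[!matched])
  classification$table <- tab
  classification
}
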