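# Controlled vocabularies for the screen design: three p53 target readouts,
# the LMNA reference gene, two treatments, and the four well roles.
READOUTS <- c("CDKN1A", "BBC3", "TP53")
REFERENCE_GENE <- "LMNA"
TREATMENTS <- c("DMSO", "etoposide")
ROLES <- c("library", "nontargeting_control", "tp53_control", "mdm2_control")

# Fixed column order of every screen matrix.
CONDITIONS <- c(
  "CDKN1A.DMSO", "CDKN1A.etoposide",
  "BBC3.DMSO", "BBC3.etoposide",
  "TP53.DMSO", "TP53.etoposide"
)

condition_label <- function(readout, treatment) paste(readout, treatment, sep = ".")

condition_parts <- function(condition) {
  parts <- strsplit(condition, ".", fixed = TRUE)
  data.frame(
    readout = vapply(parts, `[`, character(1), 1L),
    treatment = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' Construct a screen expression matrix
#'
#' The central container of the pipeline: a gene-by-condition grid of
#' reference-normalized expression values (dimensionless ratios to the LMNA
#' reference gene). Columns are the six (readout, treatment) combinations in
#' fixed order: CDKN1A.DMSO, CDKN1A.etoposide, BBC3.DMSO, BBC3.etoposide,
#' TP53.DMSO, TP53.etoposide. `NA` marks missing cells (for example toxic
#' knockdowns with no reference signal).
#'
#' @param values Numeric matrix with one row per siRNA entry and six columns.
#'   Column names, if present, must match the fixed condition order.
#' @param genes Character vector of gene symbols, one per row. Defaults to
#'   `rownames(values)`.
#' @param role Character vector of well roles, recycled if length one. One of
#'   `"library"`, `"nontargeting_control"`, `"tp53_control"`,
#'   `"mdm2_control"`.
#' @param plate Optional character vector of plate identifiers.
#' @param well Optional character vector of well identifiers (e.g. "A01").
#' @return An object of class `screen_matrix`.
#' @examples
#' m <- matrix(rlnorm(12), nrow = 2)
#' sm <- screen_matrix(m, genes = c("SETD3", "CTCF"))
#' dim(sm$values)
#' @export
screen_matrix <- function(values, genes = rownames(values), role = "library",
                          plate = NA_character_, well = NA_character_) {
  values <- as.matrix(values)
  if (ncol(values) != length(CONDITIONS)) {
    stop("screen matrix must have exactly ", length(CONDITIONS), " columns (",
         paste(CONDITIONS, collapse = ", "), ")")
  }
  if (!is.null(colnames(values)) && !identical(colnames(values), CONDITIONS)) {
    if (!setequal(colnames(values), CONDITIONS)) {
      stop("unknown condition columns: ",
           paste(setdiff(colnames(values), CONDITIONS), collapse = ", "))
    }
    values <- values[, CONDITIONS, drop = FALSE]
  }
  colnames(values) <- CONDITIONS
  if (is.null(genes)) stop("gene symbols are required")
  genes <- as.character(genes)
  if (length(genes) != nrow(values)) stop("length(genes) must equal nrow(values)")
  rownames(values) <- NULL
  role <- rep_len(as.character(role), nrow(values))
  plate <- rep_len(as.character(plate), nrow(values))
  well <- rep_len(as.character(well), nrow(values))
  x <- structure(
    list(genes = genes, role = role, plate = plate, well = well, values = values),
    class = "screen_matrix"
  )
  validate_screen_matrix(x)
}

#' Validate a screen matrix
#'
#' Checks the type invariants: non-empty gene symbols, known roles, all
#' non-missing values finite and non-negative, fixed condition column order,
#' and unique (plate, well) pairs where both are given.
#'
#' @param x A `screen_matrix`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_screen_matrix <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  if (any(!nzchar(x$genes)) || anyNA(x$genes)) stop("empty gene symbol")
  bad_role <- setdiff(unique(x$role), ROLES)
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  if (!identical(colnames(x$values), CONDITIONS)) stop("condition columns out of order")
  v <- x$values[!is.na(x$values)]
  if (any(!is.finite(v))) stop("non-finite expression value")
  if (any(v < 0)) stop("negative expression value")
  pw <- paste(x$plate, x$well)
  has_pw <- !is.na(x$plate) & !is.na(x$well)
  if (anyDuplicated(pw[has_pw])) stop("duplicate (plate, well) assignment")
  x
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat("screen_matrix:", length(x$genes), "siRNA entries x", ncol(x$values),
      "conditions\n")
  tab <- table(factor(x$role, levels = ROLES))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.screen_matrix <- function(x) dim(x$values)

#' Subset a screen matrix by gene index
#'
#' @param x A `screen_matrix`.
#' @param i Row (gene) index.
#' @param ... Unused.
#' @return A `screen_matrix` with the selected entries.
#' @export
`[.screen_matrix` <- function(x, i, ...) {
  screen_matrix(x$values[i, , drop = FALSE], genes = x$genes[i],
                role = x$role[i], plate = x$plate[i], well = x$well[i])
}
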