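#' Read a screen table from CSV/TSV
#'
#' Reads one of three tabular layouts into the pipeline's data structures.
#' `"normalized_long"` is the canonical tidy interchange format: one row per
#' (gene, readout, treatment) with a `value` column of reference-normalized
#' expression; it returns a [screen_matrix()]. `"matrix"` accepts a wide table
#' with a `gene` column plus the six condition columns. `"ct_long"` reads raw
#' qPCR Ct records (including LMNA reference rows and optional `standard`
#' dilution-series rows carrying a `quantity` column) and returns a
#' `ct_records` data frame for [quantify_screen()].
#'
#' Missing values may be written as an empty field or `NA`. Gene order is
#' preserved as first-appearance order. Column names can be remapped through
#' `col_map` for tables exported with non-default headers.
#'
#' @param path Path to a delimited text file.
#' @param schema One of `"normalized_long"`, `"matrix"`, `"ct_long"`.
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param col_map Named character vector mapping canonical column names
#'   (names) to the file's column names (values), e.g.
#'   `c(gene = "GeneSymbol", value = "norm_expr")`.
#' @return A `screen_matrix` for `"normalized_long"`/`"matrix"`, or a
#'   `ct_records` data frame for `"ct_long"`.
#' @export
read_screen_table <- function(path,
                              schema = c("normalized_long", "matrix", "ct_long"),
                              sep = ",", col_map = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""), check.names = FALSE),
    error = function(e) stop("schema error: cannot read table (", conditionMessage(e), ")")
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  switch(schema,
    normalized_long = read_normalized_long(df),
    matrix = read_wide_matrix(df),
    ct_long = read_ct_long(df)
  )
}

require_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
}

check_vocabulary <- function(x, allowed, what) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad)) {
    stop("vocabulary error: unknown ", what, " token(s): ",
         paste(bad, collapse = ", "))
  }
}

parse_numeric_column <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("parse error: non-numeric ", what, " at row ", bad[1], ": '", x[bad[1]], "'")
  }
  out
}

read_normalized_long <- function(df) {
  require_columns(df, c("gene", "readout", "treatment", "value"))
  check_vocabulary(df$readout, READOUTS, "readout")
  check_vocabulary(df$treatment, TREATMENTS, "treatment")
  if ("role" %in% names(df)) check_vocabulary(df$role, ROLES, "role")
  df$value <- parse_numeric_column(df$value, "value")
  key <- paste(df$gene, df$readout, df$treatment,
               if ("replicate" %in% names(df)) df$replicate else "")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, readout, treatment",
         if ("replicate" %in% names(df)) ", replicate" else "", ") rows")
  }
  genes <- unique(df$gene)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(CONDITIONS),
                 dimnames = list(NULL, CONDITIONS))
  cond <- condition_label(df$readout, df$treatment)
  ridx <- match(df$gene, genes)
  cidx <- match(cond, CONDITIONS)
  if ("replicate" %in% names(df)) {
    # average replicate-level normalized values into the cell
    agg <- tapply(df$value, list(ridx, cidx), function(v) mean(v, na.rm = TRUE))
    for (r in rownames(agg)) for (cl in colnames(agg)) {
      v <- agg[r, cl]
      if (!is.null(v) && !is.na(v)) vals[as.integer(r), as.integer(cl)] <- v
    }
  } else {
    vals[cbind(ridx, cidx)] <- df$value
  }
  meta_first <- function(col, default) {
    if (col %in% names(df)) df[[col]][match(genes, df$gene)] else default
  }
  screen_matrix(vals, genes = genes,
                role = meta_first("role", "library"),
                plate = meta_first("plate", NA_character_),
                well = meta_first("well", NA_character_))
}

read_wide_matrix <- function(df) {
  require_columns(df, "gene")
  # accept "." or "_" separated condition headers
  names(df) <- sub("^(CDKN1A|BBC3|TP53)_(DMSO|etoposide)$", "\\1.\\2", names(df))
  require_columns(df, CONDITIONS)
  vals <- as.matrix(df[, CONDITIONS])
  storage.mode(vals) <- "double"
  screen_matrix(vals, genes = df$gene,
                role = if ("role" %in% names(df)) df$role else "library",
                plate = if ("plate" %in% names(df)) df$plate else NA_character_,
                well = if ("well" %in% names(df)) df$well else NA_character_)
}

read_ct_long <- function(df) {
  require_columns(df, c("gene", "readout", "treatment", "replicate", "ct"))
  check_vocabulary(df$readout, c(READOUTS, REFERENCE_GENE), "readout")
  check_vocabulary(df$treatment, TREATMENTS, "treatment")
  df$ct <- parse_numeric_column(df$ct, "ct")
  df$replicate <- parse_numeric_column(df$replicate, "replicate")
  if ("quantity" %in% names(df)) {
    df$quantity <- parse_numeric_column(df$quantity, "quantity")
  }
  key <- paste(df$gene, df$readout, df$treatment, df$replicate,
               if ("role" %in% names(df)) df$role else "")
  if (anyDuplicated(key)) stop("duplicate (gene, readout, treatment, replicate) rows")
  class(df) <- c("ct_records", "data.frame")
  df
}

#' Write a screen matrix as a long CSV
#'
#' Writes the canonical tidy interchange format (gene, role, plate, well,
#' readout, treatment, value), one row per cell including missing cells
#' (written as `NA`). [read_screen_table()] with `schema = "normalized_long"`
#' inverts this exactly.
#'
#' @param x A `screen_matrix`.
#' @param path Output file path.
#' @param sep Field separator (default CSV).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path, sep = ",") {
  validate_screen_matrix(x)
  cp <- condition_parts(CONDITIONS)
  n <- length(x$genes)
  long <- data.frame(
    gene = rep(x$genes, times = length(CONDITIONS)),
    role = rep(x$role, times = length(CONDITIONS)),
    plate = rep(x$plate, times = length(CONDITIONS)),
    well = rep(x$well, times = length(CONDITIONS)),
    readout = rep(cp$readout, each = n),
    treatment = rep(cp$treatment, each = n),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
  # keep first-appearance gene order on re-read
  long <- long[order(match(long$gene, x$genes)), ]
  utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write per-category hit tables
#'
#' Emits one TSV per regulator category (joint, CDKN1A-specific,
#' BBC3-specific, TP53-specific) with columns `direction`, `condition`,
#' `gene`, `z`, `secondary_flag`, `low_expression_flag`. Within each
#' direction-by-treatment group genes are ordered from strongest to weakest
#' effect (|z| descending), mirroring how screen hit tables are conventionally
#' presented.
#'
#' @param classification A [classify_regulators()] result.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the four file paths, invisibly.
#' @export
write_hit_tables <- function(classification, out_dir) {
  stopifnot(inherits(classification, "regulator_classification"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  tab <- classification$table
  files <- c(joint = "joint_regulators.tsv",
             CDKN1A_specific = "CDKN1A_specific.tsv",
             BBC3_specific = "BBC3_specific.tsv",
             TP53_specific = "TP53_specific.tsv")
  paths <- character(0)
  for (cat_name in names(files)) {
    sub <- tab[tab$category == cat_name, , drop = FALSE]
    sub <- sub[order(sub$direction, sub$treatment, -abs(sub$z)), , drop = FALSE]
    out <- data.frame(direction = sub$direction, condition = sub$treatment,
                      gene = sub$gene, z = sub$z,
                      secondary_flag = sub$secondary_status,
                      low_expression_flag = sub$low_expression_flag,
                      stringsAsFactors = FALSE)
    p <- file.path(out_dir, files[[cat_name]])
    utils::write.table(out, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
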