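#' Run the full screen-analysis pipeline
#'
#' Orchestrates every stage over a primary screen input: quantification (when
#' the input is raw Ct records), z-scoring, hit calling, regulator
#' classification, optional secondary-screen validation and expression-based
#' false-positive flagging, SOM clustering, and screen QC. Results are
#' written to `out_dir` as TSV/CSV/JSON, together with a JSON run manifest
#' recording input hashes, thresholds, seeds, the package version, and
#' per-stage row counts, so a run can be reproduced byte-for-byte.
#'
#' Optional stages degrade gracefully: a missing secondary screen or
#' expression table leaves the corresponding flags at their defaults with a
#' warning; QC is skipped with a warning when the input carries no plate
#' assignments.
#'
#' @param input A [screen_matrix()], a `ct_records` data frame, or a path to
#'   a file readable by [read_screen_table()] (schema auto-set to
#'   `"normalized_long"` for paths).
#' @param out_dir Output directory (created if needed).
#' @param threshold Primary hit z cut-off (default 2).
#' @param secondary Optional secondary-screen [screen_matrix()] or file path.
#' @param secondary_threshold Secondary cut-off (default 1).
#' @param expression Optional gene-to-expression table (data frame, named
#'   vector, or TSV path with columns `gene`, `value`).
#' @param som Either a [som_config()] or `NULL` to skip clustering.
#' @param include_controls Passed to [compute_zscores()].
#' @param curves Optional standard curves for Ct input (see
#'   [quantify_screen()]).
#' @return Invisibly, a list with the in-memory stage results: `matrix`,
#'   `zscores`, `hits`, `classification`, `clusters`, `qc`, `manifest`.
#' @export
run_screen_pipeline <- function(input, out_dir, threshold = 2,
                                secondary = NULL, secondary_threshold = 1,
                                expression = NULL, som = som_config(),
                                include_controls = FALSE, curves = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(
    package = "p53screen",
    version = as.character(utils::packageVersion("p53screen")),
    thresholds = list(primary = threshold, secondary = secondary_threshold),
    include_controls = include_controls,
    stages = list()
  )
  log_stage <- function(name, n) {
    manifest$stages[[name]] <<- list(rows = n)
    message(sprintf("[%s] %d rows", name, n))
  }

  if (is.character(input)) {
    manifest$input <- list(path = input,
                           md5 = unname(tools::md5sum(input)))
    input <- read_screen_table(input, schema = "normalized_long")
  }
  if (inherits(input, "ct_records")) {
    quant <- quantify_screen(input, curves = curves)
    mat <- quant$matrix
    utils::write.table(quant$qc, file.path(out_dir, "quantification_qc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_stage("quantify", length(mat$genes))
  } else {
    mat <- validate_screen_matrix(input)
  }
  log_stage("input", length(mat$genes))

  ztable <- compute_zscores(mat, include_controls = include_controls)
  log_stage("zscore", length(ztable$genes))
  hits <- call_hits(ztable, threshold = threshold)
  log_stage("call_hits", nrow(hits))
  classification <- classify_regulators(hits, genes = mat$genes[mat$role == "library"])
  log_stage("classify", nrow(classification$table))

  if (!is.null(secondary)) {
    if (is.character(secondary)) {
      manifest$secondary_input <- list(path = secondary,
                                       md5 = unname(tools::md5sum(secondary)))
      secondary <- read_screen_table(secondary, schema = "normalized_long")
    }
    classification <- validate_secondary(classification, secondary,
                                         threshold = secondary_threshold)
    log_stage("validate_secondary", sum(classification$table$secondary_status !=
                                          "not_retested"))
  } else {
    warning("no secondary screen provided; secondary_status left not_retested")
  }
  if (!is.null(expression)) {
    if (is.character(expression)) {
      manifest$expression_input <- list(path = expression,
                                        md5 = unname(tools::md5sum(expression)))
      expression <- utils::read.table(expression, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
    }
    classification <- flag_low_expression(classification, expression)
    log_stage("flag_low_expression", sum(classification$table$low_expression_flag))
  } else {
    warning("no expression table provided; low_expression_flag left FALSE")
  }
  write_hit_tables(classification, out_dir)

  clusters <- NULL
  if (!is.null(som)) {
    manifest$som <- unclass(som)
    model <- train_som(mat, config = som)
    clusters <- assign_clusters(model, mat)
    utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      cbind(unit = seq_len(nrow(model$codebook)), as.data.frame(model$codebook)),
      file.path(out_dir, "som_codebook.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    log_stage("cluster", nrow(clusters))
  }

  qc <- NULL
  if (!all(is.na(mat$plate)) && any(mat$role != "library")) {
    qc <- tryCatch(screen_qc_report(mat), error = function(e) {
      warning("QC stage failed and was skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(qc)) {
      utils::write.table(qc$ttests, file.path(out_dir, "qc_ttests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log_stage("qc", nrow(qc$ttests))
    }
  } else {
    warning("no plate/control annotation; QC stage skipped")
  }

  write_screen_table(mat, file.path(out_dir, "normalized_matrix.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(matrix = mat, zscores = ztable, hits = hits,
                 classification = classification, clusters = clusters,
                 qc = qc, manifest = manifest))
}
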