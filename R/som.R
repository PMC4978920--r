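#' Self-organizing map configuration
#'
#' Training configuration for [train_som()]. The defaults reproduce the
#' documented default behavior of the classical R SOM implementation widely
#' used for expression profiling: a 5 x 5 hexagonal grid, bubble
#' neighborhood, learning rate decaying linearly from 0.05 to 0.01, and a
#' neighborhood radius starting at the 2/3 quantile of inter-unit grid
#' distances and decaying linearly to zero over training, so that late
#' updates touch the winning unit only.
#'
#' @param rows,cols Grid dimensions (default 5 x 5, i.e. 25 clusters).
#' @param iterations Number of passes over the full data set (default 100).
#'   Each pass presents every complete-profile gene once, in seeded random
#'   order.
#' @param alpha_start,alpha_end Learning rate bounds, linear decay
#'   (defaults 0.05 and 0.01).
#' @param radius_start Initial neighborhood radius in grid-distance units;
#'   `NULL` (default) means the 2/3 quantile of pairwise inter-unit
#'   distances.
#' @param neighborhood `"bubble"` (full-strength update for units within the
#'   radius; default) or `"gaussian"`.
#' @param topology `"hexagonal"` (default) or `"rectangular"` unit layout.
#' @param seed Integer seed controlling codebook initialization and
#'   presentation order.
#' @return A `som_config` list.
#' @export
som_config <- function(rows = 5, cols = 5, iterations = 100,
                       alpha_start = 0.05, alpha_end = 0.01,
                       radius_start = NULL,
                       neighborhood = c("bubble", "gaussian"),
                       topology = c("hexagonal", "rectangular"),
                       seed = 1L) {
  neighborhood <- match.arg(neighborhood)
  topology <- match.arg(topology)
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 2 || rows * cols == 1,
            iterations >= 1, alpha_start >= alpha_end, alpha_end > 0)
  structure(list(rows = rows, cols = cols, iterations = iterations,
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 radius_start = radius_start, neighborhood = neighborhood,
                 topology = topology, seed = as.integer(seed)),
            class = "som_config")
}

# Grid coordinates of the units, row-major from the top-left (unit 1 = top
# left), 1-based. Hexagonal layout offsets every second row by half a unit.
som_unit_coords <- function(rows, cols, topology) {
  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  if (topology == "hexagonal") {
    x <- c_ + ifelse(r %% 2 == 0, 0.5, 0)
    y <- r * sqrt(3) / 2
  } else {
    x <- c_
    y <- as.numeric(r)
  }
  cbind(x = x, y = y)
}

#' Train a self-organizing map on screen profiles
#'
#' Online (sequential) Kohonen training of a grid of prototype vectors on the
#' six-condition expression profiles of a screen. Genes with any missing
#' condition are excluded from training and listed in the result. The
#' codebook is initialized by sampling data rows without replacement; each
#' pass presents all rows in a fresh seeded random order; for each
#' presentation the best-matching unit (BMU) is found by Euclidean distance
#' and every unit `i` is moved by
#' `w_i <- w_i + alpha(t) * h(i, bmu, t) * (x - w_i)`, with linearly decaying
#' learning rate and radius. All updates are convex combinations, so the
#' codebook remains inside the data bounding box. Training is deterministic
#' given the seed.
#'
#' @param x A [screen_matrix()] (profiles are used as-is; see `scale`).
#' @param config A [som_config()].
#' @param scale If `TRUE`, columns are z-scaled before training (default
#'   `FALSE`: normalized expression values are used directly).
#' @return An object of class `som_model`: list with `config`, `codebook`
#'   ((rows*cols) x 6 matrix, row-major unit order), `unit_coords`,
#'   `trained_genes`, `excluded_genes`, and `scale_pars` (`NULL` unless
#'   `scale`).
#' @export
train_som <- function(x, config = som_config(), scale = FALSE) {
  validate_screen_matrix(x)
  stopifnot(inherits(config, "som_config"))
  complete <- stats::complete.cases(x$values)
  data <- x$values[complete, , drop = FALSE]
  n_units <- config$rows * config$cols
  if (nrow(data) < 2) stop("cannot train: fewer than 2 complete profiles")
  if (nrow(data) < n_units) {
    warning("fewer complete profiles (", nrow(data), ") than units (", n_units, ")")
  }
  scale_pars <- NULL
  if (scale) {
    ctr <- colMeans(data)
    scl <- apply(data, 2, stats::sd)
    scl[scl == 0] <- 1
    data <- sweep(sweep(data, 2, ctr), 2, scl, "/")
    scale_pars <- list(center = ctr, scale = scl)
  }
  coords <- som_unit_coords(config$rows, config$cols, config$topology)
  grid_dist <- as.matrix(stats::dist(coords))
  radius0 <- config$radius_start
  if (is.null(radius0)) {
    radius0 <- unname(stats::quantile(grid_dist[upper.tri(grid_dist)], 2 / 3))
  }
  if (n_units == 1) radius0 <- 0

  set.seed(config$seed)
  init_idx <- sample.int(nrow(data), n_units, replace = nrow(data) < n_units)
  codebook <- data[init_idx, , drop = FALSE]
  rownames(codebook) <- NULL

  n <- nrow(data)
  total_steps <- config$iterations * n
  step <- 0L
  for (pass in seq_len(config$iterations)) {
    ord <- sample.int(n)
    for (i in ord) {
      frac <- step / max(total_steps - 1L, 1L)
      alpha <- config$alpha_start - (config$alpha_start - config$alpha_end) * frac
      radius <- radius0 * (1 - frac)
      xi <- data[i, ]
      d2 <- rowSums((codebook - matrix(xi, n_units, ncol(data), byrow = TRUE))^2)
      bmu <- which.min(d2)
      if (config$neighborhood == "bubble") {
        upd <- which(grid_dist[, bmu] <= radius)
        codebook[upd, ] <- codebook[upd, , drop = FALSE] +
          alpha * (matrix(xi, length(upd), ncol(data), byrow = TRUE) -
                     codebook[upd, , drop = FALSE])
      } else {
        h <- if (radius > 0) exp(-grid_dist[, bmu]^2 / (2 * radius^2)) else
          as.numeric(seq_len(n_units) == bmu)
        codebook <- codebook + (alpha * h) *
          (matrix(xi, n_units, ncol(data), byrow = TRUE) - codebook)
      }
      step <- step + 1L
    }
  }
  structure(
    list(config = config, codebook = codebook, unit_coords = coords,
         trained_genes = x$genes[complete], excluded_genes = x$genes[!complete],
         scale_pars = scale_pars),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$config$rows, "x", x$config$cols, "grid (",
      nrow(x$codebook), "units ),", x$config$iterations, "passes,",
      length(x$trained_genes), "profiles\n")
  invisible(x)
}

#' Assign genes to their best-matching SOM unit
#'
#' Maps every complete-profile gene to the codebook unit at minimal Euclidean
#' distance. Ties are broken deterministically toward the lowest unit id
#' (units numbered 1..rows*cols, row-major from the top-left). The per-gene
#' distance to the winning unit is the quantization error; its mean is the
#' standard diagnostic of map fit.
#'
#' @param model A [train_som()] result.
#' @param x A [screen_matrix()] with the same six conditions used in
#'   training.
#' @return An object of class `cluster_assignment`: data frame with columns
#'   `gene`, `unit`, `quantization_error`; mean quantization error in
#'   `attr(, "mean_qe")`.
#' @export
assign_clusters <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  validate_screen_matrix(x)
  if (ncol(x$values) != ncol(model$codebook)) {
    stop("shape error: profile dimensionality does not match codebook")
  }
  complete <- stats::complete.cases(x$values)
  data <- x$values[complete, , drop = FALSE]
  if (!is.null(model$scale_pars)) {
    data <- sweep(sweep(data, 2, model$scale_pars$center), 2,
                  model$scale_pars$scale, "/")
  }
  n_units <- nrow(model$codebook)
  unit <- integer(nrow(data))
  qe <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    d <- sqrt(rowSums((model$codebook -
                         matrix(data[i, ], n_units, ncol(data), byrow = TRUE))^2))
    unit[i] <- which.min(d)  # which.min returns the first (lowest id) on ties
    qe[i] <- d[unit[i]]
  }
  out <- data.frame(gene = x$genes[complete], unit = unit,
                    quantization_error = qe, stringsAsFactors = FALSE)
  structure(out, mean_qe = mean(qe), class = c("cluster_assignment", "data.frame"))
}

#' Summarize SOM clusters
#'
#' Per-cluster membership and mean expression profile over the six
#' conditions — the content of a cluster-panel figure. Empty clusters are
#' listed with count 0 and missing means.
#'
#' @param assignment An [assign_clusters()] result.
#' @param x The [screen_matrix()] the assignment was computed on.
#' @param n_units Total number of units (defaults to the maximum assigned
#'   unit; pass `rows * cols` to list trailing empty clusters).
#' @return Data frame with columns `unit`, `n`, `members`
#'   (comma-separated gene symbols), and the six per-condition means.
#' @export
summarize_clusters <- function(assignment, x, n_units = max(assignment$unit)) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  validate_screen_matrix(x)
  row_of <- match(assignment$gene, x$genes)
  out <- data.frame(unit = seq_len(n_units), n = 0L,
                    members = "", stringsAsFactors = FALSE)
  means <- matrix(NA_real_, n_units, length(CONDITIONS),
                  dimnames = list(NULL, CONDITIONS))
  for (u in seq_len(n_units)) {
    sel <- assignment$unit == u
    out$n[u] <- sum(sel)
    if (any(sel)) {
      out$members[u] <- paste(assignment$gene[sel], collapse = ",")
      means[u, ] <- colMeans(x$values[row_of[sel], , drop = FALSE], na.rm = TRUE)
    }
  }
  cbind(out, as.data.frame(means))
}
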