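#' Z-score marker intensities per batch
#'
#' Standardizes each intensity channel within each staining/imaging batch
#' (population denominator), so that intensities from samples processed or
#' imaged on different days become comparable.
#'
#' @param table Data frame with one row per cell.
#' @param channels Character vector of intensity column names.
#' @param batch Optional name of the batch column; `NULL` treats the whole
#'   table as one batch.
#' @return The table with added columns `z_<channel>`.
#' @export
zscore_channels <- function(table, channels, batch = NULL) {
  groups <- if (is.null(batch)) rep(1L, nrow(table)) else table[[batch]]
  for (ch in channels) {
    if (is.null(table[[ch]])) abort(sprintf("channel '%s' not found", ch))
    z <- numeric(nrow(table))
    for (g in unique(groups)) {
      i <- which(groups == g)
      if (length(i) < 2) abort(sprintf("batch '%s' has fewer than 2 cells", g))
      mu <- mean(table[[ch]][i])
      s <- sqrt(mean((table[[ch]][i] - mu)^2)) # population sd
      if (s == 0) {
        abort(sprintf("channel '%s' has zero variance in batch '%s'", ch, g))
      }
      z[i] <- (table[[ch]][i] - mu) / s
    }
    table[[paste0("z_", ch)]] <- z
  }
  table
}

#' Classify cells by k-means on z-scored intensities
#'
#' Runs k-means (k-means++-style multi-start via `nstart`) on the z-scored
#' channels and assigns type labels. Cluster indices are arbitrary, so the
#' cluster with the higher mean z-score in the first channel receives the
#' first label; labels are therefore invariant to cluster-index
#' permutation.
#'
#' @param table Output of [zscore_channels()].
#' @param channels Intensity channel names (their `z_` columns are used).
#' @param k Number of clusters (default 2).
#' @param labels Labels to assign, ordered by decreasing mean first-channel
#'   z-score; defaults to `cluster1..clusterk`.
#' @param nstart Random restarts.
#' @param seed Integer seed (recorded in the `kmeans` attribute).
#' @return The table with an `assigned_label` column; the fitted `kmeans`
#'   object (with `seed`) is kept in the `kmeans` attribute. `k = 1`
#'   assigns a single label and flags the clustering as degenerate.
#' @export
kmeans_classify <- function(table, channels, k = 2, labels = NULL,
                            nstart = 10, seed = 1) {
  zcols <- paste0("z_", channels)
  if (!all(zcols %in% names(table))) abort("run zscore_channels() first")
  x <- as.matrix(table[zcols])
  if (nrow(x) < k) abort("fewer cells than clusters")
  if (nrow(unique(x)) < k) abort("fewer distinct intensity profiles than clusters")
  labels <- labels %||% paste0("cluster", seq_len(k))
  if (k == 1) {
    warn("k = 1: degenerate clustering, all cells get one label")
    table$assigned_label <- labels[1]
    return(table)
  }
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = nstart)
  ord <- order(km$centers[, 1], decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  table$assigned_label <- labels[relabel[km$cluster]]
  km$seed <- seed
  attr(table, "kmeans") <- km
  table
}

#' Classify cells by a z-score threshold
#'
#' Marks cells positive for a channel when their z-score strictly exceeds
#' `z_threshold` — the simple rule that k-means clustering is used to
#' cross-check.
#'
#' @param table Output of [zscore_channels()].
#' @param channel Channel name.
#' @param z_threshold Threshold on the z-score.
#' @return The table with a logical `positive` column. If an
#'   `assigned_label` column from [kmeans_classify()] is present, the
#'   agreement rate with it is stored in the `kmeans_agreement` attribute.
#' @export
threshold_classify <- function(table, channel, z_threshold = 0) {
  zcol <- paste0("z_", channel)
  if (is.null(table[[zcol]])) abort("run zscore_channels() first")
  table$positive <- table[[zcol]] > z_threshold
  if (!is.null(table[["assigned_label"]])) {
    lab_pos <- names(which.max(tapply(table[[zcol]], table$assigned_label, mean)))
    attr(table, "kmeans_agreement") <-
      mean(table$positive == (table$assigned_label == lab_pos))
  }
  table
}

#' Estimate RNAscope transcript dot counts
#'
#' Converts each cell's integrated probe fluorescence into an estimated
#' number of transcript puncta:
#' `(integrated_intensity - background_per_px * area_px) / single_dot_intensity`,
#' floored at 0. The single-dot intensity is calibrated as the mean
#' integrated intensity of isolated single dots (at least ~21 of them);
#' `background_per_px` is the mean per-pixel intensity of a cell-free
#' region. Non-integer dot numbers are retained: the positivity thresholds
#' compare the real value.
#'
#' @param integrated_intensity Summed probe intensity over the cell.
#' @param area_px Cell area in pixels.
#' @param background_per_px Mean background intensity per pixel.
#' @param single_dot_intensity Mean integrated intensity of one dot (> 0).
#' @return Tibble: `dot_number` (floored at 0) and `floored` (whether the
#'   raw formula was negative).
#' @examples
#' count_dots(5000, 1000, 1, 40)$dot_number # 100
#' @export
count_dots <- function(integrated_intensity, area_px, background_per_px,
                       single_dot_intensity) {
  if (any(single_dot_intensity <= 0)) abort("single-dot intensity must be positive")
  if (any(area_px <= 0)) abort("cell area must be positive")
  raw <- (integrated_intensity - background_per_px * area_px) / single_dot_intensity
  tibble::tibble(dot_number = pmax(raw, 0), floored = raw < 0)
}

#' Probe positivity from dot counts
#'
#' Strict thresholds on the estimated dot number: a cell is positive for a
#' probe only when its dot number is strictly greater than the probe's
#' threshold (defaults: BNC2 40 dots, FSTL4 80 dots).
#'
#' @param dot_number Estimated dot numbers.
#' @param probe Probe name; must appear in `thresholds`.
#' @param thresholds Named numeric vector of dot thresholds.
#' @return Logical vector.
#' @export
call_probe_positive <- function(dot_number, probe,
                                thresholds = c(BNC2 = 40, FSTL4 = 80)) {
  if (!probe %in% names(thresholds)) {
    abort(sprintf("unknown probe '%s'; thresholds are defined for: %s",
                  probe, paste(names(thresholds), collapse = ", ")))
  }
  dot_number > thresholds[[probe]]
}

#' Screen cluster pairs for excluding marker expression
#'
#' For each (foveal, peripheral) cluster pair and each screened gene,
#' compares expression between the two clusters: a pair is excluded as a
#' candidate when any screened gene differs by more than 2 natural-log fold
#' (difference of log mean normalized counts) with P < 0.05 by two-sided
#' Wilcoxon rank-sum test. Counts are library-size normalized (counts per
#' median library size) before comparison.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param clusters Data frame `cell`, `cluster` covering the columns of
#'   `counts`.
#' @param cluster_pairs Data frame `foveal`, `peripheral`.
#' @param genes Genes to screen (must be rows of `counts`).
#' @param log_fold_cut,p_cut Exclusion thresholds (strict `>` and `<`).
#' @param pseudocount Added to mean normalized counts before taking logs.
#' @return Tibble of class `screen_result`, one row per pair x gene:
#'   `foveal`, `peripheral`, `gene`, `log_fold` (peripheral minus foveal),
#'   `p_value`, `gene_excluding`; plus per-pair `excluded` (any screened
#'   gene excluding).
#' @export
marker_screen <- function(counts, clusters, cluster_pairs, genes,
                          log_fold_cut = 2, p_cut = 0.05, pseudocount = 1) {
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes)) {
    abort(sprintf("genes absent from the matrix: %s",
                  paste(missing_genes, collapse = ", ")))
  }
  lib <- colSums(counts)
  norm <- sweep(counts, 2, lib / median(lib), "/")
  res <- purrr::map_dfr(seq_len(nrow(cluster_pairs)), function(i) {
    fov <- cluster_pairs$foveal[i]
    per <- cluster_pairs$peripheral[i]
    fcells <- clusters$cell[clusters$cluster == fov]
    pcells <- clusters$cell[clusters$cluster == per]
    if (length(fcells) == 0 || length(pcells) == 0) {
      abort(sprintf("cluster pair (%s, %s) has an empty member", fov, per))
    }
    purrr::map_dfr(genes, function(g) {
      xf <- norm[g, fcells]
      xp <- norm[g, pcells]
      lfc <- log(mean(xp) + pseudocount) - log(mean(xf) + pseudocount)
      p <- if (length(unique(c(xf, xp))) == 1) 1 else
        suppressWarnings(wilcox.test(xp, xf)$p.value)
      tibble::tibble(foveal = fov, peripheral = per, gene = g,
                     log_fold = lfc, p_value = p,
                     gene_excluding = abs(lfc) > log_fold_cut & p < p_cut)
    })
  })
  out <- res |>
    dplyr::group_by(.data$foveal, .data$peripheral) |>
    dplyr::mutate(excluded = any(.data$gene_excluding)) |>
    dplyr::ungroup()
  class(out) <- c("screen_result", class(out))
  out
}

#' Dot-plot statistics per cluster and gene
#'
#' The two numbers a transcriptomic dot plot encodes: the percentage of
#' cells in a cluster with nonzero counts for the gene, and the mean count
#' among those expressing cells (undefined, `NA`, when no cell expresses
#' it).
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param clusters Data frame `cell`, `cluster`.
#' @param genes Genes to tabulate.
#' @return Tibble: `cluster`, `gene`, `pct_expressing`,
#'   `mean_in_expressing`.
#' @export
dotplot_stats <- function(counts, clusters, genes = rownames(counts)) {
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes)) {
    abort(sprintf("genes absent from the matrix: %s",
                  paste(missing_genes, collapse = ", ")))
  }
  purrr::map_dfr(unique(clusters$cluster), function(cl) {
    cells <- clusters$cell[clusters$cluster == cl]
    purrr::map_dfr(genes, function(g) {
      x <- counts[g, cells]
      expressing <- x > 0
      tibble::tibble(
        cluster = cl, gene = g,
        pct_expressing = 100 * mean(expressing),
        mean_in_expressing = if (any(expressing)) mean(x[expressing]) else NA_real_
      )
    })
  })
}

#' Write / read an expression matrix as MatrixMarket plus label CSV
#'
#' @param x A list as returned by [synth_expression()].
#' @param dir Output directory; files `counts.mtx`, `genes.txt`,
#'   `cells.csv` are written there.
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.txt"))
  utils::write.csv(x$clusters, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.txt"))
  clusters <- tibble::as_tibble(utils::read.csv(file.path(dir, "cells.csv")))
  rownames(counts) <- genes
  colnames(counts) <- clusters$cell
  list(counts = counts, clusters = clusters)
}
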