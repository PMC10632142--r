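#' Simulate a marker-intensity table
#'
#' Draws per-cell immunofluorescence intensities from class-conditional
#' Gaussians, emulating the bimodal two-marker tables (e.g. BNC2 and FOXP2
#' nuclear intensity) used to split a labelled population into types. True
#' class labels are retained for scoring classifiers.
#'
#' @param n_cells Number of cells.
#' @param class_fractions Named numeric vector of class proportions, summing
#'   to 1.
#' @param channel_means Matrix (classes x channels) of mean intensities;
#'   row names are classes, column names channels.
#' @param channel_sds Matrix like `channel_means` with positive sds (or a
#'   scalar).
#' @param batch Optional number of batches; cells are split evenly and each
#'   batch `b > 1` gets a random gain/offset, emulating day-to-day staining
#'   differences that per-batch z-scoring must remove.
#' @param seed Integer seed.
#' @return Tibble: `cell_id`, `batch`, `true_class`, one intensity column
#'   per channel.
#' @export
synth_marker_table <- function(n_cells,
                               class_fractions = c(pos = 0.5, neg = 0.5),
                               channel_means,
                               channel_sds = 1,
                               batch = 1,
                               seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-8) abort("class fractions must sum to 1")
  if (any(channel_sds <= 0)) abort("channel sds must be positive")
  classes <- names(class_fractions)
  if (is.null(classes)) abort("`class_fractions` must be named by class")
  if (!is.matrix(channel_means)) {
    channel_means <- matrix(channel_means, nrow = length(classes),
                            dimnames = list(classes, paste0("ch", seq_len(length(channel_means) / length(classes)))))
  }
  channels <- colnames(channel_means)
  if (!is.matrix(channel_sds)) {
    channel_sds <- matrix(channel_sds, nrow(channel_means), ncol(channel_means),
                          dimnames = dimnames(channel_means))
  }
  set.seed(seed)
  lab <- sample(classes, n_cells, replace = TRUE, prob = class_fractions)
  out <- tibble::tibble(
    cell_id = seq_len(n_cells),
    batch = rep_len(seq_len(batch), n_cells),
    true_class = lab
  )
  for (ch in channels) {
    out[[ch]] <- rnorm(n_cells, channel_means[lab, ch], channel_sds[lab, ch])
  }
  # per-batch affine distortions (gain, offset) beyond batch 1
  if (batch > 1) {
    gain <- c(1, stats::runif(batch - 1, 0.5, 2))
    offs <- c(0, stats::runif(batch - 1, -5, 5))
    for (ch in channels) {
      out[[ch]] <- out[[ch]] * gain[out$batch] + offs[out$batch]
    }
  }
  out
}

#' Simulate a two-condition expression count matrix
#'
#' Negative-binomial counts for paired cell clusters (e.g. a peripheral
#' retinal ganglion cell type and its foveal counterpart), with designated
#' genes shifted by a specified natural-log fold change between the members
#' of each pair. Used to exercise the marker screen with known ground
#' truth.
#'
#' @param n_genes Number of genes (named gene1..geneN).
#' @param cluster_pairs Data frame with columns `foveal`, `peripheral`
#'   (cluster labels); every peripheral cluster must have a foveal partner.
#' @param cells_per_cluster Cells per cluster.
#' @param base_mean Mean count of an unperturbed gene.
#' @param dispersion NB dispersion (size parameter).
#' @param log_fold Named list: `log_fold[[gene]][[peripheral cluster]]` =
#'   natural-log fold change applied to the peripheral member relative to
#'   its foveal partner. Alternatively a data frame `gene`, `peripheral`,
#'   `log_fold`.
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells matrix), `clusters` (tibble
#'   `cell`, `cluster`), `cluster_pairs`.
#' @export
synth_expression <- function(n_genes = 50,
                             cluster_pairs = tibble::tibble(
                               foveal = "fRGC1", peripheral = "pRGC1"),
                             cells_per_cluster = 200,
                             base_mean = 20,
                             dispersion = 2,
                             log_fold = NULL,
                             seed = 1) {
  if (any(is.na(cluster_pairs$foveal)) || any(is.na(cluster_pairs$peripheral))) {
    abort("every peripheral cluster needs a foveal partner")
  }
  if (is.data.frame(log_fold)) {
    lf <- log_fold
  } else if (is.null(log_fold)) {
    lf <- tibble::tibble(gene = character(), peripheral = character(),
                         log_fold = numeric())
  } else {
    lf <- purrr::imap_dfr(log_fold, function(per_cl, g)
      tibble::tibble(gene = g, peripheral = names(per_cl),
                     log_fold = unname(unlist(per_cl))))
  }
  set.seed(seed)
  clusters <- c(rbind(cluster_pairs$foveal, cluster_pairs$peripheral))
  genes <- paste0("gene", seq_len(n_genes))
  cell_tbl <- tidyr::expand_grid(cluster = clusters,
                                 idx = seq_len(cells_per_cluster)) |>
    dplyr::mutate(cell = paste0(.data$cluster, "_c", .data$idx)) |>
    dplyr::select("cell", "cluster")
  counts <- matrix(0L, n_genes, nrow(cell_tbl),
                   dimnames = list(genes, cell_tbl$cell))
  for (cl in clusters) {
    cols <- which(cell_tbl$cluster == cl)
    mu <- rep(base_mean, n_genes)
    hit <- lf[lf$peripheral == cl, ]
    if (nrow(hit)) {
      gi <- match(hit$gene, genes)
      if (anyNA(gi)) abort("log_fold refers to a gene outside the matrix")
      mu[gi] <- mu[gi] * exp(hit$log_fold)
    }
    counts[, cols] <- rnbinom(n_genes * length(cols), mu = mu, size = dispersion)
  }
  list(counts = counts, clusters = cell_tbl, cluster_pairs = cluster_pairs)
}
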