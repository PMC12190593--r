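# Functional connectivity: Pearson correlation matrices over band-filtered
# channel time courses, binarized at a threshold into an undirected graph,
# summarized by node degree k_i = sum_j a_ij and local clustering
# C_i = 2 E_i / (k_i (k_i - 1)), where E_i counts edges among node i's
# neighbours (equivalently, triangles through i).

#' Pearson correlation matrix across channels
#'
#' Pairwise Pearson correlations over the full time course of every channel
#' pair, typically computed on a band-filtered recording. Symmetry is
#' enforced exactly.
#'
#' @param rec An `eeg_recording` (usually the output of [bandpass()]).
#' @return A `corr_matrix`: `r` (n x n symmetric, unit diagonal), `channels`,
#'   `band` (label of the filtering band if present, else `"broadband"`).
#' @export
correlation_matrix <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$channels) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (ncol(rec$data) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(rec$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance channel: ",
         paste(rec$channels[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(rec$data))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  band <- attr(rec, "band")
  structure(list(r = r, channels = rec$channels,
                 band = if (is.null(band)) "broadband" else band$name),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("<corr_matrix> %d channels (%s band), off-diagonal r: %.2f..%.2f\n",
              length(x$channels), x$band, min(off), max(off)))
  invisible(x)
}

#' Binarize a correlation matrix into a network
#'
#' An edge joins channels i and j iff `r_ij >= threshold` (signed comparison;
#' set `absolute = TRUE` to threshold `|r|` instead). Node degree and local
#' clustering coefficients are computed on the resulting undirected graph;
#' clustering is defined 0 for nodes of degree below 2.
#'
#' @param cm A `corr_matrix`.
#' @param threshold Correlation threshold in (0, 1). The study used 0.32
#'   (delta) and 0.56 (gamma) for the working-memory contrast, and 0.43/0.67
#'   for the stimulation contrast.
#' @param absolute Threshold on `|r|` instead of signed `r`; default FALSE.
#' @return A `binary_network`: `adjacency` (0/1, hollow, symmetric),
#'   `threshold`, `degree`, `clustering`, `density`, `channels`, `band`.
#' @export
binarize <- function(cm, threshold, absolute = FALSE) {
  stopifnot(inherits(cm, "corr_matrix"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)", call. = FALSE)
  r <- if (absolute) abs(cm$r) else cm$r
  adj <- (r >= threshold) * 1L
  diag(adj) <- 0L
  n <- nrow(adj)
  degree <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2      # E_i: edges among neighbours
  clustering <- ifelse(degree >= 2, 2 * tri / (degree * (degree - 1)), 0)
  structure(list(adjacency = adj, threshold = threshold,
                 degree = stats::setNames(degree, cm$channels),
                 clustering = stats::setNames(clustering, cm$channels),
                 density = sum(adj) / (n * (n - 1)),
                 channels = cm$channels, band = cm$band),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf(
    "<binary_network> %d nodes (%s band), threshold %.2f, density %.3f\n  mean degree %.2f, mean clustering %.3f\n",
    length(x$channels), x$band, x$threshold, x$density,
    mean(x$degree), mean(x$clustering)))
  invisible(x)
}

#' Select a correlation threshold on a 0.01 grid
#'
#' Scans thresholds 0.01, 0.02, ..., 0.99 and returns the largest one whose
#' binarized network has no isolated node and a density inside
#' `density_range` - the usual criteria of no isolated nodes, appropriate
#' density, and valid topological parameters. If no grid value satisfies
#' both, the largest no-isolated-node threshold is returned with a warning;
#' if even that fails the input is essentially uncorrelated and an error is
#' raised.
#'
#' @param cm A `corr_matrix`.
#' @param density_range Length-2 numeric in (0, 1), default `c(0.05, 0.45)`.
#' @param absolute Passed to [binarize()].
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(cm, density_range = c(0.05, 0.45), absolute = FALSE) {
  stopifnot(inherits(cm, "corr_matrix"))
  if (length(density_range) != 2L || density_range[1] <= 0 ||
      density_range[2] >= 1 || density_range[1] >= density_range[2]) {
    stop("density_range must be an increasing pair inside (0, 1)", call. = FALSE)
  }
  grid <- round(seq(0.99, 0.01, by = -0.01), 2)  # canonical grid doubles
  fallback <- NA_real_
  for (th in grid) {
    net <- binarize(cm, th, absolute)
    if (all(net$degree > 0)) {
      if (is.na(fallback)) fallback <- th
      if (net$density >= density_range[1] && net$density <= density_range[2]) {
        return(th)
      }
    }
  }
  if (!is.na(fallback)) {
    warning(sprintf(
      "no threshold gives density in [%.2f, %.2f]; using largest with no isolated node (%.2f)",
      density_range[1], density_range[2], fallback), call. = FALSE)
    return(fallback)
  }
  stop("no threshold yields a network without isolated nodes", call. = FALSE)
}

#' Per-channel network features
#'
#' Degree and clustering coefficient per channel, plus whole-network mean
#' rows under channel `"whole_brain"`.
#'
#' @param net A `binary_network`.
#' @return A tibble with columns `channel`, `feature_name` (`"degree"`,
#'   `"clustering"`), `band`, `value`.
#' @export
network_features <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  dplyr::bind_rows(
    tibble::tibble(channel = net$channels, feature_name = "degree",
                   band = net$band, value = as.numeric(net$degree)),
    tibble::tibble(channel = net$channels, feature_name = "clustering",
                   band = net$band, value = as.numeric(net$clustering)),
    tibble::tibble(channel = "whole_brain",
                   feature_name = c("degree", "clustering"),
                   band = net$band,
                   value = c(mean(net$degree), mean(net$clustering)))
  )
}

#' Export a binary network as an edge list
#'
#' @param net A `binary_network`.
#' @param path Optional CSV destination; when given, the edge list is written
#'   there.
#' @return A tibble with columns `channel_a`, `channel_b`, one row per edge,
#'   invisibly when `path` is given.
#' @export
edge_list <- function(net, path = NULL) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  el <- tibble::tibble(channel_a = net$channels[idx[, 1L]],
                       channel_b = net$channels[idx[, 2L]])
  if (!is.null(path)) {
    readr::write_csv(el, path)
    return(invisible(el))
  }
  el
}
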