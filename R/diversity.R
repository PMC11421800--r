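.counts_of <- function(x) {
  if (methods::is(x, "StormExperiment")) asvCounts(x) else as.matrix(x)
}

#' Rarefy a count matrix to even depth
#'
#' Each sample (column) is replaced by a uniform random subsample without
#' replacement of exactly \code{depth} reads, making richness and Shannon
#' entropy comparable across unequal library sizes. ASVs left with zero total
#' count are dropped. A sample whose library is smaller than \code{depth} is
#' an error (samples are never silently discarded).
#'
#' @param x a \code{\linkS4class{StormExperiment}} or ASV-by-day count matrix.
#' @param depth target reads per sample (default 4000).
#' @param seed optional integer seed for the subsampling draw; the main
#'   analysis is a single draw at a recorded seed.
#' @return object of the same type as \code{x} with every column summing to
#'   \code{depth}.
#' @export
rarefyCounts <- function(x, depth = 4000, seed = NULL) {
  counts <- .counts_of(x)
  short <- colSums(counts) < depth
  if (any(short))
    stop("sample(s) with fewer than ", depth, " reads: ",
         paste(colnames(counts)[short], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  # vegan nags when the smallest nonzero count exceeds 1; irrelevant here
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(rar) <- "integer"
  keep <- rowSums(rar) > 0
  rar <- rar[keep, , drop = FALSE]
  if (methods::is(x, "StormExperiment")) {
    out <- x[keep, ]
    SummarizedExperiment::assay(out, "counts") <- rar
    S4Vectors::metadata(out)$rarefaction <- list(depth = depth, seed = seed)
    out
  } else rar
}

#' Base-2 Shannon entropy of a community
#'
#' \code{H = -sum(p_i * log2(p_i))} over the proportions of taxa with
#' positive count (0 log 0 is treated as 0). Reported in bits.
#'
#' @param x a count vector, or a matrix whose columns are samples.
#' @return numeric entropy value(s).
#' @examples
#' shannonIndex(c(10, 10, 10, 10))  # 2 bits
#' @export
shannonIndex <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, shannonIndex))
  if (any(x < 0)) stop("counts must be nonnegative")
  if (sum(x) == 0) stop("undefined for an all-zero sample")
  unname(vegan::diversity(x, index = "shannon", base = 2))
}

#' Alpha diversity per sample day
#'
#' @param x a \code{\linkS4class{StormExperiment}} or count matrix (columns
#'   are days).
#' @return data.frame with \code{date}, \code{richness} (ASVs with positive
#'   count) and \code{shannon} (base-2 entropy).
#' @export
alphaDiversity <- function(x) {
  counts <- .counts_of(x)
  data.frame(date = as.Date(colnames(counts)),
             richness = colSums(counts > 0),
             shannon = shannonIndex(counts),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \code{sum(|u - v|) / sum(u + v)}: 0 for identical composition, 1 for
#' disjoint support.
#'
#' @param u,v equal-length nonnegative abundance vectors, not both all zero.
#' @return dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(6, 2), c(2, 2))  # 4/12
#' @export
brayCurtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be nonnegative")
  tot <- sum(u + v)
  if (tot == 0) stop("undefined when both samples are all zero")
  sum(abs(u - v)) / tot
}

#' Bray-Curtis dissimilarity matrix across sample days
#'
#' @param x a \code{\linkS4class{StormExperiment}} or count matrix.
#' @return symmetric matrix with zero diagonal, labeled by sample date.
#' @export
brayCurtisMatrix <- function(x) {
  counts <- .counts_of(x)
  m <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  dimnames(m) <- list(colnames(counts), colnames(counts))
  m
}

.resolve_dates <- function(all_dates, preevent) {
  if (is.null(preevent)) preevent <- utils::head(all_dates, 4)
  preevent <- as.character(as.Date(preevent))
  missing <- setdiff(preevent, all_dates)
  if (length(missing))
    stop("pre-event date(s) not among samples: ", paste(missing, collapse = ", "))
  preevent
}

#' Mean distance of each sample from the pre-event baseline
#'
#' For each sample day, the mean (and SD) of its dissimilarity to each of the
#' pre-event samples. By default the first four sample days define the
#' baseline and a pre-event day's zero self-distance is included in its own
#' mean; set \code{includeSelf = FALSE} to average only over the other
#' baseline days.
#'
#' @param dist symmetric dissimilarity matrix labeled by date (e.g. from
#'   \code{\link{brayCurtisMatrix}}).
#' @param preevent_dates baseline days (default: first four columns).
#' @param includeSelf include the self-pair for baseline days?
#' @return data.frame with \code{date}, \code{mean_dist}, \code{sd_dist}.
#' @export
meanPreeventDistance <- function(dist, preevent_dates = NULL,
                                 includeSelf = TRUE) {
  dates <- colnames(dist)
  pre <- .resolve_dates(dates, preevent_dates)
  if (!length(pre)) stop("pre-event set must be nonempty")
  res <- t(vapply(dates, function(l) {
    ref <- if (includeSelf) pre else setdiff(pre, l)
    d <- dist[l, ref]
    c(mean(d), if (length(d) > 1) stats::sd(d) else 0)
  }, numeric(2)))
  data.frame(date = as.Date(dates), mean_dist = res[, 1], sd_dist = res[, 2],
             row.names = NULL)
}

#' Mean Euclidean distance of a scalar series from its pre-event values
#'
#' The tracer analogue of \code{\link{meanPreeventDistance}}: per-day mean of
#' \code{|x_l - x_m|} over pre-event days \code{m} (e.g. for d2H or
#' d-excess).
#'
#' @param series named numeric vector keyed by ISO date.
#' @param preevent_dates baseline days (default: first four).
#' @param includeSelf include the self-pair for baseline days?
#' @return data.frame with \code{date}, \code{mean_dist}, \code{sd_dist}.
#' @export
meanPreeventEuclid <- function(series, preevent_dates = NULL,
                               includeSelf = TRUE) {
  dates <- names(series)
  if (is.null(dates)) stop("series must be named by date")
  pre <- .resolve_dates(dates, preevent_dates)
  res <- t(vapply(dates, function(l) {
    ref <- if (includeSelf) pre else setdiff(pre, l)
    d <- abs(series[l] - series[ref])
    c(mean(d), if (length(d) > 1) stats::sd(d) else 0)
  }, numeric(2)))
  data.frame(date = as.Date(dates), mean_dist = res[, 1], sd_dist = res[, 2],
             row.names = NULL)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of \code{-0.5 * D^2} followed by a symmetric
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues, ordered by decreasing eigenvalue.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are dropped from the embedding and recorded on the result.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal, >= 3
#'   samples.
#' @param n_axes number of axes to retain (default: all positive ones).
#' @return a \code{\linkS4class{PcoaResult}}.
#' @export
runPcoa <- function(dist, n_axes = NULL) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (is.null(n_axes)) n_axes <- n - 1
  if (n_axes > n - 1) stop("n_axes must be <= n_samples - 1")
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = n - 1,
                                         eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-10
  pos <- which(eig > tol)
  k <- min(n_axes, length(pos))
  coords <- if (k > 0) sc$points[, seq_len(k), drop = FALSE]
            else matrix(0, n, 0, dimnames = list(rownames(dist), NULL))
  if (k > 0) colnames(coords) <- paste0("PCo", seq_len(k))
  methods::new("PcoaResult",
    coordinates = coords,
    eigenvalues = eig[pos][seq_len(k)],
    proportionExplained = if (length(pos)) eig[pos][seq_len(k)] / sum(eig[pos])
                          else numeric(0),
    negativeEigenvalues = eig[eig < -tol])
}
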