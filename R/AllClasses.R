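#' The eight taxonomic groups used throughout the package
#'
#' Five phyla, the two large Proteobacteria subgroups, and a catch-all.
#' @export
TAXON_GROUPS <- c("Actinobacteriota", "Bacteroidota", "Cyanobacteria",
                  "Planctomycetota", "Verrucomicrobiota",
                  "Gammaproteobacteria", "Alphaproteobacteria", "Other")

#' The eight source-environment categories
#'
#' Habitat hits are collapsed onto these categories; unassigned ASVs fall to
#' \code{"other"}.
#' @export
SOURCE_ENVIRONMENTS <- c("freshwater", "sediment", "soil", "groundwater",
                         "biofilm", "marine", "sewage_wastewater", "other")

#' Discharge-response class labels
#' @export
CQ_CLASSES <- c("mobilized", "diluted", "static", "uncharacterized")

#' StormExperiment: daily ASV counts with hydrograph and isotope metadata
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} whose single
#' \code{"counts"} assay holds nonnegative integer ASV-by-day counts.
#' \code{colData} must contain a \code{date} column (class \code{Date},
#' strictly increasing) and may carry \code{discharge_cms} (> 0),
#' \code{precip_mm}, \code{d2H} and \code{d18O}. \code{rowData} may carry
#' \code{lineage}, \code{group} (one of \code{\link{TAXON_GROUPS}}) and,
#' for simulated objects, the ground-truth \code{true_class} and \code{beta}.
#'
#' @export
setClass("StormExperiment", contains = "SummarizedExperiment")

setValidity("StormExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)))
      msg <- c(msg, "counts must be finite")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
      if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"date" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'date' column")
  else {
    d <- cd$date
    if (anyDuplicated(d)) msg <- c(msg, "sample dates must be unique")
    if (is.unsorted(d, strictly = TRUE)) msg <- c(msg, "sample dates must be strictly increasing")
  }
  if ("discharge_cms" %in% colnames(cd)) {
    q <- cd$discharge_cms
    if (any(!is.finite(q)) || any(q <= 0))
      msg <- c(msg, "discharge_cms must be finite and > 0")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "ASV ids must be unique")
  if (length(msg)) msg else TRUE
})

#' PcoaResult: classical-scaling ordination of a sample dissimilarity matrix
#'
#' Coordinates are eigenvectors of the Gower-centered matrix scaled by the
#' square roots of their (positive) eigenvalues, ordered by decreasing
#' eigenvalue. Negative eigenvalues are dropped from the embedding and kept
#' in \code{negativeEigenvalues} for inspection; \code{proportionExplained}
#' is relative to the sum of positive eigenvalues.
#'
#' @slot coordinates numeric matrix, samples x retained axes.
#' @slot eigenvalues positive eigenvalues, non-increasing.
#' @slot proportionExplained per-axis share of the positive-eigenvalue total.
#' @slot negativeEigenvalues any negative eigenvalues of the centered matrix.
#' @export
setClass("PcoaResult",
  representation(coordinates = "matrix",
                 eigenvalues = "numeric",
                 proportionExplained = "numeric",
                 negativeEigenvalues = "numeric"))

setValidity("PcoaResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) && is.unsorted(rev(ev)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(ev) && any(ev < 0))
    msg <- c(msg, "retained eigenvalues must be nonnegative")
  pe <- object@proportionExplained
  if (length(pe) && sum(pe) > 1 + 1e-8)
    msg <- c(msg, "proportionExplained must sum to <= 1")
  if (ncol(object@coordinates) != length(pe))
    msg <- c(msg, "one proportionExplained entry per retained axis")
  if (length(msg)) msg else TRUE
})
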