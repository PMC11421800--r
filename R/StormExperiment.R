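#' Construct a StormExperiment
#'
#' Assembles ASV-by-day counts and per-day hydrograph / isotope measurements
#' into a validated container. All per-day vectors are matched to \code{dates}
#' positionally and must have the same length as \code{ncol(counts)}.
#'
#' @param counts nonnegative integer matrix, ASVs in rows, days in columns.
#'   Row names are ASV ids; they must be unique.
#' @param dates \code{Date} vector, one per column, strictly increasing.
#' @param discharge_cms optional daily mean discharge, cubic meters per second.
#' @param precip_mm optional daily precipitation depth, millimeters.
#' @param d2H,d18O optional stream stable-isotope ratios, permil VSMOW.
#' @param rowData optional \code{DataFrame}/data.frame of per-ASV annotation
#'   (e.g. \code{lineage}, \code{group}).
#' @param metadata optional list stored in the object metadata.
#' @return A \code{\linkS4class{StormExperiment}}.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, dimnames = list(c("asv1", "asv2"), NULL))
#' StormExperiment(m, as.Date(c("2020-10-06", "2020-10-07")),
#'                 discharge_cms = c(0.25, 0.30))
#' @export
StormExperiment <- function(counts, dates, discharge_cms = NULL,
                            precip_mm = NULL, d2H = NULL, d18O = NULL,
                            rowData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("asv_%04d", seq_len(nrow(counts)))
  dates <- as.Date(dates)
  if (length(dates) != ncol(counts))
    stop("need one date per count column")
  cd <- S4Vectors::DataFrame(date = dates, row.names = as.character(dates))
  for (nm in c("discharge_cms", "precip_mm", "d2H", "d18O")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != length(dates))
        stop("'", nm, "' must have one value per date")
      cd[[nm]] <- as.numeric(v)
    }
  }
  colnames(counts) <- as.character(dates)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, metadata = metadata)
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  methods::new("StormExperiment", se)
}

#' @rdname asvCounts
#' @export
setGeneric("asvCounts", function(x) standardGeneric("asvCounts"))

#' Accessors for StormExperiment
#'
#' \code{asvCounts} returns the ASV-by-day integer count matrix;
#' \code{sampleDates} the \code{Date} vector; \code{discharge} and
#' \code{precipitation} the hydrograph columns (or \code{NULL} when absent);
#' \code{isotopeSeries} a data.frame of \code{date}, \code{d2H}, \code{d18O}.
#'
#' @param x a \code{\linkS4class{StormExperiment}}.
#' @return See description; hydrograph accessors return named numeric vectors
#'   keyed by date.
#' @aliases asvCounts sampleDates discharge precipitation isotopeSeries
#' @export
setMethod("asvCounts", "StormExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname asvCounts
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname asvCounts
#' @export
setMethod("sampleDates", "StormExperiment", function(x)
  SummarizedExperiment::colData(x)$date)

.coldata_vector <- function(x, nm) {
  cd <- SummarizedExperiment::colData(x)
  if (!nm %in% colnames(cd)) return(NULL)
  stats::setNames(cd[[nm]], as.character(cd$date))
}

#' @rdname asvCounts
#' @export
setGeneric("discharge", function(x) standardGeneric("discharge"))

#' @rdname asvCounts
#' @export
setMethod("discharge", "StormExperiment", function(x)
  .coldata_vector(x, "discharge_cms"))

#' @rdname asvCounts
#' @export
setGeneric("precipitation", function(x) standardGeneric("precipitation"))

#' @rdname asvCounts
#' @export
setMethod("precipitation", "StormExperiment", function(x)
  .coldata_vector(x, "precip_mm"))

#' @rdname asvCounts
#' @export
setGeneric("isotopeSeries", function(x) standardGeneric("isotopeSeries"))

#' @rdname asvCounts
#' @export
setMethod("isotopeSeries", "StormExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("d2H", "d18O") %in% colnames(cd))) return(NULL)
  data.frame(date = cd$date, d2H = cd$d2H, d18O = cd$d18O)
})

setMethod("show", "StormExperiment", function(object) {
  cat("StormExperiment:", nrow(object), "ASVs x", ncol(object), "days\n")
  d <- sampleDates(object)
  if (length(d))
    cat("  dates: ", format(min(d)), " .. ", format(max(d)), "\n", sep = "")
  q <- discharge(object)
  if (!is.null(q))
    cat(sprintf("  discharge [CMS]: %.3g .. %.3g\n", min(q), max(q)))
  extras <- intersect(c("precip_mm", "d2H", "d18O"),
                      colnames(SummarizedExperiment::colData(object)))
  if (length(extras))
    cat("  colData also:", paste(extras, collapse = ", "), "\n")
  rd <- colnames(SummarizedExperiment::rowData(object))
  if (length(rd)) cat("  rowData:", paste(rd, collapse = ", "), "\n")
})

setMethod("show", "PcoaResult", function(object) {
  cat("PcoaResult:", nrow(object@coordinates), "samples,",
      ncol(object@coordinates), "axes\n")
  pe <- object@proportionExplained
  if (length(pe))
    cat("  proportion explained:",
        paste(sprintf("%.3f", utils::head(pe, 4)), collapse = ", "),
        if (length(pe) > 4) "..." else "", "\n")
  if (length(object@negativeEigenvalues))
    cat("  negative eigenvalues dropped:", length(object@negativeEigenvalues),
        sprintf("(largest magnitude %.3g)", max(abs(object@negativeEigenvalues))), "\n")
})

#' @rdname pcoaCoordinates
#' @export
setGeneric("pcoaCoordinates", function(x) standardGeneric("pcoaCoordinates"))

#' Accessors for PcoaResult
#'
#' @param x a \code{\linkS4class{PcoaResult}}.
#' @return \code{pcoaCoordinates}: the samples-by-axes coordinate matrix;
#'   \code{eigenvalues}: positive eigenvalues; \code{proportionExplained}:
#'   per-axis variance share.
#' @aliases pcoaCoordinates eigenvalues proportionExplained
#' @export
setMethod("pcoaCoordinates", "PcoaResult", function(x) x@coordinates)

#' @rdname pcoaCoordinates
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname pcoaCoordinates
#' @export
setMethod("eigenvalues", "PcoaResult", function(x) x@eigenvalues)

#' @rdname pcoaCoordinates
#' @export
setGeneric("proportionExplained", function(x) standardGeneric("proportionExplained"))

#' @rdname pcoaCoordinates
#' @export
setMethod("proportionExplained", "PcoaResult", function(x) x@proportionExplained)
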