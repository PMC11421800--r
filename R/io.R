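#' Read and write ASV count tables
#'
#' The on-disk dialect is TSV with ASV ids in the first column and ISO-8601
#' sample dates as the remaining column headers. Cells must be nonnegative
#' integers; all-zero ASV rows are dropped with a warning; duplicate dates or
#' ASV ids are format errors.
#'
#' @param path file to read or write.
#' @return \code{readCountTable}: a nonnegative integer matrix with ASV row
#'   names and ISO-date column names, dates strictly increasing.
#' @export
readCountTable <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an ASV id column and >= 1 date column")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate ASV ids in ", path)
  dates <- as.Date(colnames(raw)[-1])
  if (any(is.na(dates))) stop("count table headers must be ISO-8601 dates")
  if (anyDuplicated(dates)) stop("duplicate sample date in ", path)
  if (is.unsorted(dates, strictly = TRUE)) stop("sample dates must be strictly increasing")
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    stop("non-numeric count in column '", colnames(raw)[-1][bad], "'")
  }
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at row '%s', column '%s': must be a nonnegative integer",
                 ids[bad[1, 1]], colnames(raw)[-1][bad[1, 2]]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  colnames(m) <- as.character(dates)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero ASV row(s) dropped")
    m <- m[!zero, , drop = FALSE]
  }
  m
}

#' @rdname readCountTable
#' @param counts ASV-by-date integer matrix (or a
#'   \code{\linkS4class{StormExperiment}}, whose counts are used).
#' @export
writeCountTable <- function(counts, path) {
  if (methods::is(counts, "StormExperiment")) counts <- asvCounts(counts)
  df <- data.frame(asv_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns \code{asv_id} and \code{lineage} (rank-prefixed,
#' semicolon-separated, SILVA style); an optional \code{group} column is
#' passed through.
#'
#' @param path file to read.
#' @return data.frame with \code{asv_id}, \code{lineage} and, if present,
#'   \code{group}.
#' @export
readTaxonomyTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("asv_id", "lineage") %in% colnames(df)))
    stop("taxonomy table must have columns 'asv_id' and 'lineage'")
  if (anyDuplicated(df$asv_id)) stop("duplicate ASV ids in taxonomy table")
  df
}

# rank-wise, case-insensitive substring match against the seven named groups
.match_group <- function(lineage) {
  if (is.na(lineage) || !nzchar(trimws(lineage))) return(NA_character_)
  l <- tolower(lineage)
  for (g in setdiff(TAXON_GROUPS, "Other"))
    if (grepl(tolower(g), l, fixed = TRUE)) return(g)
  "Other"
}

#' Assign each ASV to one of the eight taxonomic groups
#'
#' Matches lineage strings (case-insensitive substring) against five phyla
#' (Actinobacteriota, Bacteroidota, Cyanobacteria, Planctomycetota,
#' Verrucomicrobiota) and the two Proteobacteria subgroups
#' (Gammaproteobacteria, Alphaproteobacteria); anything else, including an
#' empty or missing lineage, is \code{"Other"} (with a warning for
#' missing/empty entries).
#'
#' @param taxonomy data.frame from \code{\link{readTaxonomyTable}}.
#' @param asv_ids ASV ids to label (e.g. rownames of a count matrix);
#'   defaults to the ids in \code{taxonomy}.
#' @return named character vector, one of \code{\link{TAXON_GROUPS}} per ASV.
#' @export
assignGroups <- function(taxonomy, asv_ids = taxonomy$asv_id) {
  lin <- taxonomy$lineage[match(asv_ids, taxonomy$asv_id)]
  g <- vapply(lin, .match_group, character(1), USE.NAMES = FALSE)
  n_missing <- sum(is.na(g))
  if (n_missing)
    warning(n_missing, " ASV(s) with missing or empty lineage assigned to 'Other'")
  g[is.na(g)] <- "Other"
  stats::setNames(g, asv_ids)
}

#' Read hydrograph or isotope time series
#'
#' CSV with an ISO-8601 \code{date} column plus \code{discharge_cms} and
#' \code{precip_mm} (kind \code{"hydro"}) or \code{d2H} and \code{d18O}
#' (kind \code{"isotope"}).
#'
#' @param path file to read.
#' @param kind \code{"hydro"} or \code{"isotope"}.
#' @return data.frame sorted by date with validated numeric columns.
#' @export
readTimeseries <- function(path, kind = c("hydro", "isotope")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- switch(kind, hydro = c("date", "discharge_cms", "precip_mm"),
                 isotope = c("date", "d2H", "d18O"))
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop("unparseable date in ", path)
  if (anyDuplicated(df$date)) stop("duplicate date in ", path)
  for (v in setdiff(need, "date")) {
    if (!is.numeric(df[[v]])) stop("non-numeric values in column '", v, "'")
    if (kind == "hydro" && v == "discharge_cms" && any(df[[v]] <= 0, na.rm = TRUE))
      stop("discharge_cms must be > 0")
    if (any(!is.finite(df[[v]])))
      stop("non-finite values in column '", v, "'")
  }
  df[order(df$date), need]
}

#' Read a habitat-hit table
#'
#' Long-format TSV of habitat hits per ASV (columns \code{asv_id},
#' \code{habitat}, \code{hits}), the tabular shape of a habitat-preference
#' query result.
#'
#' @param path file to read.
#' @return data.frame with nonnegative integer \code{hits}.
#' @export
readHabitatHits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("asv_id", "habitat", "hits")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$hits) || any(!is.finite(df$hits)) || any(df$hits < 0))
    stop("habitat hits must be nonnegative numbers")
  df[, need]
}

#' Read a habitat-to-environment mapping
#'
#' TSV with columns \code{habitat} and \code{environment}; environments
#' should be among \code{\link{SOURCE_ENVIRONMENTS}} (others are kept but
#' flagged with a warning).
#'
#' @param path file to read.
#' @return data.frame with \code{habitat}, \code{environment}.
#' @export
readHabitatMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("habitat", "environment") %in% colnames(df)))
    stop("habitat map must have columns 'habitat' and 'environment'")
  unknown <- setdiff(unique(df$environment), SOURCE_ENVIRONMENTS)
  if (length(unknown))
    warning("environments outside the standard eight: ",
            paste(unknown, collapse = ", "))
  df
}

#' Assemble a StormExperiment from files
#'
#' Reads the count table, taxonomy and (optionally) hydrograph and isotope
#' series, inner-joins everything on sample date, and reports any days
#' dropped from either side of the join.
#'
#' @param counts_path count table TSV (see \code{\link{readCountTable}}).
#' @param taxonomy_path optional taxonomy TSV.
#' @param hydro_path optional hydrograph CSV.
#' @param isotope_path optional isotope CSV.
#' @return a \code{\linkS4class{StormExperiment}}.
#' @export
readStormExperiment <- function(counts_path, taxonomy_path = NULL,
                                hydro_path = NULL, isotope_path = NULL) {
  counts <- readCountTable(counts_path)
  dates <- as.Date(colnames(counts))
  hydro <- if (!is.null(hydro_path)) readTimeseries(hydro_path, "hydro")
  iso <- if (!is.null(isotope_path)) readTimeseries(isotope_path, "isotope")
  keep <- dates
  for (ts in list(hydro, iso)) if (!is.null(ts)) keep <- keep[keep %in% ts$date]
  dropped <- setdiff(as.character(dates), as.character(keep))
  if (length(dropped))
    warning("days without matching series dropped from the experiment: ",
            paste(dropped, collapse = ", "))
  counts <- counts[, as.character(keep), drop = FALSE]
  rd <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- readTaxonomyTable(taxonomy_path)
    grp <- suppressWarnings(assignGroups(tax, rownames(counts)))
    rd <- data.frame(lineage = tax$lineage[match(rownames(counts), tax$asv_id)],
                     group = unname(grp), row.names = rownames(counts))
  }
  StormExperiment(counts, keep,
    discharge_cms = if (!is.null(hydro)) hydro$discharge_cms[match(keep, hydro$date)],
    precip_mm = if (!is.null(hydro)) hydro$precip_mm[match(keep, hydro$date)],
    d2H = if (!is.null(iso)) iso$d2H[match(keep, iso$date)],
    d18O = if (!is.null(iso)) iso$d18O[match(keep, iso$date)],
    rowData = rd)
}
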