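.discharge_for <- function(x, discharge) {
  if (is.null(discharge) && methods::is(x, "StormExperiment"))
    discharge <- discharge(x)
  if (is.null(discharge)) stop("discharge series required")
  as.numeric(discharge)
}

# vectorized simple linear regression of each row of Y on x:
# slope, two-sided t-test p-value with n - 2 df
.row_ols <- function(Y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0)
    return(list(slope = rep(NA_real_, nrow(Y)), p = rep(NA_real_, nrow(Y))))
  slope <- as.vector(Y %*% xc) / sxx
  ybar <- rowMeans(Y)
  syy <- rowSums((Y - ybar)^2)
  sse <- pmax(syy - slope^2 * sxx, 0)
  se <- sqrt(sse / ((n - 2) * sxx))
  tstat <- ifelse(se > 0, slope / se,
                  ifelse(slope == 0, 0, sign(slope) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[syy == 0] <- NA_real_  # zero-variance abundance: no association testable
  list(slope = slope, p = p)
}

.labels_from <- function(slope, p, n_det, alpha, min_detections) {
  lab <- rep("static", length(slope))
  sig <- !is.na(p) & p < alpha & !is.na(slope)
  lab[sig & slope > 0] <- "mobilized"
  lab[sig & slope < 0] <- "diluted"
  lab[n_det < min_detections] <- "uncharacterized"
  lab
}

#' Classify taxa by their abundance-discharge (cQ) response
#'
#' For every ASV detected on at least \code{min_detections} days, fits a
#' simple linear regression of its per-day (rarefied) counts on daily
#' discharge over the whole record, zeros included. Taxa with a positive
#' slope significant at level \code{alpha} (two-sided, default 90%
#' confidence) are \code{mobilized}, significantly negative ones
#' \code{diluted}, the rest \code{static}; taxa detected on fewer days are
#' \code{uncharacterized}. A slope of exactly zero or zero-variance
#' abundance resolves to \code{static}.
#'
#' @param x a \code{\linkS4class{StormExperiment}} (rarefied) or ASV-by-day
#'   count matrix.
#' @param discharge daily discharge [CMS] aligned with the columns; taken
#'   from the experiment when omitted.
#' @param alpha two-sided significance level on the slope (default 0.1).
#' @param min_detections minimum days with positive count (default 3).
#' @param use_proportions regress per-day proportions instead of counts
#'   (equivalent for evenly rarefied data up to a constant factor).
#' @return data.frame with \code{asv_id}, \code{label}, \code{slope}
#'   [counts (or proportion) per CMS], \code{p_value}, \code{n_detections}.
#' @export
classifyTaxa <- function(x, discharge = NULL, alpha = 0.1,
                         min_detections = 3, use_proportions = FALSE) {
  counts <- .counts_of(x)
  q <- .discharge_for(x, discharge)
  if (length(q) != ncol(counts))
    stop("discharge must have one value per sample day")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (nrow(counts) == 0)
    return(data.frame(asv_id = character(), label = character(),
                      slope = numeric(), p_value = numeric(),
                      n_detections = integer()))
  Y <- counts
  if (use_proportions) Y <- sweep(Y, 2, pmax(colSums(Y), 1), "/")
  fit <- .row_ols(Y, q)
  n_det <- rowSums(counts > 0)
  data.frame(asv_id = rownames(counts),
             label = .labels_from(fit$slope, fit$p, n_det, alpha, min_detections),
             slope = fit$slope, p_value = fit$p,
             n_detections = as.integer(n_det), row.names = NULL)
}

#' @rdname classifyTaxa
#' @param abundance per-day counts for a single taxon.
#' @export
classifyTaxon <- function(abundance, discharge, alpha = 0.1,
                          min_detections = 3) {
  m <- matrix(abundance, nrow = 1, dimnames = list("taxon", NULL))
  colnames(m) <- names(discharge) %||% as.character(seq_along(discharge))
  classifyTaxa(m, discharge, alpha = alpha, min_detections = min_detections)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-day community fraction of each discharge-response class
#'
#' For each sample day, the fraction of that day's sequences belonging to
#' mobilized, static, and diluted taxa. Uncharacterized taxa (detected on too
#' few days) are excluded from both numerator and denominator, scoping the
#' fractions to taxa with a defined discharge response.
#'
#' @param x a \code{\linkS4class{StormExperiment}} or count matrix.
#' @param classification result of \code{\link{classifyTaxa}} covering all
#'   ASVs.
#' @param denominator \code{"per_day"} (each day's retained sequences) or
#'   \code{"whole_study"} (retained sequences over the full record).
#' @return data.frame with \code{date} and columns \code{mobilized},
#'   \code{static}, \code{diluted}; days with zero retained sequences are
#'   \code{NA}.
#' @export
classFractionTimeseries <- function(x, classification,
                                    denominator = c("per_day", "whole_study")) {
  denominator <- match.arg(denominator)
  counts <- .counts_of(x)
  lab <- classification$label[match(rownames(counts), classification$asv_id)]
  if (anyNA(lab)) stop("classification must cover all ASVs")
  keep <- lab != "uncharacterized"
  classes <- c("mobilized", "static", "diluted")
  by_class <- t(vapply(classes, function(k)
    colSums(counts[keep & lab == k, , drop = FALSE]),
    numeric(ncol(counts))))
  denom <- if (denominator == "per_day") colSums(by_class)
           else rep(sum(by_class), ncol(by_class))
  frac <- t(sweep(by_class, 2, denom, "/"))
  frac[denom == 0, ] <- NA_real_
  data.frame(date = as.Date(colnames(counts)), frac, row.names = NULL)
}

# sequence- and taxon-weighted class fractions per taxonomic group;
# ug fixes the group set (and order) so surrogate draws are conformable
.group_fractions <- function(row_totals, labels, groups, ug) {
  fg <- factor(groups, levels = ug)
  fl <- factor(labels, levels = CQ_CLASSES)
  idx <- (as.integer(fl) - 1L) * length(ug) + as.integer(fg)
  K <- length(ug) * length(CQ_CLASSES)
  seq_tab <- tax_tab <- numeric(K)
  agg <- rowsum(cbind(row_totals, 1), idx)
  at <- as.integer(rownames(agg))
  seq_tab[at] <- agg[, 1]
  tax_tab[at] <- agg[, 2]
  dim(seq_tab) <- dim(tax_tab) <- c(length(ug), length(CQ_CLASSES))
  gtot_seq <- rowSums(seq_tab)
  gtot_tax <- rowSums(tax_tab)
  list(sequences = seq_tab / ifelse(gtot_seq == 0, NA, gtot_seq),
       taxa = tax_tab / ifelse(gtot_tax == 0, NA, gtot_tax))
}

#' Class fractions within each taxonomic group
#'
#' For each of the eight taxonomic groups, the fraction of its study-period
#' sequences (and of its unique taxa) carrying each discharge-response label.
#' Within a group the four label fractions sum to 1 under both weightings.
#'
#' @param x a \code{\linkS4class{StormExperiment}} or count matrix.
#' @param classification result of \code{\link{classifyTaxa}}.
#' @param groups named group vector per ASV (see \code{\link{assignGroups}});
#'   taken from the experiment rowData when omitted.
#' @return data.frame with \code{group}, \code{label},
#'   \code{fraction_sequences}, \code{fraction_taxa}.
#' @export
groupClassFractions <- function(x, classification, groups = NULL) {
  counts <- .counts_of(x)
  if (is.null(groups) && methods::is(x, "StormExperiment"))
    groups <- stats::setNames(SummarizedExperiment::rowData(x)$group, rownames(x))
  if (is.null(groups)) stop("per-ASV groups required")
  groups <- groups[rownames(counts)]
  if (anyNA(groups)) stop("every ASV must be grouped")
  lab <- classification$label[match(rownames(counts), classification$asv_id)]
  ug <- TAXON_GROUPS[TAXON_GROUPS %in% unique(groups)]
  absent <- setdiff(TAXON_GROUPS, ug)
  if (length(absent))
    warning("group(s) absent from data omitted: ", paste(absent, collapse = ", "))
  fr <- .group_fractions(rowSums(counts), lab, groups, ug)
  data.frame(group = rep(ug, times = length(CQ_CLASSES)),
             label = rep(CQ_CLASSES, each = length(ug)),
             fraction_sequences = as.vector(fr$sequences),
             fraction_taxa = as.vector(fr$taxa), row.names = NULL)
}

#' Shuffled-surrogates significance test for group class fractions
#'
#' Builds an empirical null for the observed per-group class fractions by
#' repeatedly (1) permuting, independently within each sample day, the
#' assignment of that day's count values to ASV ids, and (2) permuting the
#' alignment of sample days to discharge -- preserving each day's abundance
#' multiset while destroying taxon identity and discharge association. The
#' classification and group fractions are recomputed for every surrogate, and
#' an observed fraction is flagged significant when it falls above the 95th
#' or below the 5th percentile of its surrogate distribution (two-sided
#' p < 0.05).
#'
#' @inheritParams groupClassFractions
#' @param discharge daily discharge aligned with columns (from the
#'   experiment when omitted).
#' @param n_surrogates number of shuffled surrogates (>= 100; default 1000).
#' @param seed integer seed for the shuffling (recorded on the result).
#' @param alpha,min_detections classifier settings, as
#'   \code{\link{classifyTaxa}}.
#' @param shuffle_scope \code{"all"} permutes each day's values over the full
#'   ASV id set; \code{"nonzero"} permutes only among that day's detected
#'   ASVs.
#' @return data.frame with \code{group}, \code{label},
#'   \code{observed_fraction} (of sequences), \code{observed_fraction_taxa},
#'   \code{surrogate_p5}, \code{surrogate_p95} (linear-interpolation
#'   percentiles) and \code{significant}; attributes \code{seed} and
#'   \code{n_surrogates} record the run.
#' @export
surrogateNull <- function(x, discharge = NULL, groups = NULL,
                          n_surrogates = 1000, seed = 1, alpha = 0.1,
                          min_detections = 3,
                          shuffle_scope = c("all", "nonzero")) {
  shuffle_scope <- match.arg(shuffle_scope)
  if (n_surrogates < 100)
    stop("n_surrogates must be >= 100 for stable tail percentiles")
  counts <- .counts_of(x)
  q <- .discharge_for(x, discharge)
  if (is.null(groups) && methods::is(x, "StormExperiment"))
    groups <- stats::setNames(SummarizedExperiment::rowData(x)$group, rownames(x))
  if (is.null(groups)) stop("per-ASV groups required")
  groups <- groups[rownames(counts)]
  ug <- TAXON_GROUPS[TAXON_GROUPS %in% unique(groups)]

  obs_cls <- classifyTaxa(counts, q, alpha = alpha,
                          min_detections = min_detections)
  obs <- .group_fractions(rowSums(counts), obs_cls$label, groups, ug)

  nr <- nrow(counts); nd <- ncol(counts)
  K <- length(ug) * length(CQ_CLASSES)
  null_seq <- matrix(NA_real_, n_surrogates, K)
  set.seed(seed)
  for (s in seq_len(n_surrogates)) {
    cs <- counts
    for (j in seq_len(nd)) {
      if (shuffle_scope == "all") {
        cs[, j] <- counts[sample.int(nr), j]
      } else {
        nz <- which(counts[, j] > 0)
        cs[nz, j] <- counts[nz[sample.int(length(nz))], j]
      }
    }
    qs <- q[sample.int(nd)]
    fit <- .row_ols(cs, qs)
    labs <- .labels_from(fit$slope, fit$p, rowSums(cs > 0),
                         alpha, min_detections)
    null_seq[s, ] <- as.vector(
      .group_fractions(rowSums(cs), labs, groups, ug)$sequences)
  }
  p5 <- apply(null_seq, 2, stats::quantile, probs = 0.05, type = 7, na.rm = TRUE)
  p95 <- apply(null_seq, 2, stats::quantile, probs = 0.95, type = 7, na.rm = TRUE)
  obs_seq <- as.vector(obs$sequences)
  out <- data.frame(group = rep(ug, times = length(CQ_CLASSES)),
                    label = rep(CQ_CLASSES, each = length(ug)),
                    observed_fraction = obs_seq,
                    observed_fraction_taxa = as.vector(obs$taxa),
                    surrogate_p5 = p5, surrogate_p95 = p95,
                    significant = obs_seq > p95 | obs_seq < p5,
                    row.names = NULL)
  attr(out, "seed") <- seed
  attr(out, "n_surrogates") <- n_surrogates
  attr(out, "shuffle_scope") <- shuffle_scope
  out
}
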