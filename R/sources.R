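#' Collapse habitat hits onto the eight source environments
#'
#' Maps each habitat to an environment (habitats absent from the mapping fall
#' to \code{"other"}), sums hits per ASV and environment, and normalizes each
#' ASV's vector to sum to one. ASVs listed in \code{asv_ids} but with no hits
#' get the \code{other = 1} indicator profile.
#'
#' @param hits data.frame with \code{asv_id}, \code{habitat}, \code{hits}
#'   (see \code{\link{readHabitatHits}}).
#' @param mapping data.frame with \code{habitat}, \code{environment}; by
#'   default habitats already named as environments map to themselves.
#' @param asv_ids full ASV id set to cover (default: ids present in
#'   \code{hits}).
#' @return numeric matrix, ASVs x \code{\link{SOURCE_ENVIRONMENTS}}, rows
#'   summing to 1.
#' @export
aggregateHabitats <- function(hits, mapping = NULL, asv_ids = NULL) {
  if (any(hits$hits < 0)) stop("habitat hit counts must be nonnegative")
  env <- if (is.null(mapping)) hits$habitat
         else mapping$environment[match(hits$habitat, mapping$habitat)]
  env[is.na(env) | !env %in% SOURCE_ENVIRONMENTS] <- "other"
  if (is.null(asv_ids)) asv_ids <- unique(hits$asv_id)
  prof <- matrix(0, length(asv_ids), length(SOURCE_ENVIRONMENTS),
                 dimnames = list(asv_ids, SOURCE_ENVIRONMENTS))
  keep <- hits$asv_id %in% asv_ids
  if (any(keep)) {
    agg <- rowsum(hits$hits[keep],
                  paste(hits$asv_id[keep], env[keep], sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    prof[cbind(key[, 1], key[, 2])] <- agg[, 1]
  }
  tot <- rowSums(prof)
  none <- tot == 0
  prof[!none, ] <- prof[!none, , drop = FALSE] / tot[!none]
  prof[none, "other"] <- 1
  prof
}

#' Abundance-weighted source-environment composition per day
#'
#' Each day's community composition over the eight environments is the
#' count-weighted mean of the per-ASV environment profiles; rows sum to 1.
#' ASVs without a profile contribute to \code{"other"}.
#'
#' @param x a \code{\linkS4class{StormExperiment}} or count matrix.
#' @param profiles ASV x environment fraction matrix (rows summing to 1),
#'   e.g. from \code{\link{aggregateHabitats}}.
#' @return data.frame with \code{date} and one column per environment.
#' @export
communityEnvironmentFractions <- function(x, profiles) {
  counts <- .counts_of(x)
  P <- matrix(0, nrow(counts), length(SOURCE_ENVIRONMENTS),
              dimnames = list(rownames(counts), SOURCE_ENVIRONMENTS))
  hit <- rownames(counts) %in% rownames(profiles)
  P[hit, ] <- profiles[rownames(counts)[hit], SOURCE_ENVIRONMENTS]
  P[!hit, "other"] <- 1
  comp <- t(counts) %*% P / colSums(counts)
  data.frame(date = as.Date(colnames(counts)), comp, row.names = NULL,
             check.names = FALSE)
}

#' Mann-Whitney U test
#'
#' \code{U} counts pairs where \code{x} exceeds \code{y} (ties count one
#' half). The p-value is exact (from the null Wilcoxon distribution) when
#' \code{length(x) + length(y) <= 12} and there are no ties, and otherwise a
#' normal approximation with tie correction and continuity correction. The
#' one-sided p is the smaller tail; two-sided is twice that, capped at 1.
#'
#' @param x,y numeric samples, each nonempty.
#' @return list with \code{U}, \code{p_one_sided}, \code{p_two_sided},
#'   \code{method}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, one-sided p = 1/6
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && N <= 12) {
    p_lo <- stats::pwilcox(U, nx, ny)
    p_hi <- stats::pwilcox(nx * ny - U, nx, ny)
    p1 <- min(p_lo, p_hi)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(c(x, y))
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {  # all values identical
      p1 <- 0.5
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p1 <- stats::pnorm(-abs(z))
    }
    method <- "normal_approximation"
  }
  list(U = U, p_one_sided = p1, p_two_sided = min(1, 2 * p1), method = method)
}

#' Contrast storm-period source composition against the pre-event baseline
#'
#' For each environment, expresses each day's community representation as a
#' difference (percentage points) from the pre-event mean, and compares the
#' pre-event daily values against each storm period with the exact
#' Mann-Whitney U test. Periods with fewer than 2 days are reported without a
#' test (with a warning).
#'
#' @param env_fracs data.frame from
#'   \code{\link{communityEnvironmentFractions}}.
#' @param periods named list of date vectors, e.g. \code{list(pre = ...,
#'   early_event = ..., post_event = ...)}; must be disjoint and \code{pre}
#'   nonempty.
#' @return list with \code{differences} (long data.frame: environment,
#'   period, date, diff_pp) and \code{tests} (environment, period, U,
#'   p_one_sided, p_two_sided, direction).
#' @export
periodContrast <- function(env_fracs, periods) {
  if (is.null(periods$pre) || !length(periods$pre))
    stop("periods$pre must be nonempty")
  all_dates <- as.character(env_fracs$date)
  per <- lapply(periods, function(d) intersect(as.character(as.Date(d)), all_dates))
  if (any(duplicated(unlist(per)))) stop("periods must be disjoint")
  envs <- intersect(SOURCE_ENVIRONMENTS, colnames(env_fracs))
  rownames(env_fracs) <- all_dates
  pre_mean <- colMeans(env_fracs[per$pre, envs, drop = FALSE])

  diffs <- do.call(rbind, lapply(names(per), function(pn) {
    if (!length(per[[pn]])) return(NULL)
    block <- env_fracs[per[[pn]], envs, drop = FALSE]
    data.frame(environment = rep(envs, each = nrow(block)),
               period = pn,
               date = rep(as.Date(per[[pn]]), times = length(envs)),
               diff_pp = 100 * as.vector(sweep(as.matrix(block), 2, pre_mean)),
               row.names = NULL)
  }))

  test_periods <- setdiff(names(per), "pre")
  tests <- do.call(rbind, lapply(test_periods, function(pn) {
    if (length(per[[pn]]) < 2) {
      warning("period '", pn, "' has fewer than 2 days; test skipped")
      return(NULL)
    }
    do.call(rbind, lapply(envs, function(e) {
      mw <- mannWhitneyU(env_fracs[per$pre, e], env_fracs[per[[pn]], e])
      data.frame(environment = e, period = pn, U = mw$U,
                 p_one_sided = mw$p_one_sided, p_two_sided = mw$p_two_sided,
                 direction = ifelse(mean(env_fracs[per[[pn]], e]) >= pre_mean[e],
                                    "increase", "decrease"),
                 method = mw$method, row.names = NULL)
    }))
  }))
  list(differences = diffs, tests = tests)
}
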