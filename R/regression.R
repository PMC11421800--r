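#' Ordinary least-squares fit with adjusted r-squared
#'
#' Thin wrapper around \code{\link[stats]{lm}} returning the quantities the
#' hydrograph-reconstruction analyses need: coefficients with two-sided
#' t-test p-values, \code{r2}, \code{r2_adjusted = 1 - (1 - r2) (n - 1) /
#' (n - p - 1)}, and fitted values. Rank-deficient predictor sets are an
#' error naming the collinear columns rather than a silent drop.
#'
#' @param X predictor matrix / data.frame / vector (one row per day).
#' @param y response (e.g. daily discharge [CMS]).
#' @return list of class \code{"RegressionFit"}: \code{coefficients}
#'   (without intercept), \code{intercept}, \code{p_values} (intercept
#'   first), \code{r2}, \code{r2_adjusted}, \code{fitted}, \code{residuals},
#'   \code{n}, \code{p}.
#' @export
olsFit <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y must cover the same days")
  if (n <= p + 1) stop("need n > p + 1 observations")
  M <- cbind(`(Intercept)` = 1, X)
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M)) {
    bad <- colnames(M)[qr_M$pivot[(qr_M$rank + 1):ncol(M)]]
    stop("rank-deficient predictors; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  names(cf) <- colnames(M)
  structure(list(coefficients = cf[-1], intercept = unname(cf[1]),
                 p_values = stats::setNames(sm$coefficients[, 4], colnames(M)),
                 r2 = sm$r.squared, r2_adjusted = sm$adj.r.squared,
                 fitted = stats::setNames(fit$fitted.values, rownames(X)),
                 residuals = unname(fit$residuals),
                 n = n, p = p),
            class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("RegressionFit: n = %d, p = %d, r2 = %.4f, adj r2 = %.4f\n",
              x$n, x$p, x$r2, x$r2_adjusted))
  invisible(x)
}

#' Reconstruct discharge from ordination coordinates
#'
#' Multivariate OLS of daily discharge on the first \code{p} principal
#' coordinates, plus the full r2-versus-p profile for nested models
#' \code{p = 1..max} (non-decreasing in p by construction).
#'
#' @param pcoa a \code{\linkS4class{PcoaResult}} over the sample days.
#' @param discharge daily discharge [CMS], one per ordination row (named
#'   vectors are matched by date).
#' @param p number of leading coordinates in the reported fit (default 4).
#' @return list with \code{fit} (a \code{"RegressionFit"}) and
#'   \code{profile} (data.frame \code{p}, \code{r2}, \code{r2_adjusted}).
#' @export
dischargeFromCoordinates <- function(pcoa, discharge, p = 4) {
  coords <- pcoaCoordinates(pcoa)
  if (!is.null(names(discharge)) && !is.null(rownames(coords))) {
    if (!all(rownames(coords) %in% names(discharge)))
      stop("discharge series does not cover all ordination samples")
    discharge <- discharge[rownames(coords)]
  }
  pmax_av <- ncol(coords)
  if (p > pmax_av) stop("p exceeds available axes (", pmax_av, ")")
  prof_max <- min(pmax_av, nrow(coords) - 2)  # keep n > p + 1
  profile <- do.call(rbind, lapply(seq_len(prof_max), function(k) {
    f <- olsFit(coords[, seq_len(k), drop = FALSE], discharge)
    data.frame(p = k, r2 = f$r2, r2_adjusted = f$r2_adjusted)
  }))
  list(fit = olsFit(coords[, seq_len(p), drop = FALSE], discharge),
       profile = profile)
}

#' Regress discharge on alpha diversity and on isotope ratios
#'
#' Simple linear regressions of daily discharge on taxonomic richness and on
#' Shannon entropy (singly and jointly), and -- when an isotope series is
#' supplied -- a joint OLS on d2H and d18O.
#'
#' @param alpha data.frame from \code{\link{alphaDiversity}} (or NULL).
#' @param discharge daily discharge [CMS] aligned by position.
#' @param isotopes optional data.frame with \code{d2H}, \code{d18O}.
#' @return named list of \code{"RegressionFit"} objects: \code{richness},
#'   \code{shannon}, \code{alpha_both}, and \code{isotopes} when supplied.
#' @export
diversityDischargeFit <- function(alpha, discharge, isotopes = NULL) {
  out <- list()
  if (!is.null(alpha)) {
    out$richness <- olsFit(cbind(richness = alpha$richness), discharge)
    out$shannon <- olsFit(cbind(shannon = alpha$shannon), discharge)
    out$alpha_both <- olsFit(cbind(richness = alpha$richness,
                                   shannon = alpha$shannon), discharge)
  }
  if (!is.null(isotopes))
    out$isotopes <- olsFit(cbind(d2H = isotopes$d2H, d18O = isotopes$d18O),
                           discharge)
  out
}

#' Serialize regression fits to a report list
#'
#' @param fits named list of \code{"RegressionFit"} objects.
#' @return list suitable for JSON serialization.
#' @export
regressionReport <- function(fits) {
  lapply(fits, function(f) {
    if (is.list(f) && !inherits(f, "RegressionFit")) return(regressionReport(f))
    list(coefficients = as.list(f$coefficients), intercept = f$intercept,
         p_values = as.list(f$p_values), r2 = f$r2,
         r2_adjusted = f$r2_adjusted, n = f$n, p = f$p)
  })
}
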