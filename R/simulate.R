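#' Configuration for the synthetic storm-microbiome generator
#'
#' Defaults emulate the observed study conditions the package is designed
#' around: 17 daily samples, a baseflow of 0.25 CMS rising to a 1.8 CMS peak,
#' raw library sizes between 4,333 and 37,740 reads, and an
#' old-water-dominated isotope response between a -53.9 permil pre-event
#' stream endmember and a -38.7 permil precipitation endmember.
#'
#' @param n_days number of daily samples (>= 3).
#' @param q_base,q_peak baseflow and peak discharge [CMS]; \code{q_peak >
#'   q_base > 0}.
#' @param event_start_day 1-based day on which the storm begins; discharge is
#'   \code{q_base} through this day and rises linearly afterwards.
#' @param rise_days days of linear rise; the peak falls on
#'   \code{event_start_day + rise_days}.
#' @param recession_shape geometric recession factor in (0, 1):
#'   \code{Q(peak + k) = q_base + (q_peak - q_base) * recession_shape^k}.
#' @param n_core_taxa taxa present throughout the record.
#' @param n_event_taxa taxa that appear only while discharge exceeds
#'   \code{event_threshold} (the designed richness spike).
#' @param class_probabilities probabilities over
#'   \code{c(mobilized, diluted, static)} for core taxa; must sum to 1.
#' @param effect_scale magnitude scale of the discharge-coupling coefficient
#'   beta (0 switches all coupling off).
#' @param library_size_range integer pair; per-day library sizes are drawn
#'   uniformly from this range.
#' @param event_threshold discharge [CMS] above which event-only taxa occur;
#'   default midpoint of \code{q_base} and \code{q_peak}.
#' @param delta_old,delta_new d2H endmembers [permil VSMOW] for pre-event
#'   ("old") water and event precipitation ("new") water; must differ.
#' @param phi event-water scaling in (0, 1]: the event-water fraction is
#'   \code{phi * (Q - q_base) / Q}, so old water dominates for small phi.
#' @param isotope_noise_sd,d18O_noise_sd measurement noise [permil] added to
#'   d2H and d18O.
#' @param start_date calendar date of the first sample.
#' @param rng_seed integer seed; the hydrograph is deterministic and the
#'   community, isotope and habitat draws use fixed offsets of this seed so
#'   each component is reproducible in isolation.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_days = 17L,
                             q_base = 0.25, q_peak = 1.8,
                             event_start_day = 5L, rise_days = 3L,
                             recession_shape = 0.6,
                             n_core_taxa = 150L, n_event_taxa = 120L,
                             class_probabilities = c(mobilized = 0.15,
                                                     diluted = 0.13,
                                                     static = 0.72),
                             effect_scale = 1.5,
                             library_size_range = c(4333L, 37740L),
                             event_threshold = NULL,
                             delta_old = -53.9, delta_new = -38.7,
                             phi = 0.14,
                             isotope_noise_sd = 0.16, d18O_noise_sd = 0.03,
                             start_date = as.Date("2020-10-06"),
                             rng_seed = 1L) {
  cfg <- list(n_days = as.integer(n_days), q_base = q_base, q_peak = q_peak,
              event_start_day = as.integer(event_start_day),
              rise_days = as.integer(rise_days),
              recession_shape = recession_shape,
              n_core_taxa = as.integer(n_core_taxa),
              n_event_taxa = as.integer(n_event_taxa),
              class_probabilities = class_probabilities,
              effect_scale = effect_scale,
              library_size_range = as.integer(library_size_range),
              event_threshold = if (is.null(event_threshold))
                (q_base + q_peak) / 2 else event_threshold,
              delta_old = delta_old, delta_new = delta_new, phi = phi,
              isotope_noise_sd = isotope_noise_sd,
              d18O_noise_sd = d18O_noise_sd,
              start_date = as.Date(start_date),
              rng_seed = as.integer(rng_seed))
  num <- unlist(cfg[c("q_base", "q_peak", "recession_shape", "effect_scale",
                      "phi", "isotope_noise_sd", "d18O_noise_sd")])
  if (any(!is.finite(num)))
    stop("invalid config: non-finite numeric field")
  if (!(cfg$q_peak > cfg$q_base && cfg$q_base > 0))
    stop("invalid config: need q_peak > q_base > 0")
  if (cfg$n_days < 3)
    stop("invalid config: n_days must be >= 3")
  if (cfg$event_start_day < 2 || cfg$event_start_day >= cfg$n_days)
    stop("invalid config: event_start_day must lie in [2, n_days - 1]")
  if (cfg$rise_days < 1)
    stop("invalid config: rise_days must be >= 1")
  if (!(cfg$recession_shape > 0 && cfg$recession_shape < 1))
    stop("invalid config: recession_shape must be in (0, 1)")
  p <- cfg$class_probabilities
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("invalid config: class_probabilities must be a nonnegative 3-vector summing to 1")
  lsr <- cfg$library_size_range
  if (length(lsr) != 2 || any(lsr <= 0) || lsr[1] > lsr[2])
    stop("invalid config: library_size_range must be a positive ordered pair")
  if (cfg$effect_scale < 0)
    stop("invalid config: effect_scale must be nonnegative")
  if (cfg$delta_old == cfg$delta_new)
    stop("invalid config: delta_old and delta_new must differ")
  if (!(cfg$phi > 0 && cfg$phi <= 1))
    stop("invalid config: phi must be in (0, 1]")
  if (cfg$isotope_noise_sd < 0 || cfg$d18O_noise_sd < 0)
    stop("invalid config: noise sds must be nonnegative")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate the storm hydrograph
#'
#' Baseflow \code{q_base} through \code{event_start_day}, a linear rise to
#' \code{q_peak} on day \code{event_start_day + rise_days} (truncated at the
#' record end), then geometric recession toward baseflow. Precipitation is a
#' trivial 1 mm on the storm onset day and 15 mm on each subsequent rising-limb
#' day, zero otherwise.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame with columns \code{date}, \code{discharge_cms},
#'   \code{precip_mm}.
#' @export
generateHydrograph <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_days
  day <- seq_len(n)
  q <- rep(config$q_base, n)
  amp <- config$q_peak - config$q_base
  peak_day <- config$event_start_day + config$rise_days
  rising <- day > config$event_start_day & day <= peak_day
  q[rising] <- config$q_base +
    amp * (day[rising] - config$event_start_day) / config$rise_days
  receding <- day > peak_day
  q[receding] <- config$q_base + amp * config$recession_shape^(day[receding] - peak_day)
  precip <- rep(0, n)
  precip[config$event_start_day] <- 1
  precip[rising] <- 15
  data.frame(date = config$start_date + day - 1L,
             discharge_cms = q, precip_mm = precip)
}

.standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# group-assignment probabilities per true class; mobilized taxa skew
# Alphaproteobacteria, diluted taxa skew Gammaproteobacteria/Bacteroidota,
# emulating the taxon-level discharge-response structure the package targets
.group_probs <- local({
  g <- TAXON_GROUPS
  m <- rbind(
    mobilized    = c(0.06, 0.04, 0.02, 0.04, 0.04, 0.08, 0.60, 0.12),
    diluted      = c(0.14, 0.28, 0.02, 0.03, 0.03, 0.36, 0.02, 0.12),
    static       = c(0.14, 0.14, 0.05, 0.08, 0.08, 0.14, 0.17, 0.20),
    `event-only` = c(0.12, 0.10, 0.03, 0.08, 0.08, 0.12, 0.17, 0.30))
  colnames(m) <- g
  m / rowSums(m)
})

.group_lineages <- c(
  Actinobacteriota    = "d__Bacteria; p__Actinobacteriota; c__Actinobacteria; o__Frankiales",
  Bacteroidota        = "d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Flavobacteriales",
  Cyanobacteria       = "d__Bacteria; p__Cyanobacteria; c__Cyanobacteriia; o__Synechococcales",
  Planctomycetota     = "d__Bacteria; p__Planctomycetota; c__Planctomycetes; o__Pirellulales",
  Verrucomicrobiota   = "d__Bacteria; p__Verrucomicrobiota; c__Verrucomicrobiae; o__Chthoniobacterales",
  Gammaproteobacteria = "d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Burkholderiales",
  Alphaproteobacteria = "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhizobiales",
  Other               = "d__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales")

#' Generate an ASV count matrix coupled to the hydrograph
#'
#' Core taxa have expected relative abundance proportional to
#' \code{a_i * max(0, 1 + beta_i * z(t))}, where \code{z(t)} is standardized
#' discharge and \code{beta_i} is positive for mobilized taxa, negative for
#' diluted taxa and zero for static taxa (negative expectations from strong
#' dilution are clipped at zero). Event-only taxa occur only on days with
#' discharge above \code{event_threshold}, producing a richness spike at peak
#' flow. Each day's counts are a single multinomial draw at a library size
#' drawn uniformly from \code{library_size_range}.
#'
#' @param hydro hydrograph data.frame from \code{\link{generateHydrograph}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{counts} (ASV x day integer matrix),
#'   \code{taxonomy} (data.frame \code{asv_id}, \code{lineage},
#'   \code{group}), and \code{truth} (list with per-ASV \code{taxon_class}
#'   and \code{beta}, and the \code{event_threshold} used).
#' @export
generateCommunity <- function(hydro, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (nrow(hydro) < config$n_days)
    stop("hydrograph must cover all simulated days")
  set.seed(config$rng_seed + 1L)
  n_core <- config$n_core_taxa
  n_event <- config$n_event_taxa
  n_taxa <- n_core + n_event
  ids <- sprintf("asv_%04d", seq_len(n_taxa))

  cls <- character(n_taxa)
  cls[seq_len(n_core)] <- sample(c("mobilized", "diluted", "static"),
                                 n_core, replace = TRUE,
                                 prob = config$class_probabilities)
  if (n_event > 0) cls[(n_core + 1):n_taxa] <- "event-only"

  beta <- numeric(n_taxa)
  vary <- cls %in% c("mobilized", "diluted")
  beta[vary] <- ifelse(cls[vary] == "mobilized", 1, -1) *
    config$effect_scale * stats::runif(sum(vary), 0.75, 1.25)

  # heavy-tailed core abundances give realistic richness (~half the pool
  # detected at depth 4000) and Shannon entropy near 4-5 bits
  a <- numeric(n_taxa)
  a[seq_len(n_core)] <- stats::rlnorm(n_core, meanlog = 0, sdlog = 2.6)
  if (n_event > 0) {
    # event taxa are individually rare but even: collectively ~20% of the
    # community while active, so the richness spike is sharp
    idx <- (n_core + 1):n_taxa
    a[idx] <- stats::rlnorm(n_event, meanlog = 0, sdlog = 1.0)
    a[idx] <- a[idx] * 0.2 * sum(a[seq_len(n_core)]) / sum(a[idx])
  }

  q <- hydro$discharge_cms[seq_len(config$n_days)]
  z <- .standardize(q)
  active_event <- q > config$event_threshold

  lambda <- matrix(0, n_taxa, config$n_days)
  core <- seq_len(n_core)
  for (t in seq_len(config$n_days)) {
    lam <- a[core] * pmax(0, 1 + beta[core] * z[t])
    lambda[core, t] <- lam
    if (n_event > 0 && active_event[t])
      lambda[(n_core + 1):n_taxa, t] <- a[(n_core + 1):n_taxa]
  }

  sizes <- sample(config$library_size_range[1]:config$library_size_range[2],
                  config$n_days, replace = TRUE)
  counts <- matrix(0L, n_taxa, config$n_days,
                   dimnames = list(ids, as.character(hydro$date[seq_len(config$n_days)])))
  for (t in seq_len(config$n_days)) {
    p <- lambda[, t]
    if (sum(p) <= 0) stop("degenerate community: all expected abundances zero")
    counts[, t] <- stats::rmultinom(1, sizes[t], p / sum(p))[, 1]
  }

  grp <- vapply(cls, function(k)
    sample(TAXON_GROUPS, 1, prob = .group_probs[k, ]), character(1))
  taxonomy <- data.frame(asv_id = ids,
                         lineage = unname(.group_lineages[grp]),
                         group = unname(grp))
  list(counts = counts,
       taxonomy = taxonomy,
       truth = list(taxon_class = stats::setNames(cls, ids),
                    beta = stats::setNames(beta, ids),
                    event_threshold = config$event_threshold,
                    library_sizes = stats::setNames(sizes,
                      as.character(hydro$date[seq_len(config$n_days)]))))
}

#' Generate stream isotope series from two-endmember mixing
#'
#' The event-water fraction is \code{f(t) = phi * (Q(t) - q_base) / Q(t)}:
#' zero at baseflow and at most \code{phi} when event water dominates the
#' hydrograph rise. Stream d2H is the f-weighted mix of the new- and old-water
#' endmembers plus Gaussian measurement noise; d18O follows the meteoric-line
#' transform \code{(d2H - 10) / 8} of the noise-free mixture plus its own
#' noise.
#'
#' @inheritParams generateCommunity
#' @return list with \code{isotopes} (data.frame \code{date}, \code{d2H},
#'   \code{d18O}) and \code{event_water_fraction} (named per-day vector, the
#'   ground truth f(t)).
#' @export
generateIsotopes <- function(hydro, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed + 2L)
  q <- hydro$discharge_cms[seq_len(config$n_days)]
  f <- config$phi * (q - config$q_base) / q
  d2H_clean <- f * config$delta_new + (1 - f) * config$delta_old
  d2H <- d2H_clean + stats::rnorm(length(f), 0, config$isotope_noise_sd)
  d18O <- (d2H_clean - 10) / 8 + stats::rnorm(length(f), 0, config$d18O_noise_sd)
  dates <- hydro$date[seq_len(config$n_days)]
  list(isotopes = data.frame(date = dates, d2H = d2H, d18O = d18O),
       event_water_fraction = stats::setNames(f, as.character(dates)))
}

.rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(s) if (s > 0) stats::rgamma(1, s) else 0,
              numeric(1))
  if (sum(g) == 0) stop("Dirichlet concentration must have a positive entry")
  g / sum(g)
}

# class-conditional Dirichlet concentrations over the 8 source environments
.habitat_alpha <- local({
  m <- rbind(
    mobilized    = c(freshwater = 0.8, sediment = 0.5, soil = 4.0,
                     groundwater = 1.0, biofilm = 3.0, marine = 0.2,
                     sewage_wastewater = 0.3, other = 0.7),
    diluted      = c(freshwater = 5.0, sediment = 2.5, soil = 0.5,
                     groundwater = 0.8, biofilm = 0.4, marine = 0.3,
                     sewage_wastewater = 0.2, other = 0.8),
    static       = c(freshwater = 1, sediment = 1, soil = 1, groundwater = 1,
                     biofilm = 1, marine = 1, sewage_wastewater = 1, other = 1),
    `event-only` = c(freshwater = 0.5, sediment = 0.8, soil = 2.5,
                     groundwater = 1.5, biofilm = 1.5, marine = 0.3,
                     sewage_wastewater = 0.7, other = 1.2))
  colnames(m) <- SOURCE_ENVIRONMENTS
  m
})

#' Generate per-ASV source-environment profiles
#'
#' Each ASV gets a Dirichlet draw over the eight source environments with a
#' class-dependent concentration: mobilized taxa are weighted toward soil and
#' biofilm, diluted taxa toward freshwater and sediment, static taxa are
#' uninformative. Rows sum to one.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generateCommunity}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param concentration optional named list overriding the per-class Dirichlet
#'   concentration vectors (names over \code{\link{CQ_CLASSES}} /
#'   \code{"event-only"}); a vector with a single positive entry yields the
#'   corresponding indicator profile.
#' @return numeric matrix, ASVs x environments, rows summing to 1.
#' @export
generateHabitatProfiles <- function(truth, config, concentration = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed + 3L)
  cls <- truth$taxon_class
  alpha <- .habitat_alpha
  if (!is.null(concentration))
    for (k in names(concentration)) alpha[k, ] <- concentration[[k]]
  prof <- t(vapply(cls, function(k) .rdirichlet1(alpha[k, ]),
                   numeric(length(SOURCE_ENVIRONMENTS))))
  dimnames(prof) <- list(names(cls), SOURCE_ENVIRONMENTS)
  prof
}

#' Simulate a complete storm-microbiome dataset
#'
#' Runs \code{\link{generateHydrograph}}, \code{\link{generateCommunity}},
#' \code{\link{generateIsotopes}} and \code{\link{generateHabitatProfiles}}
#' under one configuration and assembles the results into a
#' \code{\linkS4class{StormExperiment}} plus ground truth.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{experiment} (a \code{StormExperiment} whose
#'   rowData carries lineage, group and the true class/beta),
#'   \code{habitatProfiles}, \code{truth} (taxon classes, betas, event-water
#'   fractions, library sizes) and the \code{config}.
#' @examples
#' sim <- simulateStormExperiment(simulationConfig(n_core_taxa = 40,
#'                                                 n_event_taxa = 10))
#' sim$experiment
#' @export
simulateStormExperiment <- function(config = simulationConfig()) {
  hydro <- generateHydrograph(config)
  comm <- generateCommunity(hydro, config)
  iso <- generateIsotopes(hydro, config)
  prof <- generateHabitatProfiles(comm$truth, config)
  truth <- comm$truth
  truth$event_water_fraction <- iso$event_water_fraction
  se <- StormExperiment(
    comm$counts, hydro$date,
    discharge_cms = hydro$discharge_cms, precip_mm = hydro$precip_mm,
    d2H = iso$isotopes$d2H, d18O = iso$isotopes$d18O,
    rowData = data.frame(lineage = comm$taxonomy$lineage,
                         group = comm$taxonomy$group,
                         true_class = unname(truth$taxon_class),
                         beta = unname(truth$beta),
                         row.names = comm$taxonomy$asv_id),
    metadata = list(simulation_seed = config$rng_seed))
  list(experiment = se, habitatProfiles = prof, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the on-disk dialects consumed by the package readers: counts.tsv
#' (ASV rows x ISO-8601 date columns), taxonomy.tsv, hydro.csv, isotopes.csv,
#' habitats.tsv (long-format environment hits scaled to fractions),
#' habitat_map.tsv and truth.json.
#'
#' @param sim result of \code{\link{simulateStormExperiment}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  se <- sim$experiment
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    hydro = file.path(dir, "hydro.csv"),
    isotopes = file.path(dir, "isotopes.csv"),
    habitats = file.path(dir, "habitats.tsv"),
    habitat_map = file.path(dir, "habitat_map.tsv"),
    truth = file.path(dir, "truth.json"))
  writeCountTable(asvCounts(se), paths["counts"])
  rd <- SummarizedExperiment::rowData(se)
  write.table(data.frame(asv_id = rownames(se), lineage = rd$lineage,
                         group = rd$group),
              paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  write.csv(cd[, c("date", "discharge_cms", "precip_mm")],
            paths["hydro"], row.names = FALSE, quote = FALSE)
  write.csv(cd[, c("date", "d2H", "d18O")],
            paths["isotopes"], row.names = FALSE, quote = FALSE)
  prof <- sim$habitatProfiles
  long <- data.frame(
    asv_id = rep(rownames(prof), ncol(prof)),
    habitat = rep(colnames(prof), each = nrow(prof)),
    hits = as.vector(round(prof * 1000)))
  long <- long[long$hits > 0, ]
  write.table(long[order(long$asv_id), ], paths["habitats"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(habitat = SOURCE_ENVIRONMENTS,
                         environment = SOURCE_ENVIRONMENTS),
              paths["habitat_map"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(taxon_class = as.list(truth$taxon_class),
         beta = as.list(truth$beta),
         event_threshold = truth$event_threshold,
         event_water_fraction = as.list(truth$event_water_fraction)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
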