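#' Default storm-period definitions
#'
#' Pre-event = the first \code{n_pre} sample days; early event = the
#' following days through the peak-discharge day; post-event = the remaining
#' days.
#'
#' @param dates sample dates.
#' @param discharge daily discharge aligned with \code{dates}.
#' @param n_pre number of baseline days (default 4).
#' @return named list of date vectors \code{pre}, \code{early_event},
#'   \code{post_event}.
#' @export
defaultPeriods <- function(dates, discharge, n_pre = 4) {
  dates <- as.Date(dates)
  peak <- which.max(discharge)
  list(pre = dates[seq_len(min(n_pre, length(dates)))],
       early_event = if (peak > n_pre) dates[(n_pre + 1):peak] else as.Date(character()),
       post_event = if (peak < length(dates)) dates[(peak + 1):length(dates)]
                    else as.Date(character()))
}

.default_run_config <- function() {
  list(rarefaction_depth = 4000, rarefaction_seed = 1,
       alpha = 0.1, min_detections = 3,
       n_surrogates = 1000, surrogate_seed = 1,
       n_coordinates = 4, n_preevent = 4,
       delta_new = -38.7, tracer = "d2H",
       outdir = NULL)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file of \code{\link{runPipeline}} settings and merges it over
#' the package defaults (rarefaction depth 4000, classifier alpha 0.1,
#' minimum 3 detections, 1000 surrogates).
#'
#' @param path YAML file; NULL returns the defaults.
#' @return named list of settings.
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

.write_stage <- function(obj, path) {
  if (is.matrix(obj)) {
    utils::write.table(data.frame(id = rownames(obj), obj, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(obj) && grepl("\\.tsv$", path)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(obj)) {
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  path
}

#' Run the full storm-tracer analysis
#'
#' Orchestrates rarefaction, alpha/beta diversity, PCoA, discharge
#' regressions, cQ classification, the shuffled-surrogates group test,
#' source-environment attribution, and isotopic hydrograph separation.
#' Stages whose inputs are absent (no isotope columns, no habitat profiles)
#' are skipped with a warning. When \code{config$outdir} is set, every
#' stage's table is written there along with \code{manifest.json} echoing
#' the configuration, seeds, package version and input checksums.
#'
#' @param experiment a \code{\linkS4class{StormExperiment}} with discharge
#'   (and optionally isotopes) in \code{colData}, or NULL to read from the
#'   paths in \code{config$inputs} (named \code{counts}, \code{taxonomy},
#'   \code{hydro}, \code{isotopes}, \code{habitats}, \code{habitat_map}).
#' @param config settings list from \code{\link{loadRunConfig}} (or any
#'   subset; missing entries take defaults).
#' @param habitatProfiles optional ASV x environment matrix; otherwise built
#'   from \code{config$inputs$habitats}.
#' @return a result bundle (list) with elements \code{alpha}, \code{bc},
#'   \code{preevent}, \code{pcoa}, \code{regressions}, \code{classification},
#'   \code{class_timeseries}, \code{group_fractions}, \code{surrogates},
#'   \code{env_fractions}, \code{period_contrast}, \code{mixing},
#'   \code{event_summary}, \code{periods}, \code{config}, \code{manifest}.
#' @export
runPipeline <- function(experiment = NULL, config = list(),
                        habitatProfiles = NULL) {
  base_cfg <- .default_run_config()
  base_cfg[names(config)] <- config
  cfg <- base_cfg
  inputs <- cfg$inputs

  checksums <- list()
  if (is.null(experiment)) {
    if (is.null(inputs$counts)) stop("either an experiment or input paths required")
    experiment <- readStormExperiment(inputs$counts, inputs$taxonomy,
                                      inputs$hydro, inputs$isotopes)
    files <- unlist(inputs)
    checksums <- as.list(tools::md5sum(files[file.exists(files)]))
  }
  if (is.null(discharge(experiment)))
    stop("stage 'input': experiment has no discharge series")
  if (is.null(habitatProfiles) && !is.null(inputs$habitats)) {
    hits <- readHabitatHits(inputs$habitats)
    map <- if (!is.null(inputs$habitat_map)) readHabitatMap(inputs$habitat_map)
    habitatProfiles <- aggregateHabitats(hits, map, rownames(experiment))
  }

  message("rarefying ", ncol(experiment), " samples to depth ",
          cfg$rarefaction_depth)
  rar <- rarefyCounts(experiment, depth = cfg$rarefaction_depth,
                      seed = cfg$rarefaction_seed)
  message("retained ", nrow(rar), " ASVs after rarefaction")
  q <- discharge(rar)
  dates <- sampleDates(rar)
  pre_dates <- dates[seq_len(min(cfg$n_preevent, length(dates)))]

  alpha <- alphaDiversity(rar)
  bc <- brayCurtisMatrix(rar)
  preevent <- meanPreeventDistance(bc, pre_dates)
  pc <- runPcoa(bc)
  iso <- isotopeSeries(rar)

  regs <- list(
    pcoa = dischargeFromCoordinates(pc, q, p = min(cfg$n_coordinates,
                                                   ncol(pcoaCoordinates(pc)))),
    diversity = diversityDischargeFit(alpha, q, isotopes = iso))

  cls <- classifyTaxa(rar, alpha = cfg$alpha,
                      min_detections = cfg$min_detections)
  message("classified taxa: ",
          paste(names(table(cls$label)), table(cls$label),
                sep = "=", collapse = ", "))
  cts <- classFractionTimeseries(rar, cls)
  groups <- SummarizedExperiment::rowData(rar)$group
  surr <- gcf <- NULL
  if (!is.null(groups)) {
    gvec <- stats::setNames(groups, rownames(rar))
    gcf <- suppressWarnings(groupClassFractions(rar, cls, gvec))
    message("running ", cfg$n_surrogates, " shuffled surrogates")
    surr <- surrogateNull(rar, groups = gvec, n_surrogates = cfg$n_surrogates,
                          seed = cfg$surrogate_seed, alpha = cfg$alpha,
                          min_detections = cfg$min_detections)
  } else warning("stage 'surrogates' skipped: no taxonomic groups available")

  periods <- defaultPeriods(dates, q, cfg$n_preevent)
  if (!is.null(cfg$periods)) periods[names(cfg$periods)] <-
    lapply(cfg$periods, as.Date)

  envf <- contrast <- NULL
  if (!is.null(habitatProfiles)) {
    envf <- communityEnvironmentFractions(rar, habitatProfiles)
    contrast <- suppressWarnings(periodContrast(envf, periods))
  } else warning("stage 'sources' skipped: no habitat profiles")

  mixing <- evs <- dex <- NULL
  if (!is.null(iso)) {
    dex <- data.frame(date = iso$date, d_excess = dExcess(iso$d2H, iso$d18O))
    mixing <- suppressWarnings(
      hydrographSeparation(iso, q, delta_new = cfg$delta_new,
                           preevent_dates = pre_dates, tracer = cfg$tracer))
    evs <- eventResponseSummary(q, mixing, pre_dates)
  } else {
    warning("stage 'isotopes' skipped: no isotope series")
    evs <- eventResponseSummary(q, preevent_dates = pre_dates)
  }

  bundle <- list(alpha = alpha, bc = bc, preevent = preevent, pcoa = pc,
                 regressions = regs, classification = cls,
                 class_timeseries = cts, group_fractions = gcf,
                 surrogates = surr, env_fractions = envf,
                 period_contrast = contrast, d_excess = dex, mixing = mixing,
                 event_summary = evs,
                 periods = lapply(periods, as.character), config = cfg)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    od <- cfg$outdir
    written <- c(
      .write_stage(alpha, file.path(od, "alpha.csv")),
      .write_stage(bc, file.path(od, "bc_matrix.tsv")),
      .write_stage(preevent, file.path(od, "preevent_distance.csv")),
      .write_stage(data.frame(date = dates, pcoaCoordinates(pc),
                              check.names = FALSE),
                   file.path(od, "pcoa_coords.csv")),
      .write_stage(regressionReport(list(pcoa = regs$pcoa$fit,
                                         diversity = regs$diversity)),
                   file.path(od, "regression_report.json")),
      .write_stage(cls, file.path(od, "classification.tsv")),
      .write_stage(cts, file.path(od, "class_fractions_by_day.csv")))
    if (!is.null(gcf))
      written <- c(written, .write_stage(gcf, file.path(od, "group_fractions.csv")))
    if (!is.null(surr))
      written <- c(written,
        .write_stage(c(list(seed = attr(surr, "seed"),
                            n_surrogates = attr(surr, "n_surrogates")),
                       list(table = surr)),
                     file.path(od, "surrogate_report.json")))
    if (!is.null(envf)) {
      written <- c(written,
        .write_stage(envf, file.path(od, "env_composition_by_day.csv")),
        .write_stage(contrast$differences, file.path(od, "period_differences.csv")),
        .write_stage(contrast$tests, file.path(od, "period_contrast.csv")))
      if (!is.null(habitatProfiles))
        written <- c(written,
          .write_stage(habitatProfiles, file.path(od, "env_profiles.tsv")))
    }
    if (!is.null(mixing))
      written <- c(written,
        .write_stage(dex, file.path(od, "d_excess.csv")),
        .write_stage(mixing, file.path(od, "mixing.csv")),
        .write_stage(evs, file.path(od, "summary.json")))
    manifest <- list(
      package = "stormtracer",
      version = as.character(utils::packageVersion("stormtracer")),
      config = cfg[setdiff(names(cfg), "outdir")],
      periods = lapply(periods, as.character),
      input_checksums = checksums,
      outputs = basename(written))
    .write_stage(manifest, file.path(od, "manifest.json"))
    bundle$manifest <- manifest
  }
  bundle
}

#' One-page summary of a pipeline result bundle
#'
#' Deterministic markdown summary: alpha-diversity extremes, regression fit
#' quality, counts per discharge-response class, significant group-class
#' pairs, significant source-environment shifts, and the peak mixing
#' fraction.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @return character vector of markdown lines (invisibly printable with
#'   \code{cat(..., sep = "\n")}).
#' @export
stormReport <- function(bundle) {
  ln <- c("# Storm-tracer analysis summary", "")
  a <- bundle$alpha
  ln <- c(ln, sprintf(
    "- Richness %d to %d; Shannon %.2f to %.2f bits (peak on %s).",
    min(a$richness), max(a$richness), min(a$shannon), max(a$shannon),
    format(a$date[which.max(a$richness)])))
  rp <- bundle$regressions$pcoa
  if (!is.null(rp))
    ln <- c(ln, sprintf(
      "- Discharge vs first %d principal coordinates: r2 = %.3f (adjusted %.3f).",
      rp$fit$p, rp$fit$r2, rp$fit$r2_adjusted))
  cls <- bundle$classification
  if (nrow(cls) == 0) {
    ln <- c(ln, "- Zero classified taxa.")
  } else {
    tab <- table(factor(cls$label, levels = CQ_CLASSES))
    ln <- c(ln, sprintf(
      "- Taxa: %d mobilized, %d diluted, %d static, %d uncharacterized.",
      tab["mobilized"], tab["diluted"], tab["static"], tab["uncharacterized"]))
  }
  s <- bundle$surrogates
  if (!is.null(s)) {
    sig <- s[s$significant & s$label != "uncharacterized", ]
    ln <- c(ln, if (nrow(sig))
      sprintf("- Significant group-class fractions (surrogate test): %s.",
              paste(sprintf("%s/%s (%.1f%%)", sig$group, sig$label,
                            100 * sig$observed_fraction), collapse = "; "))
      else "- No group-class fraction outside the surrogate bounds.")
  }
  ct <- bundle$period_contrast
  if (!is.null(ct) && !is.null(ct$tests)) {
    sig <- ct$tests[ct$tests$p_two_sided < 0.1, ]
    ln <- c(ln, if (nrow(sig))
      sprintf("- Source-environment shifts (Mann-Whitney, p < 0.1): %s.",
              paste(sprintf("%s %s in %s (p = %.3f)", sig$environment,
                            sig$direction, sig$period, sig$p_two_sided),
                    collapse = "; "))
      else "- No significant source-environment shift.")
  }
  e <- bundle$event_summary
  if (!is.null(e)) {
    ln <- c(ln, sprintf(
      "- Discharge %.2f to %.2f CMS (+%.0f%%), peak on %s.",
      e$q_pre_cms, e$q_peak_cms, e$percent_increase, e$peak_date))
    if (!is.null(e$peak_event_water_fraction))
      ln <- c(ln, sprintf(
        "- Event water at peak: fraction %.3f (%.2f CMS); old water %.3f.",
        e$peak_event_water_fraction, e$peak_event_water_cms,
        1 - e$peak_event_water_fraction))
  }
  ln
}
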