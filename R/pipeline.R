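# End-to-end workflow: simulate -> coherence -> PAC -> cluster stats ->
# peak tables and condition-ordering summary, with a YAML-configurable
# surface and deterministic, re-runnable outputs.

#' Default pipeline configuration
#'
#' Returns the pipeline configuration as a nested list: a \code{cohort}
#' section (arguments of \code{\link{cohortConfig}}), an \code{analysis}
#' section (peak-extraction bands, phase source, PAC grids and band widths)
#' and a \code{stats} section (arguments of
#' \code{\link{permutationConfig}}). Every analysis constant is surfaced as
#' a named key. The demo scale (10 subjects, 60 s, reduced amplitude grid)
#' keeps a full run in the minutes range; \code{ampStep = 0.5} restores the
#' full printed grid.
#'
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function() {
  list(
    cohort = list(nSubjects = 10, fs = 200, trialDuration = 60, nTrials = 1,
                  syllableRate = 5.5, prosodicRate = 1.8, gammaFreq = 33,
                  couplingDepth = 0.7, entrainmentStrength = 1, snr = 1,
                  tempoFactors = list(decelerated = 0.75, normal = 1,
                                      accelerated = 1.25),
                  rois = c("LAC", "RAC"), subjectRateSD = 0.25,
                  subjectGammaSD = 1.5, seed = 1),
    analysis = list(
      cohGrid = list(lo = 0.5, hi = 10, step = 0.5),
      deltaBand = list(lo = 0.5, hi = 2),
      thetaBand = list(lo = 3, hi = 9),
      phaseSource = "stimulus",
      phaseGrid = list(lo = 0.5, hi = 10, step = 0.5),
      ampGrid = list(lo = 10, hi = 50, step = 1),
      phaseHalfwidth = 0.5, ampHalfwidth = 7, nBins = 10),
    stats = list(nPerm = 200, alpha = 0.05, clusterFormingP = 0.05,
                 seed = 1))
}

readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultPipelineConfig()
  for (sec in names(base)) {
    if (!is.null(config[[sec]]))
      base[[sec]] <- utils::modifyList(base[[sec]], config[[sec]])
  }
  # maps are replaced wholesale, not key-merged with the defaults
  if (!is.null(config$cohort$tempoFactors))
    base$cohort$tempoFactors <- config$cohort$tempoFactors
  base
}

gridSeq <- function(g) seq(g$lo, g$hi, by = g$step)

stageLog <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[speechPAC] %-10s %6.1f s", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, computes per-subject coherence spectra and
#' comodulograms with their reversed-stimulus surrogates, runs
#' cluster-corrected group permutation tests, extracts band/cluster peaks,
#' and writes tidy result tables plus a JSON run manifest into
#' \code{outDir}. All randomness derives from the seeds in the
#' configuration, so identical configurations give identical tables.
#'
#' Files written: \code{coherence_peaks.tsv}, \code{pac_peaks.tsv}
#' (per-subject peak values), \code{coherence_group.tsv} (group-mean
#' spectra), \code{coherence_clusters.tsv} and \code{pac_clusters.tsv}
#' (cluster summaries), \code{report_entrainment.tsv} and
#' \code{report_pac.tsv} (group mean and standard error per condition, ROI
#' and band), \code{ordering_summary.tsv} (group-mean peak frequencies
#' versus tempo factor) and \code{manifest.json}.
#'
#' @param config a YAML file path or nested list
#'   (see \code{\link{defaultPipelineConfig}}); missing keys take defaults
#' @param outDir output directory, created if missing
#' @param quiet suppress per-stage progress messages
#' @return invisibly, the manifest as a list (with element \code{tables}
#'   holding all result data frames)
#' @export
runAll <- function(config = defaultPipelineConfig(), outDir, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  cfg <- readPipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ccArgs <- cfg$cohort
  ccArgs$tempoFactors <- unlist(ccArgs$tempoFactors)
  cohCfg <- do.call(cohortConfig, ccArgs)
  ana <- cfg$analysis
  statCfg <- permutationConfig(cfg$stats$nPerm, cfg$stats$alpha,
                               cfg$stats$clusterFormingP, cfg$stats$seed)
  cohGrid <- gridSeq(ana$cohGrid)
  phaseGrid <- gridSeq(ana$phaseGrid)
  ampGrid <- gridSeq(ana$ampGrid)
  bands <- list(bandDefinition("delta", ana$deltaBand$lo, ana$deltaBand$hi),
                bandDefinition("theta", ana$thetaBand$lo, ana$thetaBand$hi))

  cohort <- generateCohort(cohCfg)
  stageLog(quiet, "simulate", t0)

  conds <- names(cohCfg@tempoFactors)
  subjects <- groundTruth(cohort)$subject
  cohReal <- list(); cohSurr <- list()
  miReal <- list(); miSurr <- list()
  for (sid in subjects) for (cond in conds) {
    env <- cohortEnvelope(cohort, sid, cond)
    for (roi in cohCfg@rois) {
      neu <- cohortNeural(cohort, sid, cond, roi)
      key <- paste(cond, roi, sep = "|")
      cohReal[[key]][[sid]] <- coherenceSpectrum(env, neu, freqs = cohGrid)
      cohSurr[[key]][[sid]] <-
        surrogateCoherenceSpectrum(env, neu, freqs = cohGrid)
    }
  }
  stageLog(quiet, "entrain", t0)

  for (sid in subjects) for (cond in conds) {
    env <- cohortEnvelope(cohort, sid, cond)
    for (roi in cohCfg@rois) {
      neu <- cohortNeural(cohort, sid, cond, roi)
      key <- paste(cond, roi, sep = "|")
      miReal[[key]][[sid]] <- comodulogram(
        env, neu, phaseSource = ana$phaseSource, phaseFreqs = phaseGrid,
        ampFreqs = ampGrid, phaseHalfwidth = ana$phaseHalfwidth,
        ampHalfwidth = ana$ampHalfwidth, nBins = ana$nBins)
      miSurr[[key]][[sid]] <- surrogateComodulogram(
        env, neu, phaseSource = ana$phaseSource, phaseFreqs = phaseGrid,
        ampFreqs = ampGrid, phaseHalfwidth = ana$phaseHalfwidth,
        ampHalfwidth = ana$ampHalfwidth, nBins = ana$nBins)
    }
  }
  stageLog(quiet, "pac", t0)

  cohPeaks <- list(); pacPeaks <- list()
  cohClusters <- list(); pacClusters <- list()
  groupSpec <- list()
  for (key in names(cohReal)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    realM <- t(vapply(cohReal[[key]], coherenceValues,
                      numeric(length(cohGrid))))
    surrM <- t(vapply(cohSurr[[key]], coherenceValues,
                      numeric(length(cohGrid))))
    cl <- clusterPermutationPaired(realM, surrM, statCfg)
    sm <- clusterSummary(cl, freqs = cohGrid)
    if (nrow(sm)) { sm$condition <- parts[1]; sm$roi <- parts[2] }
    cohClusters[[key]] <- sm
    groupSpec[[key]] <- data.frame(condition = parts[1], roi = parts[2],
                                   freq_hz = cohGrid,
                                   coherence = colMeans(realM),
                                   surrogate = colMeans(surrM))
    for (sid in subjects) for (b in bands)
      cohPeaks[[paste(key, sid, b$name)]] <-
        bandPeak(cohReal[[key]][[sid]], b)

    realA <- array(unlist(lapply(miReal[[key]], miMatrix)),
                   dim = c(length(phaseGrid), length(ampGrid),
                           length(subjects)))
    realA <- aperm(realA, c(3, 1, 2))
    surrA <- array(unlist(lapply(miSurr[[key]], miMatrix)),
                   dim = c(length(phaseGrid), length(ampGrid),
                           length(subjects)))
    surrA <- aperm(surrA, c(3, 1, 2))
    cl2 <- clusterPermutationPaired(realA, surrA, statCfg)
    sm2 <- clusterSummary(cl2, freqs = list(phase = phaseGrid,
                                            amp = ampGrid))
    if (nrow(sm2)) { sm2$condition <- parts[1]; sm2$roi <- parts[2] }
    pacClusters[[key]] <- sm2
    mask <- significantMask(cl2, statCfg$alpha,
                            dim = c(length(phaseGrid), length(ampGrid)))
    if (!any(mask)) {
      warning("no significant PAC cluster for ", key,
              "; peaks taken over the whole comodulogram")
      mask <- NULL
    }
    for (sid in subjects)
      pacPeaks[[paste(key, sid)]] <- pacPeak(miReal[[key]][[sid]], mask)
  }
  stageLog(quiet, "stats", t0)

  cohPeaks <- do.call(rbind, unname(cohPeaks))
  pacPeaks <- do.call(rbind, unname(pacPeaks))
  repEnt <- reportTables(cohPeaks, values = c("cohMax", "fC"),
                         conditions = conds)
  pacPeaks$band <- "theta-gamma"
  repPac <- reportTables(pacPeaks, values = c("miMax", "fPhase", "fAmp"),
                         conditions = conds)
  ordering <- orderingSummary(cohPeaks, pacPeaks, cohCfg)

  tables <- list(
    coherence_peaks = cohPeaks, pac_peaks = pacPeaks,
    coherence_group = do.call(rbind, unname(groupSpec)),
    coherence_clusters = do.call(rbind, unname(cohClusters)),
    pac_clusters = do.call(rbind, unname(pacClusters)),
    report_entrainment = repEnt, report_pac = repPac,
    ordering_summary = ordering)
  for (nm in names(tables)) {
    p <- file.path(outDir, paste0(nm, ".tsv"))
    df <- tables[[nm]]
    if (is.null(df) || !nrow(df)) df <- data.frame(empty = logical(0))
    utils::write.table(format(df, digits = 8, scientific = FALSE,
                              trim = TRUE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = cfg, config_hash = configHash(as.character(cfgJson)),
    seed = cohCfg@seed,
    package_version = as.character(utils::packageVersion("speechPAC")),
    files = paste0(names(tables), ".tsv"),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stageLog(quiet, "report", t0)
  manifest$tables <- tables
  invisible(manifest)
}

#' Group mean / standard error report
#'
#' Summarizes a per-subject peaks table into group mean and standard error
#' per condition x ROI x band, one row per cell, mirroring the layout of
#' per-condition results tables.
#'
#' @param peaks data.frame with columns \code{subject}, \code{condition},
#'   \code{roi}, \code{band} and the value columns
#' @param values names of the value columns to summarize
#' @param conditions conditions expected in the table; missing ones produce
#'   a warning and are omitted
#' @return data.frame with columns \code{condition}, \code{roi},
#'   \code{band}, \code{n} and \code{<value>_mean} / \code{<value>_se} pairs
#' @examples
#' df <- data.frame(subject = c("a", "b", "c"), condition = "normal",
#'                  roi = "LAC", band = "theta", fC = c(5, 5.5, 6))
#' reportTables(df, values = "fC")
#' @export
reportTables <- function(peaks, values, conditions = unique(peaks$condition)) {
  stopIfNot(is.data.frame(peaks) && nrow(peaks) > 0, "empty peaks table")
  missing <- setdiff(conditions, unique(peaks$condition))
  if (length(missing))
    warning("missing condition(s): ", paste(missing, collapse = ", "),
            "; rows omitted")
  cells <- unique(peaks[, c("condition", "roi", "band")])
  cells <- cells[order(cells$condition, cells$roi, cells$band), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- peaks$condition == cells$condition[i] &
      peaks$roi == cells$roi[i] & peaks$band == cells$band[i]
    out <- cells[i, , drop = FALSE]
    out$n <- sum(sel)
    for (v in values) {
      x <- peaks[[v]][sel]
      out[[paste0(v, "_mean")]] <- mean(x)
      if (length(x) < 2) {
        warning("single subject in ", paste(unlist(cells[i, ]),
                                            collapse = "/"),
                "; standard error reported as 0")
        out[[paste0(v, "_se")]] <- 0
      } else out[[paste0(v, "_se")]] <- stats::sd(x) / sqrt(length(x))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Condition-ordering summary: group-mean peak frequencies vs tempo factor.
orderingSummary <- function(cohPeaks, pacPeaks, cohCfg) {
  conds <- names(cohCfg@tempoFactors)
  theta <- cohPeaks[cohPeaks$band == "theta", ]
  rows <- lapply(conds, function(cond) {
    data.frame(condition = cond,
               tempo_factor = unname(cohCfg@tempoFactors[cond]),
               f_c = mean(theta$fC[theta$condition == cond]),
               f_phase = mean(pacPeaks$fPhase[pacPeaks$condition == cond]),
               f_amp = mean(pacPeaks$fAmp[pacPeaks$condition == cond]))
  })
  out <- do.call(rbind, rows)
  out[order(out$tempo_factor), ]
}

#' Quick-look plots
#'
#' Base-graphics displays: a coherence spectrum as a line plot, a
#' comodulogram as an image with phase frequency on the x axis.
#'
#' @param x a \linkS4class{CoherenceSpectrum} or \linkS4class{Comodulogram}
#' @param y ignored
#' @param ... passed to the underlying plotting function
#' @return invisibly, NULL
#' @name plot-methods
#' @aliases plot,CoherenceSpectrum,missing-method
#' @export
setMethod("plot", signature(x = "CoherenceSpectrum", y = "missing"),
  function(x, y, ...) {
    graphics::plot(spectrumFreqs(x), coherenceValues(x), type = "l",
                   xlab = "Frequency (Hz)", ylab = "Coherence",
                   main = paste(subjectId(x), conditionLabel(x),
                                roiLabel(x)), ...)
    invisible(NULL)
  })

#' @rdname plot-methods
#' @aliases plot,Comodulogram,missing-method
#' @export
setMethod("plot", signature(x = "Comodulogram", y = "missing"),
  function(x, y, ...) {
    graphics::image(phaseFreqs(x), ampFreqs(x), miMatrix(x),
                    xlab = "Phase frequency (Hz)",
                    ylab = "Amplitude frequency (Hz)",
                    main = paste(subjectId(x), conditionLabel(x),
                                 roiLabel(x)), ...)
    invisible(NULL)
  })
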