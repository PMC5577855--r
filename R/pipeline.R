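## End-to-end orchestration: source -> sequence pool -> design -> simulated
## cohort -> PI and strategy tables, as one reproducible run directory.

#' Run configuration
#'
#' Bundles every parameter of a full simulated experiment. The defaults
#' reproduce the study protocol: a zero-order level (0.18, 0.72, 0.05,
#' 0.05) and the canonical first-order level, pools of 50 sequences kept
#' from 10,000 candidates of 672 symbols, 4 training sessions of 5 blocks
#' by 56 trials per level (1120 trials, within the 840-1400 protocol
#' range), and the default 20-responder cohort. All stage seeds are derived
#' deterministically from `masterSeed`.
#'
#' @param sources Named list of [MarkovSource-class] objects, one per level.
#' @param nGenerate,seqLength,nKeep Sequence-pool parameters.
#' @param sessionsPerLevel Training sessions per level (3-5, as in the
#'   protocol).
#' @param blocksPerSession Blocks per session.
#' @param lengthsSpec Per-block trial-length spec.
#' @param cohort List of [ResponderModel-class] objects, or `NULL` for
#'   [defaultCohort()].
#' @param epsilon Strategy smoothing floor.
#' @param masterSeed Integer master seed.
#' @return A `predstatRunConfig` list.
#' @export
runConfig <- function(sources = list(level0 = makeLevel0Source(),
                                     level1 = makeLevel1Source()),
                      nGenerate = 10000L, seqLength = 672L, nKeep = 50L,
                      sessionsPerLevel = 4L, blocksPerSession = 5L,
                      lengthsSpec = defaultLengthsSpec(),
                      cohort = NULL, epsilon = .DEFAULT_EPSILON,
                      masterSeed = 1L) {
  stopifnot(length(sources) >= 1L, !is.null(names(sources)))
  sessionsPerLevel <- as.integer(sessionsPerLevel)
  if (sessionsPerLevel < 3L || sessionsPerLevel > 5L)
    stop("sessionsPerLevel must lie in 3..5 (protocol range)")
  if (sum(lengthsSpec + 1L) != seqLength)
    stop(sprintf("lengthsSpec consumes %d symbols but seqLength is %d",
                 sum(lengthsSpec + 1L), seqLength))
  structure(list(sources = sources, nGenerate = as.integer(nGenerate),
                 seqLength = as.integer(seqLength), nKeep = as.integer(nKeep),
                 sessionsPerLevel = sessionsPerLevel,
                 blocksPerSession = as.integer(blocksPerSession),
                 lengthsSpec = as.integer(lengthsSpec), cohort = cohort,
                 epsilon = epsilon, masterSeed = as.integer(masterSeed)),
            class = "predstatRunConfig")
}

.writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Execute a full simulated experiment
#'
#' For each level: selects a sequence pool, builds the training sessions,
#' simulates every cohort member, and scores Performance Index, accuracy,
#' strategy curves and strategy indices. All tables are written as
#' tab-separated text under `outDir/<level>/`, together with a
#' machine-readable `manifest.json` (seeds, parameters, versions) and a
#' `log.txt` with stage timings. Re-running with the same config reproduces
#' every table byte-identically.
#'
#' @param config A [runConfig()] object.
#' @param outDir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a list with the in-memory results per level.
#' @export
runExperiment <- function(config, outDir, overwrite = FALSE) {
  stopifnot(inherits(config, "predstatRunConfig"))
  if (dir.exists(outDir) && length(dir(outDir)) && !overwrite)
    stop(sprintf("output directory '%s' is not empty; use overwrite = TRUE",
                 outDir))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "log.txt")
  cat(sprintf("predstat run started %s\n", format(Sys.time())),
      file = logPath)
  logStage <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logPath, append = TRUE)
  }
  nBlocksTotal <- config$sessionsPerLevel * config$blocksPerSession
  cohort <- config$cohort
  cohortSeed <- .deriveSeed(config$masterSeed, 900L)
  if (is.null(cohort)) cohort <- defaultCohort(nBlocksTotal, cohortSeed)
  seeds <- list(cohort = cohortSeed)
  results <- list()
  for (li in seq_along(config$sources)) {
    lvl <- names(config$sources)[li]
    src <- config$sources[[lvl]]
    lvlDir <- file.path(outDir, lvl)
    dir.create(lvlDir, showWarnings = FALSE)
    t0 <- Sys.time()

    selSeed <- .deriveSeed(config$masterSeed, li * 10L + 1L)
    seeds[[paste0(lvl, "_selection")]] <- selSeed
    pool <- selectSequences(src, config$nGenerate, config$seqLength,
                            config$nKeep, seed = selSeed)
    writeSequences(pool, file.path(lvlDir, "sequences.txt"))
    logStage("[%s] selected %d/%d sequences (%.1f s)", lvl, config$nKeep,
             config$nGenerate, as.numeric(Sys.time() - t0, units = "secs"))

    blocks <- list(); trialTab <- NULL
    for (s in seq_len(config$sessionsPerLevel)) {
      sSeed <- .deriveSeed(config$masterSeed, li * 100L + s)
      seeds[[sprintf("%s_session%d", lvl, s)]] <- sSeed
      sess <- buildTrainingSession(src, pool, config$blocksPerSession,
                                   seed = sSeed,
                                   lengthsSpec = config$lengthsSpec)
      ## re-index blocks globally across sessions
      for (b in seq_along(sess))
        sess[[b]]@blockIndex <- (s - 1L) * config$blocksPerSession + b
      trialTab <- rbind(trialTab, trialTable(sess, session = s))
      blocks <- c(blocks, sess)
    }
    .writeTSV(trialTab, file.path(lvlDir, "trials.tsv"))

    respTab <- NULL; piTab <- NULL; stratTab <- NULL; idxTab <- NULL
    sessionOf <- rep(seq_len(config$sessionsPerLevel),
                     each = config$blocksPerSession)
    for (m in cohort) {
      resp <- simulateResponses(m, blocks, src)
      rec <- resp@records
      respTab <- rbind(respTab, data.frame(
        responder_id = rec$responderId, session = sessionOf[rec$blockIndex],
        block = rec$blockIndex, trial = rec$trialIndex,
        context = rec$context, choice = ifelse(rec$isNull, "", rec$choice),
        is_null = rec$isNull, stringsAsFactors = FALSE))
      reports <- performanceIndex(resp, src)
      for (r in reports) {
        b <- r@blockIndex
        sub <- .subsetBlocks(resp, b)
        acc <- accuracy(sub, blocks)
        piTab <- rbind(piTab, data.frame(
          responder_id = m@id, session = sessionOf[b], block = b,
          pi = r@pi, pi_rand = r@piRand, pi_normalized = r@piNormalized,
          accuracy = acc, n_used = r@nUsed,
          n_null = sum(rec$blockIndex == b & rec$isNull)))
      }
      curve <- strategyCurve(resp, src, config$epsilon)
      stratTab <- rbind(stratTab, data.frame(
        responder_id = m@id, session = sessionOf[curve@blockIndices],
        block = curve@blockIndices, strategy_choice = curve@values,
        level = lvl, stringsAsFactors = FALSE))
      idx <- strategyIndex(curve, src, config$epsilon)
      idxTab <- rbind(idxTab, data.frame(
        responder_id = m@id, strategy_index = idx@value,
        n_blocks = idx@nBlocks,
        participant_integral = idx@participantIntegral,
        baseline_integral = idx@baselineIntegral))
    }
    .writeTSV(respTab, file.path(lvlDir, "responses.tsv"))
    .writeTSV(piTab, file.path(lvlDir, "pi.tsv"))
    .writeTSV(stratTab, file.path(lvlDir, "strategy.tsv"))
    .writeTSV(idxTab, file.path(lvlDir, "strategy_index.tsv"))
    logStage("[%s] simulated %d responders x %d blocks (%.1f s total)",
             lvl, length(cohort), length(blocks),
             as.numeric(Sys.time() - t0, units = "secs"))
    results[[lvl]] <- list(pool = pool, blocks = blocks, pi = piTab,
                           strategy = stratTab, strategyIndex = idxTab)
  }
  manifest <- list(
    package = "predstat",
    version = as.character(utils::packageVersion("predstat")),
    masterSeed = config$masterSeed,
    seeds = seeds,
    parameters = list(nGenerate = config$nGenerate,
                      seqLength = config$seqLength, nKeep = config$nKeep,
                      sessionsPerLevel = config$sessionsPerLevel,
                      blocksPerSession = config$blocksPerSession,
                      epsilon = config$epsilon,
                      trialsPerLevel = config$sessionsPerLevel *
                        config$blocksPerSession * length(config$lengthsSpec)),
    levels = names(config$sources),
    cohort = vapply(cohort, function(m) m@id, ""))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Summarize a completed run directory
#'
#' Reads the tables written by [runExperiment()] and computes per-responder
#' learning curves (PI by block), strategy curves, and the cohort-level
#' separation between asymptotic matchers and maximizers (difference of
#' their mean final-session strategy choices). Optionally writes simple
#' learning- and strategy-curve plots (PDF) into the run directory.
#'
#' @param runDir A directory produced by [runExperiment()].
#' @param plot Write `learning_curves.pdf` and `strategy_curves.pdf`.
#' @return A list with elements `levels` (per level: `piCurves`,
#'   `strategyCurves`, `separation`) and `manifest`.
#' @export
summarizeRun <- function(runDir, plot = FALSE) {
  manifestPath <- file.path(runDir, "manifest.json")
  if (!dir.exists(runDir) || !file.exists(manifestPath))
    stop(sprintf("'%s' is not a completed run directory", runDir))
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  out <- list(levels = list(), manifest = manifest)
  for (lvl in manifest$levels) {
    lvlDir <- file.path(runDir, lvl)
    piTab <- utils::read.table(file.path(lvlDir, "pi.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    stratTab <- utils::read.table(file.path(lvlDir, "strategy.tsv"),
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    piCurves <- stats::aggregate(pi ~ responder_id + block, piTab, mean)
    strCurves <- stats::aggregate(strategy_choice ~ responder_id + block,
                                  stratTab, mean)
    lastSession <- max(piTab$session)
    final <- stratTab[stratTab$session == lastSession, ]
    finalMean <- stats::aggregate(strategy_choice ~ responder_id, final,
                                  mean)
    isMax <- grepl("maximizer", finalMean$responder_id)
    isMat <- grepl("matcher", finalMean$responder_id)
    separation <- list(
      maximizerMean = mean(finalMean$strategy_choice[isMax]),
      matcherMean = mean(finalMean$strategy_choice[isMat]),
      difference = mean(finalMean$strategy_choice[isMax]) -
        mean(finalMean$strategy_choice[isMat]))
    out$levels[[lvl]] <- list(piCurves = piCurves,
                              strategyCurves = strCurves,
                              separation = separation)
    if (plot) {
      grDevices::pdf(file.path(lvlDir, "learning_curves.pdf"), 7, 5)
      ids <- unique(piCurves$responder_id)
      graphics::plot(NULL, xlim = range(piCurves$block),
                     ylim = c(0, 1), xlab = "block", ylab = "PI",
                     main = sprintf("%s learning curves", lvl))
      for (id in ids) {
        d <- piCurves[piCurves$responder_id == id, ]
        graphics::lines(d$block, d$pi, col = "grey50")
      }
      graphics::abline(h = piTab$pi_rand[1], lty = 2)
      grDevices::dev.off()
      grDevices::pdf(file.path(lvlDir, "strategy_curves.pdf"), 7, 5)
      graphics::plot(NULL, xlim = range(strCurves$block),
                     ylim = range(strCurves$strategy_choice),
                     xlab = "block", ylab = expression(Delta * "KL (bits)"),
                     main = sprintf("%s strategy curves", lvl))
      for (id in unique(strCurves$responder_id)) {
        d <- strCurves[strCurves$responder_id == id, ]
        graphics::lines(d$block, d$strategy_choice,
                        col = if (grepl("maximizer", id)) "firebrick"
                              else if (grepl("matcher", id)) "steelblue"
                              else "grey60")
      }
      graphics::abline(h = 0, lty = 2)
      grDevices::dev.off()
    }
  }
  out
}
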