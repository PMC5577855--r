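## Trial/block structure: cut a symbol stream into prediction trials, build
## training sessions and scanning runs.

#' Default per-block trial-length specification
#'
#' Eight trials at each context length 8-14, i.e. 56 trials consuming
#' `8 * sum(9:15) = 672` symbols (each trial uses its context plus one
#' hidden target).
#'
#' @return Integer vector of 56 trial lengths.
#' @export
defaultLengthsSpec <- function() rep(8:14, each = 8L)

#' Partition a symbol stream into a block of prediction trials
#'
#' The stream is consumed left-to-right without gaps: each trial takes its
#' context symbols and then one further symbol as the hidden target, so the
#' chain runs continuously across trials within the block. The order of
#' trial lengths within the block is a seeded shuffle of `lengthsSpec`
#' (every block shows the same multiset of lengths).
#'
#' @param sequence A [SymbolSequence-class] whose length equals
#'   `sum(lengthsSpec + 1)`.
#' @param lengthsSpec Multiset of context lengths (default
#'   [defaultLengthsSpec()]).
#' @param seed Integer seed for the length shuffle; `NULL` uses the current
#'   RNG stream.
#' @param blockIndex,levelLabel Metadata stored on the block.
#' @return A [Block-class].
#' @export
partitionBlock <- function(sequence, lengthsSpec = defaultLengthsSpec(),
                           seed = NULL, blockIndex = 1L,
                           levelLabel = sourceLabel(sequence)) {
  stopifnot(is(sequence, "SymbolSequence"))
  syms <- sequence@symbols
  need <- sum(lengthsSpec + 1L)
  if (length(syms) != need)
    stop(sprintf("sequence length (%d) must equal sum(lengths + 1) (%d)",
                 length(syms), need))
  ## shuffle via index permutation (sample(x) on a length-1 x permutes 1:x)
  lens <- .withSeed(seed, lengthsSpec[sample.int(length(lengthsSpec))])
  str <- paste0(syms, collapse = "")
  pos <- 1L
  ctx <- character(length(lens)); tgt <- character(length(lens))
  for (i in seq_along(lens)) {
    ctx[i] <- substring(str, pos, pos + lens[i] - 1L)
    tgt[i] <- substring(str, pos + lens[i], pos + lens[i])
    pos <- pos + lens[i] + 1L
  }
  new("Block",
      trials = data.frame(trial = seq_along(lens), length = as.integer(lens),
                          context = ctx, target = tgt,
                          stringsAsFactors = FALSE),
      blockIndex = as.integer(blockIndex), levelLabel = levelLabel,
      sourceLabel = sequence@sourceLabel, sequenceId = sequence@id)
}

#' Build one training session of blocks
#'
#' Draws `nBlocks` sequences at random from the selected-sequence pool
#' without replacement within the session, and partitions each into a block
#' of trials (default: 5 blocks of 56 trials, consuming 672 symbols each).
#'
#' @param source The generating [MarkovSource-class] (provenance only).
#' @param pool List of [SymbolSequence-class] objects (e.g. from
#'   [selectSequences()]).
#' @param nBlocks Blocks per session.
#' @param seed Integer seed governing both the pool draw and the per-block
#'   length shuffles.
#' @param lengthsSpec Per-block trial-length spec.
#' @return List of [Block-class] objects with `blockIndex` 1..nBlocks.
#' @export
buildTrainingSession <- function(source, pool, nBlocks = 5L, seed = 1L,
                                 lengthsSpec = defaultLengthsSpec()) {
  stopifnot(is(source, "MarkovSource"), length(pool) > 0L)
  nBlocks <- as.integer(nBlocks)
  if (length(pool) < nBlocks)
    stop(sprintf("pool of %d sequences cannot fill %d blocks without replacement",
                 length(pool), nBlocks))
  .withSeed(seed, {
    picks <- sample(length(pool), nBlocks)
    lapply(seq_len(nBlocks), function(b) {
      partitionBlock(pool[[picks[b]]], lengthsSpec, seed = NULL,
                     blockIndex = b, levelLabel = source@label)
    })
  })
}

#' Build one scanning run
#'
#' Five blocks of structured and five blocks of random sequences in a
#' seeded, counterbalanced random order, two trials per block, each trial a
#' 10-symbol context plus hidden target (10 structured and 10 random trials
#' per run).
#'
#' @param structured Structured [MarkovSource-class] (trained statistics).
#' @param random Random (uniform) [MarkovSource-class].
#' @param seed Integer seed for block order and sequence generation.
#' @param trialLength Context length per trial.
#' @param nBlocksPerType Blocks per sequence type.
#' @param trialsPerBlock Trials per block.
#' @return List of [Block-class] objects; each block's `levelLabel` is
#'   `"structured"` or `"random"`.
#' @export
buildScanningRun <- function(structured, random, seed = 1L,
                             trialLength = 10L, nBlocksPerType = 5L,
                             trialsPerBlock = 2L) {
  stopifnot(is(structured, "MarkovSource"), is(random, "MarkovSource"))
  .withSeed(seed, {
    labels <- sample(rep(c("structured", "random"), each = nBlocksPerType))
    lapply(seq_along(labels), function(b) {
      src <- if (labels[b] == "structured") structured else random
      seqLen <- trialsPerBlock * (trialLength + 1L)
      s <- generateSequence(src, seqLen, seed = NULL)
      partitionBlock(s, rep(trialLength, trialsPerBlock), seed = NULL,
                     blockIndex = b, levelLabel = labels[b])
    })
  })
}

#' Flatten blocks into a trial table
#'
#' @param blocks List of [Block-class] objects.
#' @param session Session number recorded in the table.
#' @return `data.frame` with columns `session, block, trial, context,
#'   target, level, source_label, trial_length`.
#' @export
trialTable <- function(blocks, session = 1L) {
  do.call(rbind, lapply(blocks, function(b) {
    tr <- b@trials
    data.frame(session = as.integer(session), block = b@blockIndex,
               trial = tr$trial, context = tr$context, target = tr$target,
               level = b@levelLabel, source_label = b@sourceLabel,
               trial_length = tr$length, stringsAsFactors = FALSE)
  }))
}

#' @rdname trialTable
#' @param x Trial table (`data.frame`).
#' @param path File path (tab-separated text).
#' @export
writeTrialTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trialTable
#' @export
readTrialTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(session = "integer", block = "integer",
                                   trial = "integer", context = "character",
                                   target = "character", level = "character",
                                   source_label = "character",
                                   trial_length = "integer"))
}
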