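## Performance Index family: AbDist, per-context PI, stationary-weighted PI,
## random-guess baseline, normalized PI, and plain accuracy.

#' Absolute distance between two response distributions
#'
#' L1 distance `sum(|p - q|)` between two distributions over the same
#' alphabet, in `[0, 2]`. `1 - abDist/2` is the overlap of the two
#' distributions, which is the Performance Index identity.
#'
#' @param p,q Numeric distributions over the same symbols (each summing to
#'   1 within 1e-9). If both are named they are aligned by name.
#' @return Numeric in `[0, 2]`.
#' @examples
#' abDist(rep(0.25, 4), c(0.18, 0.72, 0.05, 0.05))  # 0.94
#' @export
abDist <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("distributions are over different alphabets")
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("distributions are over different alphabets")
  }
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("both distributions must sum to 1")
  sum(abs(p - q))
}

#' Random-guess Performance Index baseline
#'
#' The PI attained by a responder choosing all symbols with equal
#' probability, evaluated against the source's context-conditional target
#' distributions and weighted by the stationary context probabilities. For
#' the canonical sources this reproduces the printed baselines: 0.53 for
#' the zero-order (0.18, 0.72, 0.05, 0.05) source and 0.45 for the
#' first-order 0.8/0.2 source.
#'
#' @param source A [MarkovSource-class].
#' @return Numeric in `[0, 1]`.
#' @export
piRand <- function(source) {
  stopifnot(is(source, "MarkovSource"))
  unif <- rep(1 / length(source@alphabet), length(source@alphabet))
  names(unif) <- source@alphabet
  piCtx <- stationaryDistribution(source, "context")
  perCtx <- vapply(names(piCtx), function(ctx)
    1 - abDist(unif, .ctxRow(source@probs, ctx)) / 2, 1.0)
  sum(piCtx * perCtx)
}

## Empirical response distribution per context from non-null records.
.responseCounts <- function(records, contexts, alphabet) {
  ok <- !records$isNull
  counts <- table(factor(records$context[ok], levels = contexts),
                  factor(records$choice[ok], levels = alphabet))
  matrix(as.integer(counts), nrow = length(contexts),
         dimnames = list(contexts, alphabet))
}

#' Performance Index of a response set
#'
#' For each block: per context, the distribution of non-null responses is
#' compared (L1 distance, overlap) with a reference target distribution,
#' and the per-context PIs are averaged with stationary-context weights.
#' `reference = "model"` (default) compares against the source's
#' conditional distributions; `reference = "empirical"` compares against
#' the targets actually realized in that block's trials (requires
#' `blocks`). A context with no non-null responses in a block contributes
#' its random-guess PI, keeping the weighted mean defined on small blocks.
#'
#' @param responses A [ResponseSet-class].
#' @param source The [MarkovSource-class] the design was generated from.
#' @param reference `"model"` or `"empirical"`.
#' @param blocks The design blocks (needed for `reference = "empirical"`).
#' @return Named list of [PIReport-class] objects, one per scored block.
#' @examples
#' # a responder answering B on every trial of the level-0 design scores
#' # PI = 1 - (0.18 + 0.28 + 0.05 + 0.05)/2 = 0.72
#' @export
performanceIndex <- function(responses, source,
                             reference = c("model", "empirical"),
                             blocks = NULL) {
  reference <- match.arg(reference)
  stopifnot(is(responses, "ResponseSet"), is(source, "MarkovSource"))
  rec <- responses@records
  if (nrow(rec) == 0L) stop("empty response set")
  if (reference == "empirical" && is.null(blocks))
    stop("reference = 'empirical' needs the design blocks")
  a <- source@alphabet
  k <- source@order
  unif <- rep(1 / length(a), length(a)); names(unif) <- a
  piCtx <- stationaryDistribution(source, "context")
  contexts <- names(piCtx)
  piRandVal <- piRand(source)
  blockIdx <- sort(unique(rec$blockIndex))
  reports <- lapply(blockIdx, function(b) {
    rb <- rec[rec$blockIndex == b, , drop = FALSE]
    counts <- .responseCounts(rb, contexts, a)
    refRows <- .ctxRow(source@probs, contexts)
    if (length(contexts) == 1L)
      refRows <- matrix(refRows, nrow = 1L,
                        dimnames = list(contexts, a))
    if (reference == "empirical") {
      tr <- blocks[[b]]@trials
      tctx <- if (k == 0L) rep("", nrow(tr)) else
        substring(tr$context, tr$length - k + 1L, tr$length)
      tcounts <- table(factor(tctx, levels = contexts),
                       factor(tr$target, levels = a))
      tcounts <- matrix(as.integer(tcounts), nrow = length(contexts),
                        dimnames = list(contexts, a))
      seen <- rowSums(tcounts) > 0
      refRows[seen, ] <- tcounts[seen, , drop = FALSE] /
        rowSums(tcounts)[seen]
    }
    ab <- vapply(seq_along(contexts), function(ci) {
      n <- sum(counts[ci, ])
      resp <- if (n > 0) counts[ci, ] / n else unif
      abDist(resp, refRows[ci, ])
    }, 1.0)
    names(ab) <- contexts
    pc <- 1 - ab / 2
    pival <- sum(piCtx * pc)
    new("PIReport", perContextAbDist = ab, perContextPI = pc,
        pi = pival, piRand = piRandVal, piNormalized = pival - piRandVal,
        nUsed = sum(!rb$isNull), blockIndex = as.integer(b))
  })
  names(reports) <- paste0("block", blockIdx)
  reports
}

#' Flatten PI reports into a table
#'
#' @param reports List of [PIReport-class] objects (from
#'   [performanceIndex()]).
#' @return `data.frame` with one row per block.
#' @export
piTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(block = r@blockIndex, pi = r@pi, pi_rand = r@piRand,
               pi_normalized = r@piNormalized, n_used = r@nUsed)))
}

#' Proportion of correctly predicted trials
#'
#' A trial is correct when the choice equals the hidden target of the
#' predefined sequence; null responses count as incorrect.
#'
#' @param responses A [ResponseSet-class].
#' @param blocks The design blocks the responses were simulated on (block
#'   `p` in the list corresponds to `blockIndex p`).
#' @return Numeric in `[0, 1]`.
#' @export
accuracy <- function(responses, blocks) {
  rec <- responses@records
  if (max(rec$blockIndex) > length(blocks))
    stop("responses refer to blocks beyond the supplied design")
  correct <- logical(nrow(rec))
  for (p in unique(rec$blockIndex)) {
    sel <- rec$blockIndex == p
    tr <- blocks[[p]]@trials
    tgt <- tr$target[match(rec$trialIndex[sel], tr$trial)]
    if (anyNA(tgt)) stop("responses/blocks trial mismatch")
    ch <- rec$choice[sel]
    correct[sel] <- !is.na(ch) & ch == tgt
  }
  mean(correct)
}
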