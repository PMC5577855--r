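## Synthetic responders: policies spanning uniform guessing, probability
## matching and maximization, with lapse noise, null responses and a
## learning time course across blocks.

#' Construct a responder model
#'
#' See [ResponderModel-class] for the meaning of each field. On every trial
#' the simulator first draws a null response with probability `nullRate`,
#' then a uniform lapse with probability `lapse`, and otherwise responds
#' per policy.
#'
#' @param policy `"uniform"`, `"matcher"`, `"maximizer"` or `"mixture"`.
#' @param lapse Uniform-lapse probability.
#' @param nullRate Null-response probability.
#' @param schedule Per-block mixture weights (mixture policy).
#' @param asymptoticPolicy `"matcher"` or `"maximizer"` (mixture policy).
#' @param seed Integer RNG seed.
#' @param id Responder identifier.
#' @return A [ResponderModel-class].
#' @export
responderModel <- function(policy = c("uniform", "matcher", "maximizer",
                                      "mixture"),
                           lapse = 0, nullRate = 0, schedule = numeric(),
                           asymptoticPolicy = NA_character_, seed = 1L,
                           id = NULL) {
  policy <- match.arg(policy)
  if (is.null(id)) id <- policy
  new("ResponderModel", id = id, policy = policy, lapse = lapse,
      nullRate = nullRate, schedule = as.numeric(schedule),
      asymptoticPolicy = as.character(asymptoticPolicy),
      seed = as.integer(seed))
}

#' Saturating learning schedule
#'
#' Mixture weights `w(b) = ceiling - (ceiling - floor) * exp(-rate * b)` for
#' blocks `b = 1..nBlocks`: monotone non-decreasing, rising from near
#' `floor` toward `ceiling`, emulating a participant whose responses drift
#' from uniform guessing toward an asymptotic policy over training.
#'
#' @param nBlocks Number of training blocks.
#' @param rate Learning rate (> 0, per block).
#' @param floor,ceiling Weight bounds, `0 <= floor <= ceiling <= 1`.
#' @return Numeric vector of length `nBlocks`.
#' @export
learningSchedule <- function(nBlocks, rate, floor = 0, ceiling = 1) {
  if (rate <= 0) stop("rate must be > 0")
  if (floor < 0 || ceiling > 1 || floor > ceiling)
    stop("need 0 <= floor <= ceiling <= 1")
  b <- seq_len(nBlocks)
  ceiling - (ceiling - floor) * exp(-rate * b)
}

## Modal target per context, ties broken by alphabet order.
.modalTargets <- function(source) {
  apply(source@probs, 1L, which.max)
}

#' Simulate per-trial responses of one responder
#'
#' For each trial, the conditioning context is the trailing `k` symbols of
#' the displayed context (`k = markovOrder(source)`). Response rule, in
#' order: null with probability `nullRate`; uniform lapse with probability
#' `lapse`; otherwise `uniform` draws equiprobably, `matcher` samples the
#' source's conditional distribution, `maximizer` picks the modal target
#' (alphabet-order tie-break) and `mixture` plays the asymptotic policy
#' with the block's scheduled weight and guesses uniformly otherwise.
#' Fully reproducible given the model's seed.
#'
#' @param model A [ResponderModel-class].
#' @param blocks List of [Block-class] objects; block `p` in the list is
#'   scored as `blockIndex p` and uses schedule weight `p`.
#' @param source The [MarkovSource-class] defining contexts and
#'   conditional distributions.
#' @return A [ResponseSet-class] with one record per trial.
#' @export
simulateResponses <- function(model, blocks, source) {
  stopifnot(is(model, "ResponderModel"), is(source, "MarkovSource"))
  k <- source@order
  a <- source@alphabet
  nA <- length(a)
  cum <- t(apply(source@probs, 1L, cumsum))
  modal <- .modalTargets(source)
  ctxNames <- rownames(source@probs)
  recs <- .withSeed(model@seed, lapply(seq_along(blocks), function(p) {
    tr <- blocks[[p]]@trials
    if (any(tr$length < k))
      stop("trial context shorter than the source order")
    ctx <- if (k == 0L) rep("", nrow(tr)) else
      substring(tr$context, tr$length - k + 1L, tr$length)
    ctxIdx <- match(ctx, ctxNames)
    n <- nrow(tr)
    isNull <- stats::runif(n) < model@nullRate
    isLapse <- stats::runif(n) < model@lapse
    ## policy choice for every trial (draws consumed regardless of
    ## null/lapse so the stream layout is simple and reproducible)
    uniformDraw <- sample.int(nA, n, replace = TRUE)
    pick <- switch(model@policy,
      uniform = uniformDraw,
      matcher = 1L + as.integer(
        rowSums(stats::runif(n) > cum[ctxIdx, , drop = FALSE])),
      maximizer = modal[ctxIdx],
      mixture = {
        w <- model@schedule[min(p, length(model@schedule))]
        useAsym <- stats::runif(n) < w
        asym <- if (model@asymptoticPolicy == "matcher")
          1L + as.integer(rowSums(stats::runif(n) > cum[ctxIdx, , drop = FALSE]))
        else modal[ctxIdx]
        ifelse(useAsym, asym, uniformDraw)
      })
    choice <- a[ifelse(isLapse, uniformDraw, pick)]
    choice[isNull] <- NA_character_
    data.frame(responderId = model@id, blockIndex = p,
               trialIndex = tr$trial, context = ctx, choice = choice,
               isNull = isNull, stringsAsFactors = FALSE)
  }))
  new("ResponseSet", records = do.call(rbind, recs), alphabet = a)
}

#' Default synthetic cohort
#'
#' Twenty responders spanning the matching-maximization axis: 12 learners
#' (mixture policy, lapse 0/0.1/0.2 x asymptotic matcher/maximizer x
#' learning rate 0.2/0.5, schedule rising from uniform guessing), 6 pure
#' (non-learning) matchers/maximizers at the same lapses, and 2 uniform
#' guessers. All have a 2% null-response rate.
#'
#' @param nBlocks Number of training blocks the learners' schedules cover.
#' @param seed Master seed; each responder receives a derived seed.
#' @return Named list of 20 [ResponderModel-class] objects.
#' @export
defaultCohort <- function(nBlocks = 20L, seed = 1L) {
  grid <- expand.grid(lapse = c(0, 0.1, 0.2),
                      policy = c("matcher", "maximizer"),
                      rate = c(0.2, 0.5),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  models <- list()
  i <- 0L
  for (r in seq_len(nrow(grid))) {
    i <- i + 1L
    id <- sprintf("learn_%s_l%g_r%g", grid$policy[r], grid$lapse[r],
                  grid$rate[r])
    models[[id]] <- responderModel(
      "mixture", lapse = grid$lapse[r], nullRate = 0.02,
      schedule = learningSchedule(nBlocks, grid$rate[r]),
      asymptoticPolicy = grid$policy[r],
      seed = .deriveSeed(seed, i), id = id)
  }
  for (pol in c("matcher", "maximizer")) for (lp in c(0, 0.1, 0.2)) {
    i <- i + 1L
    id <- sprintf("pure_%s_l%g", pol, lp)
    models[[id]] <- responderModel(pol, lapse = lp, nullRate = 0.02,
                                   seed = .deriveSeed(seed, i), id = id)
  }
  for (j in 1:2) {
    i <- i + 1L
    id <- sprintf("uniform_%d", j)
    models[[id]] <- responderModel("uniform", nullRate = 0.02,
                                   seed = .deriveSeed(seed, i), id = id)
  }
  models
}
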