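## Plain-text serialization: source configs (YAML), sequence pools
## (one sequence per line plus a manifest), response tables.

#' Read and write source configuration files
#'
#' A source config is a small YAML document with `label`, `alphabet`,
#' `order` and either `probs` (order 0: symbol -> probability) or `rows`
#' (order >= 1: context -> target -> probability). Round-trips exactly.
#'
#' @param source A [MarkovSource-class].
#' @param path File path.
#' @return `readSourceConfig` returns a [MarkovSource-class];
#'   `writeSourceConfig` invisibly returns `path`.
#' @export
writeSourceConfig <- function(source, path) {
  stopifnot(is(source, "MarkovSource"))
  cfg <- list(label = source@label,
              alphabet = as.list(source@alphabet),
              order = source@order)
  if (source@order == 0L) {
    cfg$probs <- as.list(source@probs[1L, ])
  } else {
    cfg$rows <- lapply(rownames(source@probs), function(ctx) {
      row <- .ctxRow(source@probs, ctx)
      as.list(row[row > 0])
    })
    names(cfg$rows) <- rownames(source@probs)
  }
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname writeSourceConfig
#' @export
readSourceConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  a <- unlist(cfg$alphabet)
  k <- as.integer(cfg$order)
  if (k == 0L) {
    probs <- unlist(cfg$probs)[a]
    return(makeLevel0Source(probs, alphabet = a, label = cfg$label))
  }
  ctxs <- .allContexts(a, k)
  P <- matrix(0, length(ctxs), length(a), dimnames = list(ctxs, a))
  for (ctx in names(cfg$rows)) {
    row <- unlist(cfg$rows[[ctx]])
    P[ctx, names(row)] <- row
  }
  if (k == 1L) makeLevel1Source(P, alphabet = a, label = cfg$label,
                                strict = FALSE)
  else new("MarkovSource", alphabet = a, order = k, probs = P,
           label = cfg$label)
}

#' Read and write sequence pools
#'
#' Sequences are written one per line as single-character symbols to
#' `<path>`; a tab-separated manifest `<path>.manifest.tsv` records
#' sequence id, source label, seed and KL divergence.
#'
#' @param sequences List of [SymbolSequence-class] objects.
#' @param path Sequence file path.
#' @param alphabet Alphabet to assume when reading.
#' @return `readSequences` returns a named list of
#'   [SymbolSequence-class] objects.
#' @export
writeSequences <- function(sequences, path) {
  lines <- vapply(sequences, function(s) paste0(s@symbols, collapse = ""), "")
  writeLines(lines, path)
  manifest <- data.frame(
    id = vapply(sequences, function(s) s@id, ""),
    source_label = vapply(sequences, function(s) s@sourceLabel, ""),
    seed = vapply(sequences, function(s) s@seed, 1L),
    kl = vapply(sequences, function(s) s@kl, 1.0),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, paste0(path, ".manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSequences
#' @export
readSequences <- function(path, alphabet = c("A", "B", "C", "D")) {
  lines <- readLines(path)
  manifest <- utils::read.table(paste0(path, ".manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  stopifnot(nrow(manifest) == length(lines))
  out <- lapply(seq_along(lines), function(i) {
    new("SymbolSequence", symbols = strsplit(lines[i], "")[[1]],
        alphabet = alphabet, sourceLabel = manifest$source_label[i],
        seed = as.integer(manifest$seed[i]), kl = manifest$kl[i],
        id = manifest$id[i])
  })
  names(out) <- manifest$id
  out
}

#' Read and write response tables
#'
#' Tab-separated text with columns `responder_id, session, block, trial,
#' context, choice, is_null` (null choices are stored as the empty string).
#'
#' @param responses A [ResponseSet-class].
#' @param path File path.
#' @param session Session number recorded in the table.
#' @param alphabet Alphabet to assume when reading.
#' @export
writeResponseTable <- function(responses, path, session = 1L) {
  rec <- responses@records
  out <- data.frame(responder_id = rec$responderId,
                    session = as.integer(session),
                    block = rec$blockIndex, trial = rec$trialIndex,
                    context = rec$context,
                    choice = ifelse(rec$isNull, "", rec$choice),
                    is_null = rec$isNull, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResponseTable
#' @export
readResponseTable <- function(path, alphabet = c("A", "B", "C", "D")) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(choice = "character",
                                        context = "character"))
  new("ResponseSet",
      records = data.frame(responderId = x$responder_id,
                           blockIndex = as.integer(x$block),
                           trialIndex = as.integer(x$trial),
                           context = x$context,
                           choice = ifelse(x$is_null, NA_character_,
                                           x$choice),
                           isNull = as.logical(x$is_null),
                           stringsAsFactors = FALSE),
      alphabet = alphabet)
}
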