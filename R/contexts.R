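#' Extract two-word contexts for every token
#'
#' Each utterance is padded with two opening boundary symbols `{` before and
#' two closing symbols `}` after, so that every real token has a full
#' two-word context under each scheme and no n-gram spans an utterance
#' boundary. The three schemes are:
#' * `left`: the two words immediately preceding the target, key
#'   (w-2, w-1);
#' * `right`: the two words immediately following, key (w+1, w+2);
#' * `framing`: one word before and one after, key (w-1, w+1).
#'
#' The one-word backoff key is the word nearest the target on the
#' predictive side: w-1 for left and framing, w+1 for right.
#'
#' @param corpus A [tagged_corpus()] or `projected_corpus`.
#' @param scheme `"left"`, `"right"` or `"framing"`.
#' @return A tibble with one row per token: `utterance_id`, `position`
#'   (within the utterance), `form`, `pos`, `lemma`, `tier` (`NA` when the
#'   corpus is not projected), the two-word key (`key1`, `key2`), the
#'   one-word `backoff` key, the `nearest` context word, a printable
#'   `context` string (`"le _ éléphant"`, `"{{ _"`, `"_ }}"`, ...) and the
#'   `target_label` (projection symbol when projected, else the surface
#'   form).
#' @examples
#' corp <- tagged_corpus(tibble::tibble(
#'   utterance_id = 1, form = c("le", "chat", "dort"),
#'   pos = c("DET", "NOUN", "VERB")))
#' extract_contexts(corp, "framing")
#' @export
extract_contexts <- function(corpus, scheme = c("left", "right", "framing")) {
  scheme <- match.arg(scheme)
  tok <- corpus$tokens
  if (!"tier" %in% names(tok)) tok$tier <- NA_character_
  ctx <- tok |>
    group_by(.data$utterance_id) |>
    mutate(position = row_number(),
           wm1 = lag(.data$form, 1, default = BOUNDARY_OPEN),
           wm2 = lag(.data$form, 2, default = BOUNDARY_OPEN),
           wp1 = lead(.data$form, 1, default = BOUNDARY_CLOSE),
           wp2 = lead(.data$form, 2, default = BOUNDARY_CLOSE)) |>
    ungroup()
  ctx <- switch(scheme,
    left = mutate(ctx, key1 = .data$wm2, key2 = .data$wm1,
                  backoff = .data$wm1, nearest = .data$wm1),
    right = mutate(ctx, key1 = .data$wp1, key2 = .data$wp2,
                   backoff = .data$wp1, nearest = .data$wp1),
    framing = mutate(ctx, key1 = .data$wm1, key2 = .data$wp1,
                     backoff = .data$wm1, nearest = .data$wm1))
  ctx |>
    mutate(context = format_context(scheme, .data$key1, .data$key2),
           target_label = ifelse(is.na(.data$tier), .data$form, .data$tier)) |>
    select("utterance_id", "position", "form", "pos", "lemma", "tier",
           "key1", "key2", "backoff", "nearest", "context", "target_label")
}

# printable context, with adjacent boundary symbols collapsed ("{{ _")
format_context <- function(scheme, key1, key2) {
  s <- switch(scheme,
              left = paste(key1, key2, "_"),
              right = paste("_", key1, key2),
              framing = paste(key1, "_", key2))
  s <- gsub("{ {", "{{", s, fixed = TRUE)
  gsub("} }", "}}", s, fixed = TRUE)
}

format_backoff_context <- function(scheme, backoff) {
  switch(scheme,
         left = paste(backoff, "_"),
         right = paste("_", backoff),
         framing = paste(backoff, "_"))
}

# deterministic "most frequent completer" per key: highest count wins;
# ties prefer category symbols (N before V) over wordforms, then
# lexicographic order. `tie` marks keys where the rule was actually applied.
best_completers <- function(counts, keys) {
  counts |>
    mutate(.rank = match(.data$completer, c("N", "V"), nomatch = 3L)) |>
    group_by(across(all_of(keys))) |>
    mutate(tie = sum(.data$count == max(.data$count)) > 1L) |>
    arrange(desc(.data$count), .data$.rank, .data$completer,
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select(all_of(keys), "completer", "count", "tie")
}

#' Count boundary-padded trigram and bigram completions
#'
#' For every token of a projected training corpus, under the given scheme,
#' increments `trigram[two-word key][completer]` and
#' `bigram[one-word key][completer]`, where the completer is the projection
#' symbol (`N`/`V`) for seed tokens and the surface form otherwise. Context
#' words are always surface forms (a seed word occurring *in* a context is
#' kept verbatim). Training word frequencies, the training vocabulary and
#' the token total are recorded for the target-selection filter.
#'
#' @param projected A corpus returned by [project_seed()].
#' @param scheme Context scheme (see [extract_contexts()]).
#' @return An object of class `completion_counts`.
#' @export
train_tables <- function(projected, scheme = c("left", "right", "framing")) {
  scheme <- match.arg(scheme)
  if (n_tokens(projected) == 0) {
    stop("cannot train on an empty corpus", call. = FALSE)
  }
  if (!"tier" %in% names(projected$tokens)) {
    stop("`projected` must be a projected corpus (see project_seed())",
         call. = FALSE)
  }
  ctx <- extract_contexts(projected, scheme)
  ctx$completer <- ctx$target_label
  trigram <- count(ctx, .data$key1, .data$key2, .data$completer,
                   name = "count")
  bigram <- count(ctx, .data$backoff, .data$completer, name = "count")
  wf <- table(projected$tokens$form)
  structure(list(
    scheme = scheme,
    trigram = trigram,
    bigram = bigram,
    trigram_best = best_completers(trigram, c("key1", "key2")),
    bigram_best = best_completers(bigram, "backoff"),
    training_token_total = n_tokens(projected),
    training_word_freq = setNames(as.integer(wf), names(wf)),
    training_vocab = names(wf),
    seed_id = projected$seed_id
  ), class = "completion_counts")
}

#' @export
print.completion_counts <- function(x, ...) {
  cat(sprintf(
    "<completion_counts (%s): %d trigram keys, %d bigram keys, %d training tokens>\n",
    x$scheme, nrow(x$trigram_best), nrow(x$bigram_best),
    x$training_token_total))
  invisible(x)
}

#' Select target sites in a test corpus
#'
#' A token is a target for categorization iff (a) it is rare: its training
#' frequency relative to the training token total is below `threshold`
#' (words never seen in training have frequency 0 and qualify; words at or
#' above the threshold are excluded), and (b) the context word nearest to
#' the target on the predictive side occurred in the training vocabulary or
#' is a boundary symbol. Condition (b) can be switched off (used by the
#' context-blind baseline). An absolute-count variant of (a) is available
#' via `rule = "count"`.
#'
#' @param test A [tagged_corpus()].
#' @param counts A [train_tables()] result.
#' @param threshold Relative-frequency cutoff (exclusive upper bound);
#'   default 0.05%.
#' @param rule `"ratio"` (default) or `"count"` (exclude words seen
#'   `max_count` times or more).
#' @param max_count Absolute cutoff for `rule = "count"`.
#' @param require_known_context Apply condition (b).
#' @return A tibble of target sites (rows of [extract_contexts()] plus
#'   `train_freq`).
#' @export
select_targets <- function(test, counts, threshold = 5e-4,
                           rule = c("ratio", "count"), max_count = 17L,
                           require_known_context = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(counts, "completion_counts"))
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  ctx <- extract_contexts(test, counts$scheme)
  f <- counts$training_word_freq[ctx$form]
  f[is.na(f)] <- 0L
  ctx$train_freq <- as.integer(f)
  rare <- if (rule == "ratio") {
    ctx$train_freq / counts$training_token_total < threshold
  } else {
    ctx$train_freq < max_count
  }
  known <- ctx$nearest %in% counts$training_vocab |
    ctx$nearest %in% c(BOUNDARY_OPEN, BOUNDARY_CLOSE)
  ctx[rare & (known | !require_known_context), ]
}

#' Predict a category (or wordform) for each target site
#'
#' If the site's two-word key was seen in training, the most frequent
#' completer of that trigram is the response (provenance `"trigram"`); else
#' if the one-word backoff key was seen, the most frequent completer of that
#' bigram is the response (provenance `"bigram"`; for framing contexts the
#' backoff uses the left word); else the model abstains.
#'
#' @param sites Target sites from [select_targets()].
#' @param counts A [train_tables()] result.
#' @return The sites with columns `response` (`"N"`, `"V"`, a wordform, or
#'   `NA` on abstention), `response_type` (`"category"`, `"wordform"`,
#'   `"abstain"`), `provenance` (`"trigram"`, `"bigram"`, `"none"`),
#'   `context_used` and `tie` (whether the tie-break rule fired).
#' @export
predict_targets <- function(sites, counts) {
  stopifnot(inherits(counts, "completion_counts"))
  tri <- rename(counts$trigram_best, tri_completer = "completer",
                tri_tie = "tie")[, c("key1", "key2", "tri_completer",
                                     "tri_tie")]
  bi <- rename(counts$bigram_best, bi_completer = "completer",
               bi_tie = "tie")[, c("backoff", "bi_completer", "bi_tie")]
  out <- sites |>
    left_join(tri, by = c("key1", "key2")) |>
    left_join(bi, by = "backoff")
  use_tri <- !is.na(out$tri_completer)
  use_bi <- !use_tri & !is.na(out$bi_completer)
  out$response <- ifelse(use_tri, out$tri_completer,
                         ifelse(use_bi, out$bi_completer, NA_character_))
  out$provenance <- ifelse(use_tri, "trigram",
                           ifelse(use_bi, "bigram", "none"))
  out$response_type <- ifelse(is.na(out$response), "abstain",
                              ifelse(out$response %in% c("N", "V"),
                                     "category", "wordform"))
  out$context_used <- ifelse(
    use_tri, out$context,
    ifelse(use_bi, format_backoff_context(counts$scheme, out$backoff),
           NA_character_))
  out$tie <- ifelse(use_tri, out$tri_tie, ifelse(use_bi, out$bi_tie, FALSE))
  out$tri_completer <- out$tri_tie <- out$bi_completer <- out$bi_tie <- NULL
  out
}

#' Categorize every eligible token of a test corpus
#'
#' Applies [select_targets()] then [predict_targets()] in corpus order;
#' the result is deterministic for identical inputs.
#'
#' @inheritParams select_targets
#' @param quiet Suppress the tie-break message.
#' @return A tibble of prediction records (see [predict_targets()]).
#' @export
categorize_corpus <- function(test, counts, threshold = 5e-4,
                              rule = c("ratio", "count"), max_count = 17L,
                              quiet = FALSE) {
  sites <- select_targets(test, counts, threshold = threshold, rule = rule,
                          max_count = max_count)
  rec <- predict_targets(sites, counts)
  n_tie <- sum(rec$tie, na.rm = TRUE)
  if (!quiet && n_tie > 0) {
    message("tie-break rule applied at ", n_tie, " site(s)")
  }
  rec
}

#' Serialize and re-read completion count tables
#'
#' Writes a documented TSV with columns `scheme`, `ngram`
#' (`trigram`/`bigram`), `w1`, `w2` (empty for bigram rows), `completer` and
#' `count`, for inspection and round-trip testing.
#'
#' @param counts A [train_tables()] result.
#' @param path Output (input) file path.
#' @return `read_counts_tsv()` returns a list with elements `scheme`,
#'   `trigram` and `bigram` matching the written tables.
#' @export
write_counts_tsv <- function(counts, path) {
  tri <- counts$trigram
  bi <- counts$bigram
  df <- bind_rows(
    tibble(scheme = counts$scheme, ngram = "trigram", w1 = tri$key1,
           w2 = tri$key2, completer = tri$completer, count = tri$count),
    tibble(scheme = counts$scheme, ngram = "bigram", w1 = bi$backoff,
           w2 = NA_character_, completer = bi$completer, count = bi$count))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccccci", progress = FALSE)
  tri <- df[df$ngram == "trigram", ]
  bi <- df[df$ngram == "bigram", ]
  list(scheme = df$scheme[1],
       trigram = tibble(key1 = tri$w1, key2 = tri$w2,
                        completer = tri$completer, count = tri$count),
       bigram = tibble(backoff = bi$w1, completer = bi$completer,
                       count = bi$count))
}
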