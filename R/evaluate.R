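#' Majority gold tag per wordform
#'
#' Used to label wordform responses in the error taxonomy: a wordform reply
#' is classified by the majority gold tag of that form over the supplied
#' corpora (conventionally train + test). Ties are broken by tag
#' lexicographic order.
#'
#' @param ... One or more [tagged_corpus()] objects.
#' @return A named character vector mapping form to its majority POS tag.
#' @export
majority_tags <- function(...) {
  corpora <- list(...)
  tok <- bind_rows(lapply(corpora, corpus_tokens))
  if (nrow(tok) == 0) return(setNames(character(0), character(0)))
  tab <- tok |>
    count(.data$form, .data$pos, name = "n") |>
    arrange(.data$form, desc(.data$n), .data$pos) |>
    group_by(.data$form) |>
    slice_head(n = 1) |>
    ungroup()
  setNames(tab$pos, tab$form)
}

#' Code model responses as N, V or other
#'
#' A category response is coded as itself. A wordform response is coded
#' "other" with a detail label describing what was answered: `item-N` /
#' `item-V` for specific nouns and verbs, otherwise the responded word's
#' majority gold tag (`ADJ`, `ADV`, `PRON`, ...), or `UNKNOWN` when the
#' form is absent from the tag map. The baseline's explicit "other" draws
#' are coded "other" with detail `"other"`. Abstentions get `NA` coding
#' (they are excluded from scoring by default).
#'
#' @param records Prediction records ([predict_targets()] or
#'   [chance_predict()]).
#' @param wordform_tags A [majority_tags()] map (required when any response
#'   is a wordform).
#' @return The records with columns `coded` and `detail` added.
#' @export
code_responses <- function(records, wordform_tags = NULL) {
  coded <- rep(NA_character_, nrow(records))
  detail <- rep(NA_character_, nrow(records))
  is_cat <- records$response_type == "category"
  coded[is_cat] <- records$response[is_cat]
  is_other <- records$response_type == "other"
  coded[is_other] <- "other"
  detail[is_other] <- "other"
  is_wf <- records$response_type == "wordform"
  if (any(is_wf)) {
    if (is.null(wordform_tags)) {
      stop("`wordform_tags` needed to code wordform responses",
           call. = FALSE)
    }
    tag <- unname(wordform_tags[records$response[is_wf]])
    lab <- ifelse(is.na(tag), "UNKNOWN",
                  ifelse(tag == "NOUN", "item-N",
                         ifelse(tag == "VERB", "item-V", tag)))
    n_unknown <- sum(is.na(tag))
    if (n_unknown > 0) {
      message(n_unknown, " wordform response(s) absent from the tag map")
    }
    coded[is_wf] <- "other"
    detail[is_wf] <- lab
  }
  records$coded <- coded
  records$detail <- detail
  records
}

#' Score prediction records into hits, misses and false alarms
#'
#' Per record, with gold category G (N for gold NOUN targets, V for gold
#' VERB targets, other otherwise) and coded response C:
#' * G = N and C = N: a noun hit (symmetrically for V);
#' * G = N and C != N: a noun miss, recorded with the detail of what was
#'   answered instead (a wordform reply causes *only* a miss);
#' * C = N and G != N: a noun false alarm -- so a cross-category answer
#'   ("N" on a gold verb) books one miss (for V) *and* one false alarm
#'   (for N).
#'
#' Abstentions are excluded from scoring by default (misses are wrong
#' *replies*); set `abstain_as_miss = TRUE` for the sensitivity-analysis
#' variant in which an abstention on a gold N/V target counts as a miss.
#'
#' @param records Prediction records; coded on the fly when `coded` is
#'   absent.
#' @param wordform_tags Passed to [code_responses()] when needed.
#' @param abstain_as_miss Score abstentions on gold noun/verb targets as
#'   misses.
#' @return An object of class `score_counts` with per-category hits, misses
#'   (with a detail breakdown) and false alarms.
#' @export
score_records <- function(records, wordform_tags = NULL,
                          abstain_as_miss = FALSE) {
  if (!"coded" %in% names(records)) {
    records <- code_responses(records, wordform_tags)
  }
  is_abst <- records$response_type == "abstain"
  if (abstain_as_miss) {
    records$coded[is_abst] <- "other"
    records$detail[is_abst] <- "abstain"
  } else {
    records <- records[!is_abst, ]
  }
  gold <- ifelse(records$pos == "NOUN", "N",
                 ifelse(records$pos == "VERB", "V", "other"))
  counts_for <- function(cat) {
    hit <- sum(gold == cat & records$coded == cat)
    miss <- sum(gold == cat & records$coded != cat)
    fa <- sum(records$coded == cat & gold != cat)
    c(hit = hit, miss = miss, fa = fa)
  }
  n_counts <- counts_for("N")
  v_counts <- counts_for("V")
  is_miss <- gold %in% c("N", "V") & records$coded != gold
  miss_detail <- tibble(
    category = gold[is_miss],
    # a cross-category reply's detail is the category answered instead
    detail = ifelse(records$coded[is_miss] %in% c("N", "V"),
                    records$coded[is_miss], records$detail[is_miss])) |>
    count(.data$category, .data$detail, name = "n")
  structure(list(
    hits = c(N = unname(n_counts["hit"]), V = unname(v_counts["hit"])),
    misses = c(N = unname(n_counts["miss"]), V = unname(v_counts["miss"])),
    fas = c(N = unname(n_counts["fa"]), V = unname(v_counts["fa"])),
    miss_detail = miss_detail,
    n_scored = nrow(records),
    n_gold = c(N = sum(gold == "N"), V = sum(gold == "V"),
               other = sum(gold == "other"))
  ), class = "score_counts")
}

#' @export
print.score_counts <- function(x, ...) {
  cat("<score_counts>\n")
  for (cat_ in c("N", "V")) {
    cat(sprintf("  %s: hits %d, misses %d, FAs %d (precision %s, recall %s)\n",
                cat_, x$hits[[cat_]], x$misses[[cat_]], x$fas[[cat_]],
                format(round(precision(x, cat_), 3)),
                format(round(recall(x, cat_), 3))))
  }
  invisible(x)
}

#' Precision and recall per category
#'
#' `precision = hit / (hit + FA)`; `recall = hit / (hit + miss)`. When the
#' denominator is zero the measure is undefined and `NA` is returned.
#'
#' @param scores A [score_records()] result.
#' @param category `"N"` or `"V"`.
#' @return A single ratio in `[0, 1]`, or `NA`.
#' @export
precision <- function(scores, category = c("N", "V")) {
  category <- match.arg(category)
  denom <- scores$hits[[category]] + scores$fas[[category]]
  if (denom == 0) NA_real_ else scores$hits[[category]] / denom
}

#' @rdname precision
#' @export
recall <- function(scores, category = c("N", "V")) {
  category <- match.arg(category)
  denom <- scores$hits[[category]] + scores$misses[[category]]
  if (denom == 0) NA_real_ else scores$hits[[category]] / denom
}

#' Most frequently used contexts
#'
#' Tallies, per context actually used by the model, how often it was used,
#' how many of its targets were gold nouns and gold verbs, the model's
#' modal answer in that context, and how many uses produced that modal
#' answer (both tallies are emitted since either reading of "number of
#' uses" may be wanted). Rows are sorted by the gold-category tally of the
#' requested category, descending.
#'
#' @param records Prediction records carrying `context_used`.
#' @param category Sort/report for noun (`"N"`) or verb (`"V"`) targets.
#' @param top_k Number of rows to keep.
#' @return A tibble with columns `context`, `n_uses`, `n_target_N`,
#'   `n_target_V`, `answer`, `n_uses_modal`.
#' @export
frequent_context_report <- function(records, category = c("N", "V"),
                                    top_k = 20) {
  category <- match.arg(category)
  rec <- records[!is.na(records$context_used), ]
  if (nrow(rec) == 0) {
    return(tibble(context = character(0), n_uses = integer(0),
                  n_target_N = integer(0), n_target_V = integer(0),
                  answer = character(0), n_uses_modal = integer(0)))
  }
  rep_ <- rec |>
    group_by(context = .data$context_used) |>
    summarise(
      n_uses = n(),
      n_target_N = sum(.data$pos == "NOUN"),
      n_target_V = sum(.data$pos == "VERB"),
      answer = names(sort(table(.data$response), decreasing = TRUE))[1],
      n_uses_modal = max(table(.data$response)),
      .groups = "drop")
  key <- if (category == "N") rep_$n_target_N else rep_$n_target_V
  rep_ <- rep_[order(-key, -rep_$n_uses, rep_$context), ]
  head(rep_, top_k)
}

#' Breakdown of misses by response detail
#'
#' The normalized distribution, per category, of what the model answered
#' when it missed: the other category symbol, a specific noun or verb item
#' (`item-N`/`item-V`), or another tag class (`ADJ`, `ADV`, ...).
#'
#' @param scores A [score_records()] result.
#' @return A tibble with columns `category`, `detail`, `n`, `fraction`
#'   (fractions sum to 1 within each category); empty when there are no
#'   misses.
#' @export
miss_breakdown <- function(scores) {
  md <- scores$miss_detail
  if (nrow(md) == 0) {
    return(tibble(category = character(0), detail = character(0),
                  n = integer(0), fraction = numeric(0)))
  }
  md |>
    group_by(.data$category) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$category, desc(.data$n), .data$detail)
}
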