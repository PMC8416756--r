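#' Construct a tagged corpus
#'
#' A `tagged_corpus` is an ordered sequence of utterances, each an ordered
#' sequence of tokens carrying a surface form (lowercased; apostrophe-final
#' clitics such as `"l'"` are separate tokens), a gold part-of-speech tag
#' from the closed tag set, and an optional lemma. Utterance ids are
#' renumbered to consecutive integers in order of first appearance, so
#' iteration order is stable and empty utterances cannot exist.
#'
#' @param tokens A data frame with columns `utterance_id`, `form`, `pos` and
#'   optionally `lemma`.
#' @param source_id A label identifying where the corpus came from.
#' @return An object of class `tagged_corpus`.
#' @examples
#' corp <- tagged_corpus(tibble::tibble(
#'   utterance_id = c(1, 1, 2),
#'   form = c("le", "chat", "regarde"),
#'   pos = c("DET", "NOUN", "VERB")))
#' n_tokens(corp)
#' @export
tagged_corpus <- function(tokens, source_id = "corpus") {
  tokens <- as_tibble(tokens)
  need <- c("utterance_id", "form", "pos")
  if (!all(need %in% names(tokens))) {
    stop("`tokens` must have columns utterance_id, form and pos",
         call. = FALSE)
  }
  if (!"lemma" %in% names(tokens)) tokens$lemma <- NA_character_
  tokens <- tokens[, c("utterance_id", "form", "pos", "lemma")]
  tokens$form <- as.character(tokens$form)
  tokens$pos <- as.character(tokens$pos)
  tokens$lemma <- as.character(tokens$lemma)
  if (nrow(tokens) > 0) {
    if (any(!nzchar(tokens$form)) || anyNA(tokens$form)) {
      stop("token forms must be non-empty", call. = FALSE)
    }
    if (any(tokens$form %in% c(BOUNDARY_OPEN, BOUNDARY_CLOSE))) {
      stop("token forms may not equal the reserved boundary symbols { }",
           call. = FALSE)
    }
    bad <- setdiff(unique(tokens$pos), TAG_SET)
    if (length(bad)) {
      stop("unknown POS tag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    tokens$utterance_id <-
      match(tokens$utterance_id, unique(tokens$utterance_id))
  } else {
    tokens$utterance_id <- integer(0)
  }
  structure(list(tokens = tokens, source_id = as.character(source_id)),
            class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  cat(sprintf("<tagged_corpus '%s': %d utterances, %d tokens>\n",
              x$source_id, n_utterances(x), n_tokens(x)))
  invisible(x)
}

#' Corpus accessors
#'
#' @param corpus A [tagged_corpus()].
#' @return `corpus_tokens()` returns the token table (one row per token, in
#'   corpus order); `n_tokens()` and `n_utterances()` return counts.
#' @export
corpus_tokens <- function(corpus) corpus$tokens

#' @rdname corpus_tokens
#' @export
n_tokens <- function(corpus) nrow(corpus$tokens)

#' @rdname corpus_tokens
#' @export
n_utterances <- function(corpus) {
  if (nrow(corpus$tokens) == 0) 0L else max(corpus$tokens$utterance_id)
}

#' Read a POS-tagged utterance corpus
#'
#' Two dialects are supported. The TSV dialect has one token per line with
#' tab-separated columns `form`, `pos` and optional `lemma`; a blank line or
#' a line containing only `###` terminates an utterance. Strong punctuation
#' tokens (`. ! ? , ; :`) also terminate the current utterance and are never
#' kept as tokens; other purely-punctuation tokens are dropped. Forms are
#' lowercased; tags outside the closed tag set are mapped to `OTHER` with a
#' warning. The CHAT dialect reads speaker main tiers plus the `%mor` tier
#' when present; conversion is best-effort and logged via messages.
#'
#' @param path Path to the corpus file (UTF-8).
#' @param dialect `"tsv"` or `"chat"`.
#' @param speakers For CHAT input, speaker codes to keep (e.g. `"MOT"`);
#'   `NULL` keeps every speaker except `CHI`.
#' @param source_id Label stored on the corpus; defaults to the file name.
#' @return A [tagged_corpus()].
#' @export
read_tagged_corpus <- function(path, dialect = c("tsv", "chat"),
                               speakers = NULL,
                               source_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (dialect == "tsv") {
    parse_tsv_corpus(lines, source_id)
  } else {
    parse_chat_corpus(lines, speakers, source_id)
  }
}

parse_tsv_corpus <- function(lines, source_id) {
  if (length(lines) == 0) {
    return(tagged_corpus(tibble(utterance_id = integer(0),
                                form = character(0), pos = character(0),
                                lemma = character(0)), source_id))
  }
  stripped <- trimws(lines)
  is_term_line <- stripped == "" | stripped == "###"
  utt_of_line <- cumsum(is_term_line) + 1L  # id before the terminator applies
  tok_idx <- which(!is_term_line)
  if (length(tok_idx) == 0) {
    return(tagged_corpus(tibble(utterance_id = integer(0),
                                form = character(0), pos = character(0),
                                lemma = character(0)), source_id))
  }
  parts <- strsplit(lines[tok_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad)) {
    stop(sprintf(
      "malformed line %d: expected 2 or 3 tab-separated fields, got %d",
      tok_idx[bad[1]], nf[bad[1]]), call. = FALSE)
  }
  form <- tolower(trimws(vapply(parts, `[`, "", 1L)))
  pos <- toupper(trimws(vapply(parts, `[`, "", 2L)))
  lemma <- tolower(trimws(vapply(parts, function(p) {
    if (length(p) >= 3) p[3] else NA_character_
  }, NA_character_)))
  lemma[!is.na(lemma) & !nzchar(lemma)] <- NA_character_

  # strong punctuation acts as an extra utterance break; other pure
  # punctuation is silently dropped
  is_strong <- form %in% TERMINATOR_FORMS
  is_punct <- grepl("^[^[:alnum:]]+$", form) & !grepl("'", form, fixed = TRUE)
  utt_line <- utt_of_line[tok_idx]
  new_utt <- c(TRUE, utt_line[-1] != utt_line[-length(utt_line)]) |
    c(FALSE, is_strong[-length(is_strong)])
  utt_id <- cumsum(new_utt)
  keep <- !is_strong & !is_punct
  form <- form[keep]; pos <- pos[keep]; lemma <- lemma[keep]
  utt_id <- utt_id[keep]

  unknown <- setdiff(unique(pos), TAG_SET)
  if (length(unknown)) {
    warning("unknown tag(s) mapped to OTHER: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    pos[pos %in% unknown] <- "OTHER"
  }
  tagged_corpus(tibble(utterance_id = utt_id, form = form, pos = pos,
                       lemma = lemma), source_id)
}

# map a %mor tier POS code to the closed tag set
map_chat_pos <- function(p) {
  base <- sub("[:].*$", "", tolower(p))
  out <- rep("OTHER", length(base))
  out[base %in% c("n", "n:prop", "on")] <- "NOUN"
  out[base %in% c("v", "aux", "mod", "cop", "part", "inf")] <- "VERB"
  out[base == "adj"] <- "ADJ"
  out[base == "adv"] <- "ADV"
  out[base %in% c("det", "art", "qn")] <- "DET"
  out[base == "pro"] <- "PRON"
  out[base == "prep"] <- "PREP"
  out[base %in% c("conj", "coord", "comp")] <- "CONJ"
  out[base == "neg"] <- "NEG"
  out
}

parse_chat_corpus <- function(lines, speakers, source_id) {
  # join tab-indented continuation lines onto their tier line
  cont <- grepl("^\t", lines)
  if (any(cont)) {
    joined <- character(0)
    for (ln in lines) {
      if (grepl("^\t", ln) && length(joined)) {
        joined[length(joined)] <- paste(joined[length(joined)], trimws(ln))
      } else {
        joined <- c(joined, ln)
      }
    }
    lines <- joined
  }
  is_main <- grepl("^\\*[A-Z]{2,3}:", lines)
  is_mor <- grepl("^%mor:", lines)
  recs <- list()
  cur <- NULL
  for (ln in seq_along(lines)) {
    if (is_main[ln]) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      spk <- sub("^\\*([A-Z]{2,3}):.*$", "\\1", lines[ln])
      cur <- list(speaker = spk,
                  main = trimws(sub("^\\*[A-Z]{2,3}:", "", lines[ln])),
                  mor = NULL)
    } else if (is_mor[ln] && !is.null(cur)) {
      cur$mor <- trimws(sub("^%mor:", "", lines[ln]))
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur

  keep_spk <- function(s) {
    if (is.null(speakers)) s != "CHI" else s %in% speakers
  }
  rows <- list()
  utt <- 0L
  n_misaligned <- 0L
  for (r in recs) {
    if (!keep_spk(r$speaker)) next
    if (is.null(r$mor)) next  # no category tier: nothing to evaluate against
    mor_tok <- strsplit(r$mor, "[[:space:]]+")[[1]]
    mor_tok <- mor_tok[nzchar(mor_tok)]
    is_punct <- !grepl("|", mor_tok, fixed = TRUE)
    # surface forms from the main tier, when alignment is clean
    main_tok <- strsplit(r$main, "[[:space:]]+")[[1]]
    main_tok <- main_tok[nzchar(main_tok)]
    main_tok <- main_tok[!grepl("^[\\[&+(0]", main_tok)]
    main_tok <- main_tok[!grepl("^[^[:alnum:]]+$", main_tok) |
                           grepl("'", main_tok, fixed = TRUE)]
    words <- mor_tok[!is_punct]
    pos_code <- sub("\\|.*$", "", words)
    lemma <- sub("^[^|]*\\|", "", words)
    lemma <- tolower(sub("[&~#-].*$", "", lemma))
    if (length(main_tok) == length(words)) {
      form <- tolower(main_tok)
    } else {
      form <- lemma
      n_misaligned <- n_misaligned + 1L
    }
    # strong punctuation inside the mor tier splits the utterance
    seg <- cumsum(c(TRUE, (mor_tok %in% TERMINATOR_FORMS)[-length(mor_tok)]))
    seg <- seg[!is_punct]
    for (s in unique(seg)) {
      sel <- seg == s & nzchar(form)
      if (!any(sel)) next
      utt <- utt + 1L
      rows[[length(rows) + 1L]] <- tibble(
        utterance_id = utt, form = form[sel],
        pos = map_chat_pos(pos_code[sel]), lemma = lemma[sel])
    }
  }
  if (n_misaligned > 0) {
    message(n_misaligned,
            " utterance(s) had main/%mor misalignment; lemmas used as forms")
  }
  tok <- if (length(rows)) bind_rows(rows) else {
    tibble(utterance_id = integer(0), form = character(0),
           pos = character(0), lemma = character(0))
  }
  tagged_corpus(tok, source_id)
}

#' Write a tagged corpus in the TSV dialect
#'
#' One token per line (`form<TAB>pos[<TAB>lemma]`), with `###` terminating
#' each utterance. Reading the file back with [read_tagged_corpus()] yields
#' an identical corpus.
#'
#' @param corpus A [tagged_corpus()].
#' @param path Output file path.
#' @export
write_tagged_corpus <- function(corpus, path) {
  tok <- corpus$tokens
  out <- character(0)
  if (nrow(tok) > 0) {
    line <- ifelse(is.na(tok$lemma),
                   paste(tok$form, tok$pos, sep = "\t"),
                   paste(tok$form, tok$pos, tok$lemma, sep = "\t"))
    pieces <- split(line, tok$utterance_id)
    out <- unlist(lapply(pieces, function(p) c(p, "###")), use.names = FALSE)
  }
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}

#' Read a tag-correction list
#'
#' A two-column TSV mapping a lexeme to its replacement POS tag, as used for
#' the manual noun-tag audit of a tagged corpus.
#'
#' @param path Path to a two-column TSV (`lexeme<TAB>pos`).
#' @return A tibble with columns `lexeme` and `pos`.
#' @export
read_tag_corrections <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop("malformed correction line ", bad[1], ": expected 2 fields",
         call. = FALSE)
  }
  tibble(lexeme = tolower(trimws(vapply(parts, `[`, "", 1L))),
         pos = toupper(trimws(vapply(parts, `[`, "", 2L))))
}

#' Apply tag corrections to a corpus
#'
#' Every token whose lexeme (lemma when present, else surface form) matches
#' an entry has its POS tag replaced. The number of tokens whose tag actually
#' changed is recorded on the result (see [n_retagged()]); applying the same
#' corrections twice therefore retags 0 tokens the second time.
#'
#' @param corpus A [tagged_corpus()].
#' @param corrections A data frame with columns `lexeme` and `pos` (see
#'   [read_tag_corrections()]), or a named character vector
#'   (`c(pour = "PREP")`).
#' @return The corrected corpus, with attribute `n_retagged`.
#' @export
apply_tag_corrections <- function(corpus, corrections) {
  if (is.character(corrections)) {
    corrections <- tibble(lexeme = names(corrections),
                          pos = unname(corrections))
  }
  corrections <- as_tibble(corrections)
  if (nrow(corrections) > 0) {
    if (anyDuplicated(corrections$lexeme)) {
      stop("duplicate lexeme in correction list", call. = FALSE)
    }
    bad <- setdiff(unique(corrections$pos), TAG_SET)
    if (length(bad)) {
      stop("unknown replacement tag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  tok <- corpus$tokens
  lex <- ifelse(is.na(tok$lemma), tok$form, tok$lemma)
  idx <- match(lex, corrections$lexeme)
  new_pos <- tok$pos
  hit <- !is.na(idx)
  new_pos[hit] <- corrections$pos[idx[hit]]
  changed <- sum(new_pos != tok$pos)
  unmatched <- setdiff(corrections$lexeme, lex)
  if (length(unmatched)) {
    message(length(unmatched), " correction lexeme(s) not found in corpus")
  }
  tok$pos <- new_pos
  out <- tagged_corpus(tok, corpus$source_id)
  attr(out, "n_retagged") <- changed
  out
}

#' @rdname apply_tag_corrections
#' @param corpus A corpus returned by `apply_tag_corrections()`.
#' @export
n_retagged <- function(corpus) {
  n <- attr(corpus, "n_retagged")
  if (is.null(n)) 0L else n
}

#' Keep only the given utterances of a corpus
#'
#' @param corpus A [tagged_corpus()].
#' @param utterance_ids Integer utterance ids to keep; tokens are returned in
#'   corpus order.
#' @return A [tagged_corpus()] (ids renumbered consecutively).
#' @export
subset_utterances <- function(corpus, utterance_ids) {
  tok <- corpus$tokens[corpus$tokens$utterance_id %in% utterance_ids, ]
  tagged_corpus(tok, corpus$source_id)
}

#' Split a corpus into cross-validation folds
#'
#' The corpus is cut into `k` contiguous utterance blocks in original order
#' (mini-corpora); within each block the first
#' `ceiling(train_fraction * block_size)` utterances form the training part
#' and the rest the test part. The split is deterministic; an optional
#' seeded shuffle of utterance order is available.
#'
#' @param corpus A [tagged_corpus()].
#' @param k Number of folds (`>= 1`; at most the number of utterances).
#' @param train_fraction Fraction of each mini-corpus used for training.
#' @param shuffle Shuffle utterance order before cutting blocks.
#' @param seed RNG seed for the shuffle (required when `shuffle = TRUE`).
#' @return A list of folds; each fold is a list with elements `fold_id`,
#'   `train` and `test` (both [tagged_corpus()] objects).
#' @export
split_folds <- function(corpus, k, train_fraction = 2 / 3,
                        shuffle = FALSE, seed = NULL) {
  n <- n_utterances(corpus)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (n < k) stop("corpus has fewer utterances than folds", call. = FALSE)
  ord <- seq_len(n)
  if (shuffle) {
    if (is.null(seed)) stop("`seed` required when shuffle = TRUE",
                            call. = FALSE)
    ord <- withr::with_seed(seed, sample.int(n))
  }
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  lapply(seq_len(k), function(f) {
    block <- ord[starts[f]:ends[f]]
    n_train <- ceiling(train_fraction * length(block))
    if (n_train >= length(block)) {
      warning(sprintf("fold %d has an empty test set", f), call. = FALSE)
    }
    list(fold_id = f,
         train = subset_utterances(corpus, block[seq_len(n_train)]),
         test = subset_utterances(
           corpus,
           if (n_train < length(block)) {
             block[(n_train + 1L):length(block)]
           } else integer(0)))
  })
}
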