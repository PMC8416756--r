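#' Construct a seed lexicon
#'
#' A semantic seed: the small set of lexemes a learner is assumed to already
#' know, grouped into object-referring words (the noun seed) and
#' action-referring words (the verb seed). The two sets must be disjoint.
#'
#' @param id Label for the seed (e.g. `"V0"`).
#' @param noun_lexemes,verb_lexemes Character vectors of lexemes.
#' @return An object of class `seed_lexicon`.
#' @export
seed_lexicon <- function(id, noun_lexemes, verb_lexemes) {
  noun_lexemes <- unique(tolower(as.character(noun_lexemes)))
  verb_lexemes <- unique(tolower(as.character(verb_lexemes)))
  both <- intersect(noun_lexemes, verb_lexemes)
  if (length(both)) {
    stop("lexeme(s) in both noun and verb seed: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(id = as.character(id), noun_lexemes = noun_lexemes,
                 verb_lexemes = verb_lexemes),
            class = "seed_lexicon")
}

#' @export
print.seed_lexicon <- function(x, ...) {
  cat(sprintf("<seed_lexicon '%s': %d noun, %d verb lexemes>\n",
              x$id, length(x$noun_lexemes), length(x$verb_lexemes)))
  invisible(x)
}

#' Names of the shipped seed presets
#'
#' The nested presets V0 (8 nouns, 1 verb) through V4 (128 nouns, 12 verbs),
#' the French seed word lists used in the original Lyon-corpus study.
#'
#' @return Character vector of preset names.
#' @export
seed_presets <- function() c("V0", "V1", "V2", "V3", "V4")

#' Load a seed lexicon from a preset or file
#'
#' Seed files are plain text with two sections introduced by `[nouns]` and
#' `[verbs]` headers, one lexeme per line; blank lines and `#` comments are
#' ignored. The shipped presets (see [seed_presets()]) are nested:
#' V0 \eqn{\subset} V1 \eqn{\subset} ... \eqn{\subset} V4.
#'
#' @param spec A preset name (`"V0"` .. `"V4"`) or a path to a seed file.
#' @param id Seed label; defaults to the preset name or file name.
#' @return A [seed_lexicon()].
#' @examples
#' load_seed("V0")
#' @export
load_seed <- function(spec, id = NULL) {
  if (spec %in% seed_presets()) {
    path <- system.file("extdata", "seeds", paste0(spec, ".txt"),
                        package = "semseed", mustWork = TRUE)
    if (is.null(id)) id <- spec
  } else {
    path <- spec
    if (!file.exists(path)) {
      stop("unknown preset or missing file: ", spec, call. = FALSE)
    }
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- cumsum(lines %in% c("[nouns]", "[verbs]"))
  labels <- character(length(lines))
  cur <- NA_character_
  for (i in seq_along(lines)) {
    if (lines[i] == "[nouns]") cur <- "n"
    else if (lines[i] == "[verbs]") cur <- "v"
    labels[i] <- cur
  }
  body <- !(lines %in% c("[nouns]", "[verbs]"))
  if (any(body & is.na(labels))) {
    stop("seed file has lexemes before any [nouns]/[verbs] header",
         call. = FALSE)
  }
  seed_lexicon(id,
               lines[body & labels == "n" & !is.na(labels)],
               lines[body & labels == "v" & !is.na(labels)])
}

#' Build a seed from corpus frequencies
#'
#' Picks the `n_nouns` most frequent NOUN-tagged lexemes and the `n_verbs`
#' most frequent VERB-tagged lexemes (lemma when present, else surface
#' form), optionally restricted to an allowlist standing in for the
#' concreteness judgment a human would make. Frequency ties are broken
#' lexicographically.
#'
#' @param corpus A [tagged_corpus()].
#' @param n_nouns,n_verbs Number of lexemes to pick (use `Inf` for all, the
#'   maximal-projection seed).
#' @param allowlist Optional character vector of admissible lexemes.
#' @param id Seed label.
#' @return A [seed_lexicon()].
#' @export
build_frequency_seed <- function(corpus, n_nouns, n_verbs, allowlist = NULL,
                                 id = NULL) {
  tok <- corpus$tokens
  lex <- ifelse(is.na(tok$lemma), tok$form, tok$lemma)
  top_of <- function(tag, n_want) {
    sel <- tok$pos == tag
    if (!any(sel) || n_want == 0) return(character(0))
    cnt <- sort(table(lex[sel]), decreasing = TRUE)
    cand <- tibble(lexeme = names(cnt), n = as.integer(cnt))
    if (!is.null(allowlist)) cand <- cand[cand$lexeme %in% allowlist, ]
    cand <- cand[order(-cand$n, cand$lexeme), ]
    if (is.finite(n_want) && nrow(cand) < n_want) {
      warning(sprintf("only %d distinct %s lexeme(s) available (%d requested)",
                      nrow(cand), tag, n_want), call. = FALSE)
    }
    head(cand$lexeme, n_want)
  }
  if (is.null(id)) {
    id <- sprintf("freq_%sn_%sv", format(n_nouns), format(n_verbs))
  }
  seed_lexicon(id, top_of("NOUN", n_nouns), top_of("VERB", n_verbs))
}

#' Project a semantic seed over a corpus
#'
#' Adds an incomplete category tier on top of the token tier: a token is
#' marked `N` when its lexeme belongs to the noun seed (and, by default, its
#' gold tag is NOUN), `V` analogously, and is left unmarked otherwise.
#' Matching uses the lemma when available, so inflected forms of a seed verb
#' project; requiring the gold tag means noun/verb homographs are projected
#' only in their seed sense.
#'
#' @param corpus A [tagged_corpus()].
#' @param seed A [seed_lexicon()].
#' @param use_lemma Match on lemma when present (else surface form).
#' @param require_gold_tag Only project tokens whose gold tag matches the
#'   seed category.
#' @return A `projected_corpus`: the corpus with an additional `tier` column
#'   (`"N"`, `"V"` or `NA`) and the seed id attached.
#' @export
project_seed <- function(corpus, seed, use_lemma = TRUE,
                         require_gold_tag = TRUE) {
  tok <- corpus$tokens
  lex <- if (use_lemma) ifelse(is.na(tok$lemma), tok$form, tok$lemma) else
    tok$form
  is_n <- lex %in% seed$noun_lexemes
  is_v <- lex %in% seed$verb_lexemes
  if (require_gold_tag) {
    is_n <- is_n & tok$pos == "NOUN"
    is_v <- is_v & tok$pos == "VERB"
  }
  tier <- rep(NA_character_, nrow(tok))
  tier[is_n] <- "N"
  tier[is_v] <- "V"
  tok$tier <- tier
  structure(list(tokens = tok, source_id = corpus$source_id,
                 seed_id = seed$id),
            class = c("projected_corpus", "tagged_corpus"))
}

#' @export
print.projected_corpus <- function(x, ...) {
  cat(sprintf(
    "<projected_corpus '%s' (seed '%s'): %d utterances, %d tokens, %d projected>\n",
    x$source_id, x$seed_id, n_utterances(x), n_tokens(x),
    sum(!is.na(x$tokens$tier))))
  invisible(x)
}

#' Projection coverage per category
#'
#' The fraction of gold NOUN tokens projected as `N`, and of gold VERB
#' tokens projected as `V`. When a category has no gold tokens its coverage
#' is undefined and reported as `NA`.
#'
#' @param projected A corpus returned by [project_seed()].
#' @return A tibble with columns `category`, `n_gold`, `n_projected` and
#'   `coverage`.
#' @export
projection_coverage <- function(projected) {
  tok <- projected$tokens
  row_for <- function(cat, tag) {
    n_gold <- sum(tok$pos == tag)
    n_proj <- sum(!is.na(tok$tier) & tok$tier == cat)
    tibble(category = cat, n_gold = n_gold, n_projected = n_proj,
           coverage = if (n_gold > 0) n_proj / n_gold else NA_real_)
  }
  bind_rows(row_for("N", "NOUN"), row_for("V", "VERB"))
}
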