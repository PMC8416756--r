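#' Specify a synthetic child-directed-speech grammar
#'
#' The generator emulates the statistical skeleton of French maternal
#' speech as the categorization model sees it: short utterances drawn from
#' weighted category templates, a small closed inventory of high-frequency
#' function words, Zipf-distributed content lexicons, noun/verb homographs
#' (one surface form serving both categories, with distinct lexeme
#' entries), and a noise process that makes contexts imperfect predictors
#' of category. With probability `noise_rate`, a content slot is filled by
#' a word of the *other* content category and the gold tag records that
#' word's true category -- so the surrounding context genuinely misleads a
#' context-based categorizer (like French "tu as faim", where a noun
#' follows a pronoun+verb frame).
#'
#' The default templates are head-initial (determiners before nouns,
#' pronouns before verbs), mirroring the right-branching structure of
#' French; weights must sum to 1.
#'
#' @param templates List of `list(slots = c(...), weight = w)` rules; slot
#'   categories are `"N"`, `"V"` or a function-word class named in
#'   `function_words`.
#' @param n_nouns,n_verbs Content lexicon sizes.
#' @param zipf_exponent Exponent of the rank-frequency law used to sample
#'   content lexemes (P(rank r) proportional to r^-s).
#' @param homograph_rate Fraction of content lexemes whose surface form
#'   serves both NOUN and VERB.
#' @param noise_rate Probability that a content slot is filled by a word of
#'   the wrong category (see above).
#' @param function_words Named list of closed-class inventories; names must
#'   be tags from the closed tag set (DET, PRON, ADV, PREP, ...).
#' @return An object of class `synth_grammar`.
#' @export
synth_grammar <- function(
    templates = list(
      list(slots = c("DET", "N"), weight = 0.22),
      list(slots = c("PRON", "V"), weight = 0.18),
      list(slots = c("PRON", "V", "DET", "N"), weight = 0.25),
      list(slots = c("PRON", "V", "ADV"), weight = 0.10),
      list(slots = c("PREP", "DET", "N"), weight = 0.10),
      list(slots = c("DET", "N", "V"), weight = 0.08),
      list(slots = c("PRON", "V", "PREP", "DET", "N"), weight = 0.07)),
    n_nouns = 200, n_verbs = 120, zipf_exponent = 1.2,
    homograph_rate = 0.05, noise_rate = 0.05,
    function_words = list(
      DET = c("le", "la", "les", "un", "une", "des"),
      PRON = c("tu", "il", "elle", "on", "je", "moi"),
      ADV = c("bien", "encore", "aussi", "pas"),
      PREP = c("dans", "sur", "avec", "sous"))) {
  w <- vapply(templates, function(t) t$weight, numeric(1))
  if (any(w <= 0)) stop("invalid `templates`: weights must be positive",
                        call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8) {
    stop("invalid `templates`: weights must sum to 1", call. = FALSE)
  }
  if (n_nouns < 1) stop("invalid `n_nouns`: must be >= 1", call. = FALSE)
  if (n_verbs < 1) stop("invalid `n_verbs`: must be >= 1", call. = FALSE)
  if (zipf_exponent <= 0) {
    stop("invalid `zipf_exponent`: must be positive", call. = FALSE)
  }
  for (fld in c("homograph_rate", "noise_rate")) {
    v <- get(fld)
    if (v < 0 || v > 1) {
      stop(sprintf("invalid `%s`: must be in [0, 1]", fld), call. = FALSE)
    }
  }
  bad_fw <- setdiff(names(function_words), TAG_SET)
  if (length(bad_fw)) {
    stop("invalid `function_words`: unknown class ",
         paste(bad_fw, collapse = ", "), call. = FALSE)
  }
  cats <- unique(unlist(lapply(templates, `[[`, "slots")))
  bad_slot <- setdiff(cats, c("N", "V", names(function_words)))
  if (length(bad_slot)) {
    stop("invalid `templates`: slot class without inventory: ",
         paste(bad_slot, collapse = ", "), call. = FALSE)
  }
  structure(list(templates = templates, n_nouns = n_nouns,
                 n_verbs = n_verbs, zipf_exponent = zipf_exponent,
                 homograph_rate = homograph_rate, noise_rate = noise_rate,
                 function_words = function_words),
            class = "synth_grammar")
}

#' @export
print.synth_grammar <- function(x, ...) {
  cat(sprintf(
    "<synth_grammar: %d templates, %d nouns, %d verbs, zipf %.2f, homograph %.2f, noise %.2f>\n",
    length(x$templates), x$n_nouns, x$n_verbs, x$zipf_exponent,
    x$homograph_rate, x$noise_rate))
  invisible(x)
}

#' Generate a synthetic gold-tagged corpus
#'
#' Draws templates by weight, fills content slots with Zipf-distributed
#' lexemes (ranks shared between homograph pairs at the surface level,
#' distinguished by lemma), applies the wrong-category noise process, and
#' tags every token with the gold category of the word that actually fills
#' the slot. Deterministic for a given grammar and seed.
#'
#' @param grammar A [synth_grammar()].
#' @param n_utterances Number of utterances to generate.
#' @param rng_seed Integer seed.
#' @return A [tagged_corpus()].
#' @examples
#' corp <- generate_corpus(synth_grammar(), 50, rng_seed = 1)
#' n_utterances(corp)
#' @export
generate_corpus <- function(grammar, n_utterances, rng_seed) {
  stopifnot(inherits(grammar, "synth_grammar"))
  src <- sprintf("synth_seed%d", rng_seed)
  if (n_utterances == 0) {
    return(tagged_corpus(tibble(utterance_id = integer(0),
                                form = character(0), pos = character(0),
                                lemma = character(0)), src))
  }
  withr::with_seed(rng_seed, {
    slots_list <- lapply(grammar$templates, `[[`, "slots")
    w <- vapply(grammar$templates, `[[`, numeric(1), "weight")
    idx <- sample.int(length(slots_list), n_utterances, replace = TRUE,
                      prob = w)
    slot_cat <- unlist(slots_list[idx], use.names = FALSE)
    utt_id <- rep(seq_len(n_utterances), lengths(slots_list)[idx])

    # surface lexicons; homograph pairs share a surface but keep distinct
    # lexeme (lemma) identities
    noun_forms <- sprintf("nw%03d", seq_len(grammar$n_nouns))
    verb_forms <- sprintf("vw%03d", seq_len(grammar$n_verbs))
    n_h <- round(grammar$homograph_rate *
                   min(grammar$n_nouns, grammar$n_verbs))
    if (n_h > 0) {
      hn <- sample.int(grammar$n_nouns, n_h)
      hv <- sample.int(grammar$n_verbs, n_h)
      verb_forms[hv] <- noun_forms[hn]
    }

    is_content <- slot_cat %in% c("N", "V")
    actual <- slot_cat
    flip <- is_content & runif(length(slot_cat)) < grammar$noise_rate
    actual[flip & slot_cat == "N"] <- "V"
    actual[flip & slot_cat == "V"] <- "N"

    zipf_ranks <- function(n_draw, size, s) {
      if (n_draw == 0) return(integer(0))
      sample.int(size, n_draw, replace = TRUE,
                 prob = seq_len(size)^(-s))
    }
    form <- character(length(slot_cat))
    lemma <- character(length(slot_cat))
    pos <- character(length(slot_cat))
    sel_n <- actual == "N"
    rk <- zipf_ranks(sum(sel_n), grammar$n_nouns, grammar$zipf_exponent)
    form[sel_n] <- noun_forms[rk]
    lemma[sel_n] <- sprintf("nlex%03d", rk)
    pos[sel_n] <- "NOUN"
    sel_v <- actual == "V"
    rk <- zipf_ranks(sum(sel_v), grammar$n_verbs, grammar$zipf_exponent)
    form[sel_v] <- verb_forms[rk]
    lemma[sel_v] <- sprintf("vlex%03d", rk)
    pos[sel_v] <- "VERB"
    for (cls in names(grammar$function_words)) {
      sel <- actual == cls
      if (!any(sel)) next
      inv <- grammar$function_words[[cls]]
      form[sel] <- inv[sample.int(length(inv), sum(sel), replace = TRUE)]
      lemma[sel] <- form[sel]
      pos[sel] <- cls
    }
    tagged_corpus(tibble(utterance_id = utt_id, form = form, pos = pos,
                         lemma = lemma), src)
  })
}

#' Theoretical context fidelity of a grammar
#'
#' From the template weights and the noise rate, computes for each
#' function-word (or utterance-initial boundary) context the probability
#' that the content word occupying the following slot belongs to the
#' majority category for that context -- the ceiling a context-based
#' categorizer can reach -- and aggregates it per content category over the
#' contexts whose majority is that category (weighted by context mass).
#'
#' @param grammar A [synth_grammar()].
#' @return Named numeric vector `c(N = ..., V = ...)`; `NA` for a category
#'   that is the majority of no context.
#' @export
theoretical_fidelity <- function(grammar) {
  stopifnot(inherits(grammar, "synth_grammar"))
  ctx_classes <- c(names(grammar$function_words), BOUNDARY_OPEN)
  mass <- list()
  for (t in grammar$templates) {
    s <- t$slots
    for (j in seq_along(s)) {
      if (!s[j] %in% c("N", "V")) next
      ctx <- if (j == 1) BOUNDARY_OPEN else s[j - 1]
      if (!ctx %in% ctx_classes) next
      key <- ctx
      if (is.null(mass[[key]])) mass[[key]] <- c(N = 0, V = 0)
      mass[[key]][s[j]] <- mass[[key]][s[j]] + t$weight
    }
  }
  if (length(mass) == 0) return(c(N = NA_real_, V = NA_real_))
  nr <- grammar$noise_rate
  rows <- lapply(names(mass), function(ctx) {
    m <- mass[[ctx]]
    tot <- sum(m)
    # noise swaps the actually-filled category
    p_n <- (m[["N"]] * (1 - nr) + m[["V"]] * nr) / tot
    p_v <- 1 - p_n
    maj <- if (p_n >= p_v) "N" else "V"
    tibble(ctx = ctx, mass = tot, majority = maj,
           fidelity = max(p_n, p_v))
  })
  df <- bind_rows(rows)
  out <- c(N = NA_real_, V = NA_real_)
  for (cat_ in c("N", "V")) {
    sel <- df$majority == cat_
    if (any(sel)) {
      out[[cat_]] <- sum(df$fidelity[sel] * df$mass[sel]) /
        sum(df$mass[sel])
    }
  }
  out
}
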