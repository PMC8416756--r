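# Shared fixtures and independent brute-force oracles.

# the two-utterance French example sentence ("mais regarde, le bébé
# éléphant il va manger"), gold-tagged, with lemmas
table2_corpus <- function() {
  tagged_corpus(tibble::tibble(
    utterance_id = c(1, 1, 2, 2, 2, 2, 2, 2),
    form = c("mais", "regarde", "le", "bébé", "éléphant", "il", "va",
             "manger"),
    pos = c("CONJ", "VERB", "DET", "NOUN", "NOUN", "PRON", "VERB", "VERB"),
    lemma = c("mais", "regarder", "le", "bébé", "éléphant", "il", "aller",
              "manger")), source_id = "table2")
}

# small random gold-tagged corpus, independent of the synth module
random_corpus <- function(n_utt, seed, vocab_size = 12) {
  withr::with_seed(seed, {
    forms <- sprintf("w%02d", seq_len(vocab_size))
    pos_pool <- c("NOUN", "VERB", "DET", "PRON", "ADJ", "ADV")
    lens <- sample(1:6, n_utt, replace = TRUE)
    tibble::tibble(
      utterance_id = rep(seq_len(n_utt), lens),
      form = sample(forms, sum(lens), replace = TRUE),
      pos = sample(pos_pool, sum(lens), replace = TRUE))
  }) |> tagged_corpus(source_id = paste0("rand", seed))
}

# ---- brute-force oracle: explicit per-utterance loops over padded tokens ----

oracle_enumerate <- function(projected, scheme) {
  tok <- corpus_tokens(projected)
  if (!"tier" %in% names(tok)) tok$tier <- NA_character_
  rows <- list()
  for (u in unique(tok$utterance_id)) {
    ut <- tok[tok$utterance_id == u, ]
    p <- c("{", "{", ut$form, "}", "}")
    for (i in seq_len(nrow(ut))) {
      j <- i + 2
      key <- switch(scheme,
                    left = c(p[j - 2], p[j - 1]),
                    right = c(p[j + 1], p[j + 2]),
                    framing = c(p[j - 1], p[j + 1]))
      bkey <- switch(scheme, left = p[j - 1], right = p[j + 1],
                     framing = p[j - 1])
      comp <- if (!is.na(ut$tier[i])) ut$tier[i] else ut$form[i]
      rows[[length(rows) + 1L]] <- data.frame(
        utterance_id = u, position = i, key1 = key[1], key2 = key[2],
        backoff = bkey, completer = comp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

oracle_tables <- function(projected, scheme) {
  en <- oracle_enumerate(projected, scheme)
  tri <- aggregate(count ~ key1 + key2 + completer,
                   data = transform(en, count = 1L), FUN = sum)
  bi <- aggregate(count ~ backoff + completer,
                  data = transform(en, count = 1L), FUN = sum)
  list(trigram = tri[order(tri$key1, tri$key2, tri$completer), ],
       bigram = bi[order(bi$backoff, bi$completer), ])
}

# pick the most frequent completer from a named count vector using the
# same published tie-break rule (category symbols first, then alphabetic)
oracle_best <- function(counts_vec) {
  df <- data.frame(completer = names(counts_vec),
                   count = as.integer(counts_vec))
  df$rank <- match(df$completer, c("N", "V"), nomatch = 3L)
  df <- df[order(-df$count, df$rank, df$completer), ]
  df$completer[1]
}

# position-by-position oracle prediction for one site
oracle_predict_site <- function(tri, bi, key1, key2, bkey) {
  sel <- tri$key1 == key1 & tri$key2 == key2
  if (any(sel)) {
    v <- setNames(tri$count[sel], tri$completer[sel])
    return(list(response = oracle_best(v), provenance = "trigram"))
  }
  sel <- bi$backoff == bkey
  if (any(sel)) {
    v <- setNames(bi$count[sel], bi$completer[sel])
    return(list(response = oracle_best(v), provenance = "bigram"))
  }
  list(response = NA_character_, provenance = "none")
}

# normalized view of a trigram table for comparisons
sorted_tri <- function(df) {
  df <- as.data.frame(df)[, c("key1", "key2", "completer", "count")]
  df <- df[order(df$key1, df$key2, df$completer), ]
  rownames(df) <- NULL
  df
}

sorted_bi <- function(df) {
  df <- as.data.frame(df)[, c("backoff", "completer", "count")]
  df <- df[order(df$backoff, df$completer), ]
  rownames(df) <- NULL
  df
}
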