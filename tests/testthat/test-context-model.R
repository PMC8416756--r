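test_that("context keys of the worked example match the published rows", {
  proj <- project_seed(table2_corpus(),
                       seed_lexicon("t2", "bébé", "manger"),
                       use_lemma = FALSE)
  fr <- extract_contexts(proj, "framing")
  expect_equal(fr$context[fr$form == "bébé"], "le _ éléphant")
  lf <- extract_contexts(proj, "left")
  expect_equal(lf$context[lf$form == "le"], "{{ _")
  expect_equal(lf$context[lf$form == "mais"], "{{ _")
  rt <- extract_contexts(proj, "right")
  expect_equal(rt$context[rt$form == "manger"], "_ }}")
})

test_that("a single-token utterance is fully padded under every scheme", {
  corp <- tagged_corpus(tibble::tibble(utterance_id = 1, form = "oui",
                                       pos = "OTHER"))
  expect_equal(extract_contexts(corp, "left")$context, "{{ _")
  expect_equal(extract_contexts(corp, "right")$context, "_ }}")
  expect_equal(extract_contexts(corp, "framing")$context, "{ _ }")
})

test_that("training tables store category completers for seed tokens and surface forms elsewhere", {
  proj <- project_seed(table2_corpus(),
                       seed_lexicon("t2", "bébé", "manger"),
                       use_lemma = FALSE)
  counts <- train_tables(proj, "framing")
  tri <- counts$trigram
  get <- function(k1, k2) {
    r <- tri[tri$key1 == k1 & tri$key2 == k2, ]
    setNames(r$count, r$completer)
  }
  expect_equal(get("le", "éléphant"), c(N = 1L))
  expect_equal(get("va", "}"), c(V = 1L))
  # a seed word occurring in a context stays a surface form
  expect_equal(get("bébé", "il"), c("éléphant" = 1L))
})

test_that("counts match the brute-force enumeration on random corpora", {
  schemes <- c("left", "right", "framing")
  for (seed in 1:6) {
    corp <- random_corpus(20, seed)
    lex <- unique(corpus_tokens(corp)$form)
    proj <- project_seed(corp, seed_lexicon("s", lex[1:3], lex[4:5]),
                         require_gold_tag = TRUE)
    sc <- schemes[(seed - 1) %% 3 + 1]
    counts <- train_tables(proj, sc)
    oracle <- oracle_tables(proj, sc)
    expect_equal(sorted_tri(counts$trigram), sorted_tri(oracle$trigram))
    expect_equal(sorted_bi(counts$bigram), sorted_bi(oracle$bigram))
  }
})

test_that("per scheme, trigram and bigram totals equal the token count", {
  corp <- random_corpus(25, 9)
  proj <- project_seed(corp, seed_lexicon("s", "w01", "w02"))
  for (sc in c("left", "right", "framing")) {
    counts <- train_tables(proj, sc)
    expect_equal(sum(counts$trigram$count), n_tokens(corp))
    expect_equal(sum(counts$bigram$count), n_tokens(corp))
  }
})

test_that("reversing utterances swaps left and right count multisets", {
  corp <- random_corpus(18, 13)
  tok <- corpus_tokens(corp)
  rev_tok <- do.call(rbind, lapply(split(tok, tok$utterance_id), function(u) {
    u[rev(seq_len(nrow(u))), ]
  }))
  rev_corp <- tagged_corpus(rev_tok)
  proj <- project_seed(corp, seed_lexicon("s", "w03", "w04"))
  proj_rev <- project_seed(rev_corp, seed_lexicon("s", "w03", "w04"))
  right <- train_tables(proj, "right")$trigram
  left_rev <- train_tables(proj_rev, "left")$trigram
  # reversed-left key (k1,k2) corresponds to right key (k2,k1) with the
  # boundary symbols mirrored
  swap_bound <- function(x) {
    out <- x
    out[x == "{"] <- "}"
    out[x == "}"] <- "{"
    out
  }
  mapped <- tibble::tibble(key1 = swap_bound(left_rev$key2),
                           key2 = swap_bound(left_rev$key1),
                           completer = left_rev$completer,
                           count = left_rev$count)
  expect_equal(sorted_tri(mapped), sorted_tri(right))
})

test_that("the frequency threshold is an exclusive upper bound", {
  # training corpus of exactly 20000 tokens: "freq9" appears 9 times
  # (0.045%), "freq10" 10 times (0.05%)
  n_filler <- 20000 - 19
  tok <- tibble::tibble(
    utterance_id = rep(1:2000, each = 10),
    form = c(rep("freq9", 9), rep("freq10", 10),
             sprintf("f%05d", seq_len(n_filler))),
    pos = "NOUN")
  proj <- project_seed(tagged_corpus(tok), seed_lexicon("s", "f00001",
                                                        character(0)))
  counts <- train_tables(proj, "left")
  expect_equal(counts$training_token_total, 20000)
  test <- tagged_corpus(tibble::tibble(
    utterance_id = c(1, 1, 1),
    form = c("freq9", "freq10", "neverseen"),
    pos = "NOUN"))
  sites <- select_targets(test, counts, threshold = 5e-4)
  expect_true("freq9" %in% sites$form)     # 0.045% < 0.05%: eligible
  expect_false("freq10" %in% sites$form)   # 0.05%: excluded
  expect_true("neverseen" %in% sites$form) # unseen words qualify
})

test_that("the known-context condition gates prediction attempts", {
  train <- tagged_corpus(tibble::tibble(
    utterance_id = c(1, 1), form = c("the", "cat"), pos = c("DET", "NOUN")))
  proj <- project_seed(train, seed_lexicon("s", "cat", character(0)))
  counts <- train_tables(proj, "left")
  test <- tagged_corpus(tibble::tibble(
    utterance_id = c(1, 1, 2, 2),
    form = c("the", "dax", "zorp", "blick"),
    pos = c("DET", "NOUN", "DET", "NOUN")))
  sites <- select_targets(test, counts)
  # "dax" after known "the" and utterance-initial "zorp" (boundary context)
  # qualify; "the" is far too frequent in the tiny training corpus (50%);
  # "blick" after unknown "zorp" is not attempted
  expect_setequal(sites$form, c("dax", "zorp"))
  # absolute-count alternative rule
  sites_cnt <- select_targets(test, counts, rule = "count", max_count = 1L)
  expect_false("the" %in% sites_cnt$form)  # seen once, cutoff 1
})

test_that("prediction picks the most frequent completer and backs off to bigrams", {
  # training: "{ the giraffe" x2, "{ the baby" x4, baby in the noun seed
  train <- tagged_corpus(tibble::tibble(
    utterance_id = rep(1:6, each = 2),
    form = c(rep(c("the", "giraffe"), 2), rep(c("the", "baby"), 4)),
    pos = rep(c("DET", "NOUN"), 6)))
  proj <- project_seed(train, seed_lexicon("s", "baby", c("go", "do")))
  counts <- train_tables(proj, "left")
  test <- tagged_corpus(tibble::tibble(
    utterance_id = 1, form = c("the", "dax"), pos = c("DET", "NOUN")))
  rec <- categorize_corpus(test, counts, quiet = TRUE)
  dax <- rec[rec$form == "dax", ]
  expect_equal(dax$response, "N")
  expect_equal(dax$response_type, "category")
  expect_equal(dax$provenance, "trigram")
  expect_equal(dax$context_used, "{ the _")

  # backoff: context "saw the" unseen as a trigram, "the" known as a bigram
  test2 <- tagged_corpus(tibble::tibble(
    utterance_id = 1, form = c("saw", "the", "dax"),
    pos = c("VERB", "DET", "NOUN")))
  # "saw" unseen in training => freq 0, qualifies; its left context is
  # boundary-only and known
  rec2 <- predict_targets(select_targets(test2, counts), counts)
  dax2 <- rec2[rec2$form == "dax", ]
  expect_equal(dax2$provenance, "bigram")
  expect_equal(dax2$response, "N")
  expect_equal(dax2$context_used, "the _")

  # nothing known at all: abstain
  test3 <- tagged_corpus(tibble::tibble(
    utterance_id = 1, form = c("dax"), pos = "NOUN"))
  counts3 <- counts
  rec3 <- predict_targets(
    select_targets(test3, counts3)[0, ], counts3)
  expect_equal(nrow(rec3), 0)
})

test_that("tie-breaking prefers category symbols, then alphabetic order", {
  train <- tagged_corpus(tibble::tibble(
    utterance_id = rep(1:4, each = 2),
    form = c("the", "cat", "the", "dog", "the", "cat", "the", "dog"),
    pos = rep(c("DET", "NOUN"), 4)))
  # cat projected: completers of "{ the" are {N: 2, dog: 2} -> N wins
  proj <- project_seed(train, seed_lexicon("s", "cat", character(0)))
  counts <- train_tables(proj, "left")
  test <- tagged_corpus(tibble::tibble(
    utterance_id = 1, form = c("the", "dax"), pos = c("DET", "NOUN")))
  rec <- predict_targets(select_targets(test, counts), counts)
  dax <- rec[rec$form == "dax", ]
  expect_equal(dax$response, "N")
  expect_true(dax$tie)

  # no projection: {cat: 2, dog: 2} -> alphabetic
  proj2 <- project_seed(train, seed_lexicon("s", character(0), character(0)))
  counts2 <- train_tables(proj2, "left")
  rec2 <- predict_targets(select_targets(test, counts2), counts2)
  expect_equal(rec2$response[rec2$form == "dax"], "cat")
})

test_that("whenever the trigram key is known the bigram table is never consulted", {
  corp <- random_corpus(40, 17)
  folds <- split_folds(corp, 2)
  proj <- project_seed(folds[[1]]$train, seed_lexicon("s", "w01", "w02"))
  for (sc in c("left", "framing")) {
    counts <- train_tables(proj, sc)
    rec <- categorize_corpus(folds[[1]]$test, counts, threshold = 1,
                             quiet = TRUE)
    tri_keys <- paste(counts$trigram_best$key1, counts$trigram_best$key2,
                      sep = "\r")
    has_tri <- paste(rec$key1, rec$key2, sep = "\r") %in% tri_keys
    expect_true(all(rec$provenance[has_tri] == "trigram"))
    expect_true(all(rec$provenance[!has_tri] != "trigram"))
  }
})

test_that("end-to-end predictions equal the position-by-position oracle", {
  for (seed in 1:4) {
    train <- random_corpus(25, seed * 100)
    test <- random_corpus(8, seed * 100 + 1)
    lex <- unique(corpus_tokens(train)$form)
    proj <- project_seed(train, seed_lexicon("s", lex[1:2], lex[3]))
    sc <- c("left", "right", "framing")[(seed - 1) %% 3 + 1]
    counts <- train_tables(proj, sc)
    rec <- categorize_corpus(test, counts, threshold = 1, quiet = TRUE)
    oracle <- oracle_tables(proj, sc)
    for (i in seq_len(nrow(rec))) {
      o <- oracle_predict_site(oracle$trigram, oracle$bigram,
                               rec$key1[i], rec$key2[i], rec$backoff[i])
      expect_identical(rec$provenance[i], o$provenance)
      if (o$provenance != "none") {
        expect_identical(rec$response[i], o$response)
      }
    }
  }
})

test_that("categorization is deterministic and self-test is fully trigram-covered", {
  proj <- project_seed(table2_corpus(),
                       seed_lexicon("t2", "bébé", "manger"),
                       use_lemma = FALSE)
  counts <- train_tables(proj, "framing")
  rec1 <- categorize_corpus(table2_corpus(), counts, threshold = 1,
                            quiet = TRUE)
  rec2 <- categorize_corpus(table2_corpus(), counts, threshold = 1,
                            quiet = TRUE)
  expect_identical(rec1, rec2)
  expect_true(all(rec1$provenance == "trigram"))

  empty <- tagged_corpus(tibble::tibble(utterance_id = integer(0),
                                        form = character(0),
                                        pos = character(0)))
  expect_equal(nrow(categorize_corpus(empty, counts, quiet = TRUE)), 0)
})

test_that("count tables round-trip through the TSV serialization", {
  corp <- random_corpus(20, 31)
  proj <- project_seed(corp, seed_lexicon("s", "w05", "w06"))
  counts <- train_tables(proj, "framing")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(counts, path)
  back <- read_counts_tsv(path)
  expect_equal(back$scheme, "framing")
  expect_equal(sorted_tri(back$trigram), sorted_tri(counts$trigram))
  expect_equal(sorted_bi(back$bigram), sorted_bi(counts$bigram))
})
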