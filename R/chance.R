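#' Chance rates from a projected training corpus
#'
#' The context-blind baseline predicts "N", "V" or "other" with
#' probabilities equal to the proportions of projected noun tokens,
#' projected verb tokens and everything else in the training corpus.
#'
#' @param projected A corpus returned by [project_seed()].
#' @return An object of class `chance_rates` with elements `p_N`, `p_V`,
#'   `p_other` (summing to 1).
#' @export
chance_rates <- function(projected) {
  n <- n_tokens(projected)
  if (n == 0) stop("cannot compute chance rates on an empty corpus",
                   call. = FALSE)
  tier <- projected$tokens$tier
  p_n <- sum(!is.na(tier) & tier == "N") / n
  p_v <- sum(!is.na(tier) & tier == "V") / n
  structure(list(p_N = p_n, p_V = p_v, p_other = 1 - p_n - p_v),
            class = "chance_rates")
}

#' @export
print.chance_rates <- function(x, ...) {
  cat(sprintf("<chance_rates: N %.3f, V %.3f, other %.3f>\n",
              x$p_N, x$p_V, x$p_other))
  invisible(x)
}

#' Context-blind random predictions
#'
#' One independent draw per target site from (p_N, p_V, p_other) with a
#' seeded generator; the same seed reproduces the same draw sequence. An
#' "other" draw is a non-category response (scored like any other wrong
#' reply), not an abstention.
#'
#' @param sites Target sites (typically [select_targets()] with
#'   `require_known_context = FALSE`, since the baseline uses no context).
#' @param rates A [chance_rates()] result (or a list with `p_N`, `p_V`,
#'   `p_other`).
#' @param rng_seed Integer seed for the draws.
#' @return The sites with `response`, `response_type`
#'   (`"category"`/`"other"`), `provenance = "chance"` and `context_used =
#'   NA`, matching the record layout of [predict_targets()].
#' @export
chance_predict <- function(sites, rates, rng_seed) {
  p <- c(rates$p_N, rates$p_V, rates$p_other)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("invalid chance rates", call. = FALSE)
  }
  m <- nrow(sites)
  draws <- withr::with_seed(rng_seed, {
    sample(c("N", "V", "other"), m, replace = TRUE, prob = p)
  })
  out <- sites
  out$response <- draws
  out$response_type <- ifelse(draws == "other", "other", "category")
  out$provenance <- "chance"
  out$context_used <- NA_character_
  out$tie <- FALSE
  out
}
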