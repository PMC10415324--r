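## Autism-Spectrum Quotient scoring, median split, normality check.

aq_response_levels <- c("strongly_agree", "slightly_agree",
                        "slightly_disagree", "strongly_disagree")

#' The packaged AQ scoring key
#'
#' Item-level key of the 50-item Autism-Spectrum Quotient instrument:
#' subscale membership (10 items in each of social skills, attention
#' switching, attention to detail, communication, imagination) and the
#' direction in which agreement is scored as ASD-characteristic. Shipped as
#' configuration data in `extdata/aq_scoring_key.csv`.
#'
#' @return data.frame with columns `item`, `subscale`, `agree_keyed`.
#' @export
aq_scoring_key <- function() {
  path <- system.file("extdata", "aq_scoring_key.csv", package = "saccadapt")
  key <- utils::read.csv(path, stringsAsFactors = FALSE)
  key$agree_keyed <- as.logical(key$agree_keyed)
  key
}

#' Simulate an AQ response set with a known total score
#'
#' Picks `target_score` items (at random under the current RNG state) to be
#' answered in their ASD-characteristic direction and answers the rest in
#' the opposite direction, choosing "slightly" vs "strongly" at random. The
#' binary scoring rule then recovers `target_score` exactly.
#'
#' @param target_score integer in 0-50.
#' @param seed optional seed.
#' @return data.frame with columns `item`, `response` (an `AqResponseSet`).
#' @export
simulate_aq_responses <- function(target_score, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target_score <- as.integer(target_score)
  if (is.na(target_score) || target_score < 0 || target_score > 50)
    stop("target_score must lie in 0-50")
  key <- aq_scoring_key()
  hit <- rep(FALSE, 50)
  hit[sample.int(50, target_score)] <- TRUE
  strength <- sample(c("strongly", "slightly"), 50, replace = TRUE)
  agree <- ifelse(hit, key$agree_keyed, !key$agree_keyed)
  resp <- paste0(strength, ifelse(agree, "_agree", "_disagree"))
  data.frame(item = key$item, response = resp, stringsAsFactors = FALSE)
}

#' Score an AQ response set
#'
#' Standard binary scoring: an item contributes 1 point when the response
#' agrees (slightly or strongly) with the item's ASD-characteristic
#' direction, 0 otherwise. Totals range 0-50; a total of 32 or more sets
#' the clinical flag (the threshold above which clinical assessment is
#' recommended).
#'
#' @param responses data.frame with columns `item` (1-50) and `response`
#'   (one of `strongly_agree`, `slightly_agree`, `slightly_disagree`,
#'   `strongly_disagree`).
#' @param key scoring key, by default [aq_scoring_key()].
#' @return an object of class `aq_score`: list with `total`,
#'   `subscale_totals` (named integer vector), `clinical_flag`,
#'   `item_scores`.
#' @export
#' @examples
#' score_aq(simulate_aq_responses(17, seed = 1))$total  # 17
score_aq <- function(responses, key = aq_scoring_key()) {
  if (!all(c("item", "response") %in% names(responses)))
    stop("responses needs columns 'item' and 'response'")
  missing <- setdiff(key$item, responses$item)
  if (length(missing) > 0)
    stop("incomplete response set; missing items: ",
         paste(missing, collapse = ", "))
  responses <- responses[!duplicated(responses$item), , drop = FALSE]
  bad <- setdiff(unique(responses$response), aq_response_levels)
  if (length(bad) > 0)
    stop("unknown response levels: ", paste(bad, collapse = ", "))
  m <- merge(key, responses, by = "item", sort = TRUE)
  agreed <- m$response %in% c("strongly_agree", "slightly_agree")
  score <- as.integer(agreed == m$agree_keyed)
  sub <- tapply(score, m$subscale, sum)
  total <- sum(score)
  structure(list(total = total,
                 subscale_totals = setNames(as.integer(sub), names(sub)),
                 clinical_flag = total >= 32,
                 item_scores = setNames(score, m$item)),
            class = "aq_score")
}

#' @export
print.aq_score <- function(x, ...) {
  cat(sprintf("<aq_score> total %d%s\n", x$total,
              if (x$clinical_flag) " [>=32: clinical assessment threshold]" else ""))
  print(x$subscale_totals)
  invisible(x)
}

#' Median split of AQ totals into low/high trait groups
#'
#' The median is the standard sample median (mean of the two middle order
#' statistics for even n). Scores at or below the median go to the low
#' group, scores above to the high group; the split is exhaustive and
#' disjoint.
#'
#' @param scores numeric vector of AQ totals (length >= 2).
#' @return list with `low` and `high` (integer index vectors into `scores`)
#'   and `median`.
#' @export
#' @examples
#' median_split(c(10, 12, 17, 20, 25))
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  med <- stats::median(scores)
  list(low = which(scores <= med), high = which(scores > med), median = med)
}

#' Sample quartiles of AQ totals
#'
#' Thin wrapper over [stats::quantile()]; the quartile convention (`type`)
#' is configurable because published quartiles rarely state theirs.
#'
#' @param scores numeric vector.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return named numeric vector `c(lower=, median=, upper=)`.
#' @export
aq_quartiles <- function(scores, type = 7) {
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  c(lower = q[1], median = q[2], upper = q[3])
}

#' Jarque-Bera test of composite normality
#'
#' `JB = n/6 * (S^2 + K^2/4)` with moment-based sample skewness `S` and
#' excess kurtosis `K`. The p value uses the asymptotic chi-square(2)
#' reference by default; `method = "mc"` draws a Monte-Carlo null
#' distribution instead, which is preferable at small n where the
#' chi-square reference is anticonservative in the tail.
#'
#' @param x numeric sample (n >= 8).
#' @param method `"chisq"` or `"mc"`.
#' @param n_mc Monte-Carlo replicates for `method = "mc"`.
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis_excess`,
#'   `n`, `method`.
#' @export
jarque_bera <- function(x, method = c("chisq", "mc"), n_mc = 5000) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("jarque_bera requires n >= 8")
  jb_stat <- function(z) {
    m <- mean(z); d <- z - m
    m2 <- mean(d^2); s <- mean(d^3) / m2^1.5; k <- mean(d^4) / m2^2 - 3
    length(z) / 6 * (s^2 + k^2 / 4)
  }
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("degenerate sample: zero variance")
  s <- mean(d^3) / m2^1.5
  k <- mean(d^4) / m2^2 - 3
  jb <- n / 6 * (s^2 + k^2 / 4)
  p <- if (method == "chisq") {
    stats::pchisq(jb, df = 2, lower.tail = FALSE)
  } else {
    null <- vapply(seq_len(n_mc), function(i) jb_stat(rnorm(n)), numeric(1))
    (sum(null >= jb) + 1) / (n_mc + 1)
  }
  list(statistic = jb, p_value = p, skewness = s, kurtosis_excess = k,
       n = n, method = method)
}
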