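# E-Scale scoring: a 25-item, 7-point Likert empathy questionnaire with 22
# positively and 3 negatively worded items (reverse-coded), split into 13
# fictitious-situation and 12 real-life-situation items; cohort descriptives
# and a Kolmogorov-Smirnov normality check.

.ESCALE_N_ITEMS <- 25L
.ESCALE_MIN <- 1L
.ESCALE_MAX <- 7L

#' Construct an E-Scale scoring key
#'
#' The published instrument does not print which 3 items are negatively
#' worded nor the exact item-subscale assignment, so the default key is a
#' synthetic stand-in satisfying the published structure: items 7, 15 and 23
#' negative, items 1-13 fictitious, items 14-25 real-life.  Supply your own
#' assignment when the real key is available.
#'
#' @param negative_items Integer vector of exactly 3 item numbers (1-25).
#' @param fictitious_items Integer vector of exactly 13 item numbers; the
#'   remaining 12 form the real-life subscale.
#' @return An `escale_key` with per-item `polarity` and `subscale`.
#' @export
escale_key <- function(negative_items = c(7L, 15L, 23L),
                       fictitious_items = 1:13) {
  negative_items <- sort(unique(as.integer(negative_items)))
  fictitious_items <- sort(unique(as.integer(fictitious_items)))
  items <- seq_len(.ESCALE_N_ITEMS)
  if (length(negative_items) != 3L || !all(negative_items %in% items))
    stop("escale_key: exactly 3 negative items in 1..25 required")
  if (length(fictitious_items) != 13L || !all(fictitious_items %in% items))
    stop("escale_key: exactly 13 fictitious items in 1..25 required")
  polarity <- ifelse(items %in% negative_items, "negative", "positive")
  subscale <- ifelse(items %in% fictitious_items, "fictitious", "real_life")
  structure(list(n_items = .ESCALE_N_ITEMS,
                 polarity = polarity, subscale = subscale,
                 range = c(.ESCALE_MIN, .ESCALE_MAX)),
            class = "escale_key")
}

#' Read / write a key file (CSV: item, polarity, subscale)
#'
#' @param path CSV path.
#' @return An `escale_key` (reader) or `path` invisibly (writer).
#' @export
read_escale_key <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "polarity", "subscale")
  if (!all(need %in% names(df)))
    stop("key file must have columns: ", paste(need, collapse = ", "))
  df <- df[order(as.integer(df$item)), ]
  if (!identical(as.integer(df$item), 1:25))
    stop("key file must cover items 1..25 exactly once")
  escale_key(negative_items = which(df$polarity == "negative"),
             fictitious_items = which(df$subscale == "fictitious"))
}

#' @rdname read_escale_key
#' @param key An `escale_key`.
#' @export
write_escale_key <- function(key, path) {
  stopifnot(inherits(key, "escale_key"))
  utils::write.csv(data.frame(item = 1:25, polarity = key$polarity,
                              subscale = key$subscale),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score one E-Scale response vector
#'
#' Total = sum of positive-item responses plus sum of reverse-coded
#' (r -> 8 - r) negative-item responses; range 25-175.
#'
#' @param responses 25 integers, each in 1..7.
#' @param key An [escale_key()].
#' @return The total score (integer).
#' @export
score_escale <- function(responses, key = escale_key()) {
  stopifnot(inherits(key, "escale_key"))
  r <- suppressWarnings(as.numeric(responses))
  if (length(r) != key$n_items)
    stop("score_escale: expected ", key$n_items, " responses, got ", length(r))
  bad <- which(!is.finite(r) | r < key$range[1] | r > key$range[2] | r != round(r))
  if (length(bad))
    stop("score_escale: invalid response at item(s) ",
         paste(bad, collapse = ", "), " (must be integers in 1..7)")
  neg <- key$polarity == "negative"
  as.integer(sum(r[!neg]) + sum(8 - r[neg]))
}

#' Score a cohort responses table
#'
#' @param df Data frame with `subject_id` and item columns `item01..item25`.
#' @param key An [escale_key()].
#' @return Data frame `subject_id, total_score, per_item_mean`; row-level
#'   scoring errors are collected and reported together with row numbers.
#' @export
score_responses_table <- function(df, key = escale_key()) {
  item_cols <- sprintf("item%02d", 1:25)
  missing_cols <- setdiff(c("subject_id", item_cols), names(df))
  if (length(missing_cols))
    stop("responses table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  totals <- integer(nrow(df))
  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    t <- tryCatch(score_escale(unlist(df[i, item_cols]), key),
                  error = function(e) e)
    if (inherits(t, "error")) {
      errs <- c(errs, sprintf("row %d (%s): %s", i, df$subject_id[i],
                              conditionMessage(t)))
    } else totals[i] <- t
  }
  if (length(errs))
    stop("invalid responses:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  data.frame(subject_id = as.character(df$subject_id),
             total_score = totals,
             per_item_mean = totals / 25,
             stringsAsFactors = FALSE)
}

#' Cohort descriptive statistics on total scores
#'
#' Sample mean and SD (n - 1 denominator) of the totals and their per-item
#' versions (totals / 25; exact linear transforms, so per-item SD = total
#' SD / 25).
#'
#' @param totals Numeric vector of total scores, n >= 2.
#' @return List: `n`, `mean`, `sd`, `per_item_mean`, `per_item_sd`.
#' @export
cohort_descriptives <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 2L)
    stop("cohort_descriptives: SD undefined for n < 2")
  m <- mean(totals); s <- stats::sd(totals)
  list(n = length(totals), mean = m, sd = s,
       per_item_mean = m / 25, per_item_sd = s / 25)
}

# asymptotic Kolmogorov distribution upper tail:
# P(sqrt(n) D > x) = 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 x^2)
.kolmogorov_p <- function(x, kmax = 100L) {
  if (x < 1e-8) return(1)
  k <- seq_len(kmax)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' D = sup |ECDF - Phi((x - m)/s)| against the normal fitted to the sample
#' (its own mean and SD), with the asymptotic Kolmogorov p-value.  Because
#' the parameters are estimated from the same sample, the p-value is
#' anti-conservative (the Lilliefors caveat); this mirrors the default in
#' common statistics packages.
#'
#' @param totals Numeric sample, n >= 5, non-constant.
#' @param mean,sd Optional reference-normal parameters; by default fitted
#'   from the sample itself.
#' @return List: `D`, `p`, `n`, `mean`, `sd`.
#' @export
ks_normality <- function(totals, mean = NULL, sd = NULL) {
  x <- sort(as.numeric(totals))
  n <- length(x)
  if (n < 5L) stop("ks_normality: need at least 5 observations")
  m <- if (is.null(mean)) base::mean(x) else mean
  s <- if (is.null(sd)) stats::sd(x) else sd
  if (s == 0) stop("ks_normality: zero-variance sample")
  Fx <- stats::pnorm(x, m, s)
  i <- seq_len(n)
  D <- max(pmax(i / n - Fx, Fx - (i - 1) / n))
  list(D = D, p = .kolmogorov_p(sqrt(n) * D), n = n, mean = m, sd = s)
}
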