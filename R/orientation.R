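# Automatic scoring of the time-orientation task: the speaker is asked the
# current date (Western calendar) and day of the week; the transcript earns
# one point for each correctly stated element - year, month, day of month,
# day of week - for a score of 0-4.

#' Load a locale rule set for orientation scoring
#'
#' Rule sets map month names, weekday names and numeral words to values,
#' and are shipped as JSON so locales can be added without code changes.
#' English (`"en"`) and Japanese (`"ja"`) rule sets are bundled.
#'
#' @param locale `"en"` or `"ja"`, ignored when `path` is given.
#' @param path Optional path to a custom rule-set JSON file.
#' @return A list of class `orientation_rules`.
#' @export
orientation_rules <- function(locale = c("en", "ja"), path = NULL) {
  if (is.null(path)) {
    locale <- match.arg(locale)
    path <- system.file("extdata",
                        sprintf("orientation-rules-%s.json", locale),
                        package = "voicescreen")
  }
  if (!nzchar(path) || !file.exists(path))
    vs_config(sprintf("rule set not found: %s", path))
  rules <- jsonlite::fromJSON(path)
  if (is.null(rules$locale) ||
      (!length(rules$months) && !length(rules$weekdays)))
    vs_config(sprintf("empty or malformed rule set: %s", path))
  class(rules) <- "orientation_rules"
  rules
}

# ISO weekday number (1 = Monday .. 7 = Sunday) of a Date.
iso_weekday <- function(date) {
  wd <- as.POSIXlt(date)$wday            # 0 = Sunday
  ifelse(wd == 0L, 7L, wd)
}

# Case-fold, unify width/punctuation, and split into tokens. Multi-word
# numerals ("twenty four") are matched greedily against the rule set.
normalize_transcript <- function(transcript) {
  x <- tolower(transcript)
  x <- chartr("０１２３４５６７８９",
              "0123456789", x)           # full-width digits
  x <- gsub("-", " ", x, fixed = TRUE)
  x
}

# Extract candidate values for one element type from tokens + rule maps.
match_words <- function(text, map) {
  if (!length(map)) return(integer(0))
  keys <- names(map)
  # longest keys first so "twenty four" wins over "four"
  keys <- keys[order(-nchar(keys))]
  found <- integer(0)
  for (k in keys) {
    if (grepl(paste0("\\b", k, "\\b"), text)) {
      found <- c(found, as.integer(map[[k]]))
      text <- gsub(paste0("\\b", k, "\\b"), " ", text)
    }
  }
  found
}

extract_candidates <- function(transcript, rules) {
  x <- normalize_transcript(transcript)
  years <- integer(0); months <- integer(0)
  days <- integer(0); wdays <- integer(0)

  if (identical(rules$locale, "ja")) {
    # marker-based extraction: N年 / N月 / N日 / X曜日
    m <- regmatches(x, gregexpr("[0-9]+年", x))[[1]]
    years <- as.integer(sub("年", "", m))
    m <- regmatches(x, gregexpr("[0-9]+月", x))[[1]]
    months <- as.integer(sub("月", "", m))
    m <- regmatches(x, gregexpr("[0-9]+日", x))[[1]]
    days <- as.integer(sub("日", "", m))
    # no word boundaries between CJK characters: match weekday names as
    # fixed substrings, longest keys first
    keys <- names(rules$weekdays)
    keys <- keys[order(-nchar(keys))]
    for (k in keys) {
      if (grepl(k, x, fixed = TRUE)) {
        wdays <- c(wdays, as.integer(rules$weekdays[[k]]))
        x <- gsub(k, " ", x, fixed = TRUE)
      }
    }
  } else {
    x_nm <- x
    months <- match_words(x_nm, rules$months)
    wdays <- match_words(x_nm, rules$weekdays)
    num_tokens <- regmatches(x, gregexpr("[0-9]+", x))[[1]]
    nums <- suppressWarnings(as.integer(num_tokens))
    nums <- nums[!is.na(nums)]
    years <- nums[nums >= 1900 & nums <= 2099]
    days <- nums[nums >= 1 & nums <= 31]
    word_nums <- match_words(x, rules$numbers)
    days <- c(days, word_nums[word_nums >= 1 & word_nums <= 31])
  }
  list(year = unique(years), month = unique(months),
       day = unique(days), weekday = unique(wdays))
}

#' Score a transcribed time-orientation response
#'
#' Awards one point each for a correct Western-calendar year, month,
#' day of month and day of week found in the transcript; elements that are
#' absent or wrong earn nothing. Matching is case-insensitive and tolerant
#' of numeral words per the locale rule set. The reference date is an
#' explicit input (never the wall clock) so scoring is reproducible.
#'
#' @param transcript Response text (UTF-8).
#' @param reference_date The true date, as a `Date` or `"YYYY-MM-DD"` string.
#' @param rules An [orientation_rules()] rule set.
#' @return A list of class `orientation_result`: `score` (integer 0-4),
#'   `elements` (named character: `"correct"`, `"incorrect"` or `"absent"`
#'   for year/month/day/weekday), `reference_date`, `transcript`.
#' @examples
#' rules <- orientation_rules("en")
#' score_response("today is tuesday may fourteenth 2024", "2024-05-14", rules)
#' @export
score_response <- function(transcript, reference_date,
                           rules = orientation_rules("en")) {
  if (!inherits(rules, "orientation_rules"))
    vs_config("rules must be an orientation_rules object")
  ref <- tryCatch(as.Date(reference_date),
                  error = function(e) NA)
  if (is.na(ref)) vs_invalid("reference_date is not a valid calendar date")
  if (!is.character(transcript) || length(transcript) != 1L)
    vs_validation("transcript must be a single character string")

  truth <- list(year = as.integer(format(ref, "%Y")),
                month = as.integer(format(ref, "%m")),
                day = as.integer(format(ref, "%d")),
                weekday = iso_weekday(ref))
  cand <- extract_candidates(transcript, rules)
  elements <- vapply(names(truth), function(el) {
    cc <- cand[[el]]
    if (!length(cc)) "absent"
    else if (truth[[el]] %in% cc) "correct"
    else "incorrect"
  }, character(1))
  structure(list(score = sum(elements == "correct"),
                 elements = elements,
                 reference_date = ref,
                 transcript = transcript),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("<orientation_result> score %d/4 (%s)\n", x$score,
              paste(names(x$elements), x$elements, sep = "=",
                    collapse = ", ")))
  invisible(x)
}
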