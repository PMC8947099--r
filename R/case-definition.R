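#' Define how AOM-related visits are recognised
#'
#' A case definition combines ICD-9-CM code prefixes (default rubric 382,
#' suppurative and unspecified otitis media, so that `382`, `382.0`,
#' `382.00`, ... all match), token-level free-text patterns, and an
#' exclusion list of exact free-text strings standing in for expert review
#' of false positives.
#'
#' Text patterns are matched against whitespace-delimited tokens of the
#' (optionally lower-cased) diagnosis text: `prefix` patterns must anchor at
#' the start of a token, `substring` patterns may occur anywhere inside a
#' token. The defaults implement the classic otitis search -- `oti*`,
#' `*oti*`, `om*`, `*om*`.
#'
#' @param icd9_prefixes character vector of code prefixes; a code matches if
#'   it starts with a prefix at a code-field boundary.
#' @param text_patterns data frame with columns `pattern` and `mode`
#'   (`"prefix"` or `"substring"`).
#' @param exclusion_list character vector of full free-text strings to
#'   reject even when a pattern matches, or a path to a UTF-8 file with one
#'   string per line (`#` comments allowed).
#' @param case_sensitive should text matching respect case? Default `FALSE`.
#' @return an object of class `case_definition`.
#' @examples
#' def <- case_definition()
#' match_icd9("382.00", def)
#' match_freetext("otite media acuta", def)
#' @export
case_definition <- function(icd9_prefixes = "382",
                            text_patterns = default_text_patterns(),
                            exclusion_list = character(),
                            case_sensitive = FALSE) {
  if (length(icd9_prefixes) == 0 || any(!nzchar(icd9_prefixes))) {
    abort("`icd9_prefixes` must be a non-empty character vector")
  }
  text_patterns <- as_tibble(text_patterns)
  if (nrow(text_patterns) == 0 ||
      !all(c("pattern", "mode") %in% names(text_patterns))) {
    abort("`text_patterns` must have rows with columns `pattern` and `mode`")
  }
  if (!all(text_patterns$mode %in% c("prefix", "substring"))) {
    abort("pattern `mode` must be 'prefix' or 'substring'")
  }
  if (is.character(exclusion_list) && length(exclusion_list) == 1 &&
      file.exists(exclusion_list)) {
    exclusion_list <- read_exclusion_list(exclusion_list)
  }
  norm <- function(x) if (case_sensitive) x else tolower(x)
  structure(
    list(
      icd9_prefixes = trimws(icd9_prefixes),
      text_patterns = mutate(text_patterns, pattern = norm(.data$pattern)),
      exclusion_list = unique(norm(trimws(exclusion_list))),
      case_sensitive = case_sensitive
    ),
    class = "case_definition"
  )
}

#' @rdname case_definition
#' @export
default_text_patterns <- function() {
  tibble(
    pattern = c("oti", "oti", "om", "om"),
    mode = c("prefix", "substring", "prefix", "substring")
  )
}

#' Read a free-text exclusion list
#'
#' One string per line, UTF-8; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of exclusion strings.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @export
print.case_definition <- function(x, ...) {
  cat("<case_definition>\n")
  cat("  ICD-9 prefixes: ", paste(x$icd9_prefixes, collapse = ", "), "\n")
  cat("  text patterns:  ",
      paste(sprintf("%s(%s)", x$text_patterns$pattern, x$text_patterns$mode),
            collapse = ", "), "\n")
  cat("  exclusions:     ", length(x$exclusion_list), " string(s)\n", sep = "")
  invisible(x)
}

#' Match a diagnosis code against the ICD-9 prefixes
#'
#' A code matches when, after stripping whitespace, it begins with a
#' configured prefix and the prefix ends at a code-field boundary (the end
#' of the code or a `.`, or the prefix itself contains the dot). `"382"`,
#' `"382.0"` and `"382.00"` match prefix `"382"`; `"38"`, `"3821"` and
#' `"038.2"` do not.
#'
#' @param code character vector of diagnosis codes; `NA` and empty strings
#'   return `FALSE`.
#' @param definition a [case_definition()].
#' @return logical vector.
#' @export
match_icd9 <- function(code, definition = case_definition()) {
  code <- gsub("\\s+", "", as.character(code))
  out <- rep(FALSE, length(code))
  ok <- !is.na(code) & nzchar(code)
  for (pref in definition$icd9_prefixes) {
    np <- nchar(pref)
    starts <- ok & substr(code, 1, np) == pref
    boundary <- nchar(code) == np |
      substr(code, np + 1, np + 1) == "." |
      substr(code, np, np) == "."
    out <- out | (starts & boundary)
  }
  out
}

# Split a visit's code field on common delimiters; all positions (primary
# and secondary) are checked.
split_codes <- function(code_field) {
  strsplit(as.character(code_field), "[;,|[:space:]]+")
}

match_icd9_any <- function(code_field, definition) {
  purrr::map_lgl(split_codes(code_field), function(codes) {
    if (length(codes) == 0) return(FALSE)
    any(match_icd9(codes, definition))
  })
}

#' Match free-text diagnosis strings against the text patterns
#'
#' The text is normalised (lower-cased unless the definition is
#' case-sensitive) and split into whitespace-delimited tokens. It matches
#' when any pattern hits any token -- prefix patterns at the token start,
#' substring patterns anywhere in the token -- unless the full normalised
#' text is on the exclusion list.
#'
#' @param text character vector; `NA` and empty strings return `FALSE`.
#' @inheritParams match_icd9
#' @return logical vector.
#' @export
match_freetext <- function(text, definition = case_definition()) {
  text <- as.character(text)
  norm <- if (definition$case_sensitive) text else tolower(text)
  norm <- trimws(norm)
  out <- rep(FALSE, length(text))
  ok <- !is.na(norm) & nzchar(norm)
  if (!any(ok)) return(out)
  toks <- strsplit(norm[ok], "[[:space:]]+")
  pats <- definition$text_patterns
  hit <- purrr::map_lgl(toks, function(tk) {
    for (i in seq_len(nrow(pats))) {
      p <- pats$pattern[i]
      found <- if (pats$mode[i] == "prefix") {
        any(startsWith(tk, p))
      } else {
        any(grepl(p, tk, fixed = TRUE))
      }
      if (found) return(TRUE)
    }
    FALSE
  })
  excluded <- norm[ok] %in% definition$exclusion_list
  out[ok] <- hit & !excluded
  out
}

#' Identify AOM-related visits
#'
#' Filters a visit table to the visits whose ICD-9 code (any position in a
#' delimiter-separated code field) or free-text diagnosis satisfies the case
#' definition. Input order is preserved and a `match_rule` column records
#' which rule fired (`icd9`, `text`, or `both`). Rows whose `visit_date`
#' fails to parse are rejected with a warning; the reject count is stored in
#' the `n_rejected` attribute of the result.
#'
#' @param visits data frame with columns `child_id`, `visit_date`, and
#'   optionally `icd9` and `free_text`.
#' @param definition a [case_definition()].
#' @return tibble of AOM-related visits with an added `match_rule` column.
#' @export
identify_aom_visits <- function(visits, definition = case_definition()) {
  visits <- as_tibble(visits)
  if (!all(c("child_id", "visit_date") %in% names(visits))) {
    abort("`visits` must have columns `child_id` and `visit_date`")
  }
  if (nrow(visits) == 0) {
    out <- mutate(visits, match_rule = character(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  parsed <- suppressWarnings(
    as.Date(as.character(visits$visit_date), format = "%Y-%m-%d")
  )
  bad <- is.na(parsed)
  if (any(bad)) {
    warn(sprintf("rejecting %d visit row(s) with unparseable dates", sum(bad)))
    visits <- visits[!bad, , drop = FALSE]
    parsed <- parsed[!bad]
  }
  visits$visit_date <- parsed
  icd <- if ("icd9" %in% names(visits)) {
    match_icd9_any(visits$icd9, definition)
  } else rep(FALSE, nrow(visits))
  txt <- if ("free_text" %in% names(visits)) {
    match_freetext(visits$free_text, definition)
  } else rep(FALSE, nrow(visits))
  keep <- icd | txt
  out <- visits[keep, , drop = FALSE]
  out$match_rule <- dplyr::case_when(
    icd[keep] & txt[keep] ~ "both",
    icd[keep] ~ "icd9",
    TRUE ~ "text"
  )
  attr(out, "n_rejected") <- sum(bad)
  out
}
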