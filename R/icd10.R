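# ICD-10 code parsing, normalisation, and exclusion rules.
#
# All analysis happens at the three-character "category" level (letter plus
# two digits, e.g. "I10"); the leading letter is the "chapter". Fourth and
# further characters (subcategories such as "E11.9") carry clinical detail
# that the mining model deliberately discards.

#' Parse and normalise ICD-10 codes to three-character categories
#'
#' Accepts raw ICD-10 code strings in both bare three-character form
#' (`"I10"`) and longer subdivided forms (`"E11.9"`, `"E119"`), trims
#' whitespace, uppercases, and truncates to the three-character category.
#' The category must match one letter followed by exactly two digits.
#'
#' @param x Character vector of raw ICD-10 codes.
#' @param strict If `TRUE` (default) any malformed code aborts with an error
#'   naming the offending value. If `FALSE`, malformed codes yield `NA`
#'   rows and a warning reporting how many were skipped; downstream
#'   functions drop and count them, which is the faithful pipeline
#'   behaviour for records with incomplete data.
#'
#' @return A tibble with one row per input code and columns `raw` (the input
#'   as received), `category` (normalised three-character code) and
#'   `chapter` (its first letter). Malformed codes under `strict = FALSE`
#'   have `NA` category and chapter.
#'
#' @examples
#' icd10_parse(c("E11.9", "I10", "k29"))
#' @export
icd10_parse <- function(x, strict = TRUE) {
  if (length(x) == 0) {
    return(tibble(raw = character(), category = character(), chapter = character()))
  }
  x <- as.character(x)
  cleaned <- toupper(gsub("\\s+", "", x))
  category <- substr(cleaned, 1L, 3L)
  ok <- !is.na(x) & grepl("^[A-Z][0-9]{2}", cleaned)
  if (!all(ok)) {
    bad <- unique(x[!ok])
    if (strict) {
      abort(paste0(
        "Malformed ICD-10 code(s): ",
        paste(utils::head(bad, 5L), collapse = ", "),
        if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "",
        ". Expected a letter followed by two digits (e.g. \"I10\", \"E11.9\")."
      ))
    }
    warn(sprintf("Skipping %d malformed ICD-10 code(s).", sum(!ok)))
    category[!ok] <- NA_character_
  }
  tibble(
    raw = x,
    category = category,
    chapter = substr(category, 1L, 1L)
  )
}

#' Define a code-level exclusion policy
#'
#' Encodes which diagnosis codes are removed before mining: whole ICD-10
#' chapters that do not represent diseases (by default "V"--"Y", external
#' causes, and "Z", factors influencing health status) and codes whose free
#' -text description contains a catch-all token (by default the standalone
#' word "other", since such codes lump heterogeneous conditions into one
#' category).
#'
#' @param excluded_chapters Character vector of single uppercase chapter
#'   letters to drop entirely. Default `c("V","W","X","Y","Z")`.
#' @param description_token Word whose presence in a code's description
#'   excludes the code. Matched as a standalone word (word-boundary regex),
#'   so "Other gastritis" matches but "Motherhood" does not. Default
#'   `"other"`.
#' @param case_sensitive Should the token match case-sensitively?
#'   Default `FALSE`.
#'
#' @return An object of class `exclusion_policy`.
#' @examples
#' exclusion_policy()
#' exclusion_policy(excluded_chapters = c("U", "V", "W", "X", "Y", "Z"))
#' @export
exclusion_policy <- function(excluded_chapters = c("V", "W", "X", "Y", "Z"),
                             description_token = "other",
                             case_sensitive = FALSE) {
  excluded_chapters <- toupper(as.character(excluded_chapters))
  if (length(excluded_chapters) > 0 && !all(grepl("^[A-Z]$", excluded_chapters))) {
    abort("`excluded_chapters` must be single letters A-Z.")
  }
  if (!is.character(description_token) || length(description_token) != 1L) {
    abort("`description_token` must be a single string.")
  }
  structure(
    list(
      excluded_chapters = sort(unique(excluded_chapters)),
      description_token = description_token,
      case_sensitive = isTRUE(case_sensitive)
    ),
    class = "exclusion_policy"
  )
}

#' @export
print.exclusion_policy <- function(x, ...) {
  cat("<exclusion_policy>\n")
  cat("  excluded chapters:", paste(x$excluded_chapters, collapse = ", "), "\n")
  cat(sprintf(
    "  description token: \"%s\" (%s, word-boundary match)\n",
    x$description_token,
    if (x$case_sensitive) "case-sensitive" else "case-insensitive"
  ))
  invisible(x)
}

#' Test whether codes are excluded under a policy
#'
#' A code is excluded when its chapter letter belongs to the policy's
#' excluded chapters, or when its description contains the policy token as
#' a standalone word. An empty or missing description never triggers the
#' token rule.
#'
#' @param chapter Character vector of chapter letters (or three-character
#'   categories; only the first character is used).
#' @param description Character vector of free-text code descriptions,
#'   recycled against `chapter`.
#' @param policy An [exclusion_policy()].
#'
#' @return Logical vector, `TRUE` where the code is excluded.
#' @examples
#' pol <- exclusion_policy()
#' is_excluded("Z51", "Care involving chemotherapy", pol) # TRUE: Z chapter
#' is_excluded("K29", "Other gastritis", pol)             # TRUE: token
#' is_excluded("M79", "Motherhood-related myalgia", pol)  # FALSE
#' @export
is_excluded <- function(chapter, description = "", policy = exclusion_policy()) {
  stopifnot(inherits(policy, "exclusion_policy"))
  ch <- toupper(substr(as.character(chapter), 1L, 1L))
  n <- max(length(ch), length(description))
  ch <- rep_len(ch, n)
  description <- rep_len(as.character(description), n)
  description[is.na(description)] <- ""
  by_chapter <- ch %in% policy$excluded_chapters
  pattern <- paste0("\\b", escape_regex(policy$description_token), "\\b")
  by_token <- stringr::str_detect(
    description,
    stringr::regex(pattern, ignore_case = !policy$case_sensitive)
  )
  by_chapter | by_token
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
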