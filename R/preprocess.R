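#' Read a complaint table and apply the cleaning rules
#'
#' Reads a delimited UTF-8 table of complaint records and applies the intake
#' cleaning rules used throughout the pipeline: records whose free-text
#' content is missing or blank are excluded (and counted), and dates that do
#' not parse as real calendar dates are replaced by the sentinel `"—"` rather
#' than dropped or errored on.
#'
#' @param path Path to a CSV/TSV file with a header row. The delimiter is
#'   taken from `delim`, or guessed from the extension (`.tsv` → tab,
#'   otherwise comma) when `delim = NULL`.
#' @param id_col,text_col Names of the required id and free-text columns.
#' @param date_col,channel_col,group_col Optional column names; silently
#'   skipped when absent from the file.
#' @param delim Field delimiter, or `NULL` to guess.
#'
#' @return A tibble with columns `record_id`, `date` (ISO-8601 string or the
#'   sentinel `"—"`), `channel`, `group`, `raw_text`, in file order. A cleaning
#'   summary is attached as attribute `"cleaning"` (a tibble with `rows_read`,
#'   `rows_dropped`, `dates_sentineled`) and also available via
#'   [cleaning_summary()].
#'
#' @details Dates are accepted in ISO-8601 (`YYYY-MM-DD`) or `YYYY/MM/DD`
#'   form and must be real calendar dates (`2024-13-45` is sentineled).
#'   Undecodable (non-UTF-8) bytes raise an input error reporting the byte
#'   offset of the first offender. Text is Unicode NFC-normalized.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,date,text", "1,2024-01-02,long wait", "2,2024-13-45,rude desk"), f)
#' x <- read_complaints(f)
#' x$date # "2024-01-02" "—"
#' cleaning_summary(x)
#' @export
read_complaints <- function(path,
                            id_col = "id",
                            text_col = "text",
                            date_col = "date",
                            channel_col = "channel",
                            group_col = "group",
                            delim = NULL) {
  if (!file.exists(path)) {
    abort_input(paste0("complaint file not found: ", path))
  }
  assert_utf8_file(path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  for (col in c(id_col, text_col)) {
    if (!col %in% names(raw)) {
      abort_config(paste0(
        "required column '", col, "' not found in ", path,
        " (columns present: ", paste(names(raw), collapse = ", "), ")"
      ))
    }
  }
  rows_read <- nrow(raw)
  opt <- function(col) {
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, rows_read)
  }
  out <- tibble(
    record_id = raw[[id_col]],
    date = opt(date_col),
    channel = opt(channel_col),
    group = opt(group_col),
    raw_text = stringi::stri_trans_nfc(raw[[text_col]])
  )
  keep <- !is.na(out$raw_text) & trimws(out$raw_text) != ""
  out <- out[keep, , drop = FALSE]
  parsed <- sentinel_date(out$date)
  out$date <- parsed$date
  out <- as_tibble(out)
  attr(out, "cleaning") <- tibble(
    rows_read = rows_read,
    rows_dropped = rows_read - nrow(out),
    dates_sentineled = parsed$n_sentineled
  )
  out
}

#' Retrieve the cleaning summary attached by [read_complaints()]
#' @param x A tibble returned by [read_complaints()].
#' @return A one-row tibble: `rows_read`, `rows_dropped`, `dates_sentineled`.
#' @export
cleaning_summary <- function(x) {
  s <- attr(x, "cleaning")
  if (is.null(s)) abort_input("no cleaning summary attached to this object")
  s
}

# date sentinel used for unparseable dates
DATE_SENTINEL <- "—"

# Parse to ISO-8601 or sentinel. Accepts YYYY-MM-DD and YYYY/MM/DD; must be a
# real calendar date. NA dates count as sentineled only if originally present.
sentinel_date <- function(x) {
  norm <- gsub("/", "-", trimws(ifelse(is.na(x), "", x)))
  ok <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", norm)
  d <- rep(as.Date(NA), length(norm))
  d[ok] <- as.Date(norm[ok], format = "%Y-%m-%d", optional = TRUE)
  valid <- ok & !is.na(d)
  out <- ifelse(valid, format(d, "%Y-%m-%d"), DATE_SENTINEL)
  list(date = out, n_sentineled = sum(!valid))
}

assert_utf8_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(bytes)
  if (!validUTF8(txt)) {
    # locate first invalid byte by testing growing prefixes in chunks
    for (i in seq_along(bytes)) {
      if (!validUTF8(rawToChar(bytes[seq_len(i)]))) {
        abort_input(paste0("undecodable (non-UTF-8) byte at offset ", i, " in ", path))
      }
    }
  }
  invisible(TRUE)
}

#' Collapse adjacently repeated substrings ("mechanical compression")
#'
#' De-duplicates machine-repeated text: any maximal run of an adjacent,
#' identically repeated substring of length at most `max_unit` is collapsed to
#' a single occurrence, scanning left to right and re-applying until a fixed
#' point is reached. Natural non-repetitive prose is unchanged.
#'
#' @param text Character vector (vectorized).
#' @param max_unit Longest repeated-unit length to collapse (default 5).
#' @return Character vector of the same length; each element no longer than
#'   its input.
#' @examples
#' mechanical_compress("abcabcabc")        # "abc"
#' mechanical_compress(strrep("好", 4), 1) # one character
#' @export
mechanical_compress <- function(text, max_unit = 5L) {
  if (max_unit < 1) abort_config("max_unit must be >= 1")
  vapply(text, compress_one, character(1), max_unit = as.integer(max_unit), USE.NAMES = FALSE)
}

compress_one <- function(x, max_unit) {
  if (is.na(x) || x == "") {
    return(x)
  }
  repeat {
    before <- x
    for (u in seq_len(max_unit)) {
      # (?s): a unit may contain newlines; \1+ collapses the whole run
      pat <- paste0("(?s)(.{", u, "})\\1+")
      x <- gsub(pat, "\\1", x, perl = TRUE)
    }
    if (identical(x, before)) {
      return(x)
    }
  }
}

# segmenter registry ---------------------------------------------------------

.segmenters <- new.env(parent = emptyenv())

#' Register a text segmenter
#'
#' Segmenters are plug-ins mapped by id. `"whitespace"` (split on Unicode
#' whitespace) and `"character"` (each CJK character its own token, contiguous
#' latin/digit runs kept together — a dependency-free adapter for Chinese
#' text) are pre-registered.
#'
#' @param id Segmenter identifier.
#' @param fn Function taking one string, returning a character vector of
#'   tokens.
#' @return `id`, invisibly.
#' @export
register_segmenter <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1, is.function(fn))
  assign(id, fn, envir = .segmenters)
  invisible(id)
}

#' List registered segmenter ids
#' @return Character vector of ids.
#' @export
list_segmenters <- function() sort(ls(.segmenters))

seg_whitespace <- function(x) {
  toks <- stringi::stri_split_regex(x, "\\s+", omit_empty = TRUE)[[1]]
  if (length(toks) == 0) character(0) else toks
}

# CJK-aware fallback: each Han/Kana/Hangul char is a token; runs of
# letters/digits stay whole; punctuation and whitespace are separators.
seg_character <- function(x) {
  m <- stringi::stri_extract_all_regex(
    x, "[\\p{Han}\\p{Hiragana}\\p{Katakana}\\p{Hangul}]|[\\p{L}\\p{N}]+"
  )[[1]]
  if (length(m) == 1 && is.na(m[1])) character(0) else m
}

local({
  register_segmenter("whitespace", seg_whitespace)
  register_segmenter("character", seg_character)
})

#' Tokenize text with a registered segmenter
#'
#' @param text A single string (NFC-normalized before segmentation).
#' @param segmenter Segmenter id; see [list_segmenters()].
#' @return Character vector of tokens (empty for empty input). Deterministic
#'   for a fixed segmenter and input.
#' @examples
#' tokenize("poor attitude here")
#' tokenize("态度差", segmenter = "character")
#' @export
tokenize <- function(text, segmenter = "whitespace") {
  if (!segmenter %in% ls(.segmenters)) {
    abort_config(paste0(
      "unknown segmenter '", segmenter, "'; available: ",
      paste(list_segmenters(), collapse = ", ")
    ))
  }
  if (is.na(text) || text == "") {
    return(character(0))
  }
  get(segmenter, envir = .segmenters)(stringi::stri_trans_nfc(text))
}

#' Read a stop-word list
#'
#' Plain text, one token per line; `#` starts a comment; blank lines ignored;
#' entries NFC-normalized and deduplicated.
#'
#' @param path File path.
#' @return Character vector of stop-words.
#' @export
read_stoplist <- function(path) {
  if (!file.exists(path)) abort_input(paste0("stop-list file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(stringi::stri_trans_nfc(lines[lines != ""]))
}

#' Remove stop-words from a token vector
#'
#' Exact string match after NFC normalization; order of the surviving tokens
#' is preserved. Idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param stoplist Character vector of stop-words (e.g. from
#'   [read_stoplist()]).
#' @return Filtered token vector.
#' @export
remove_stopwords <- function(tokens, stoplist) {
  if (length(tokens) == 0) {
    return(character(0))
  }
  toks <- stringi::stri_trans_nfc(tokens)
  tokens[!toks %in% stringi::stri_trans_nfc(stoplist)]
}

#' Run the full preprocessing stage over a complaint table
#'
#' Convenience wrapper chaining [mechanical_compress()], [tokenize()] and
#' [remove_stopwords()] over the `raw_text` column, adding a `tokens`
#' list-column.
#'
#' @param records Tibble from [read_complaints()] (needs `raw_text`).
#' @param stoplist Character vector of stop-words (default none).
#' @param segmenter Segmenter id.
#' @param max_unit Mechanical-compression unit length; `0` disables
#'   compression.
#' @return `records` with a `tokens` list-column appended.
#' @export
preprocess_corpus <- function(records, stoplist = character(0),
                              segmenter = "whitespace", max_unit = 5L) {
  txt <- records$raw_text
  if (max_unit >= 1) txt <- mechanical_compress(txt, max_unit)
  records$tokens <- purrr::map(txt, function(t) {
    remove_stopwords(tokenize(t, segmenter), stoplist)
  })
  records
}
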