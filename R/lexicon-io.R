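#' Construct a Lexicon from an entry table
#'
#' Normalizes the entry table (missing optional columns are added as NA,
#' case/number labels are lower-cased), derives the phone alphabet from the
#' forms and validates the result.
#'
#' @param entries data.frame with at least columns form, lemma, case, number,
#'   frequency; optional gender, role, definiteness, article, syllables.
#' @param source free-text provenance description.
#' @return a \linkS4class{Lexicon}.
#' @export
Lexicon <- function(entries = data.frame(), source = "") {
  req <- c("form", "lemma", "case", "number", "frequency")
  if (nrow(entries) > 0) {
    missing <- setdiff(req, names(entries))
    if (length(missing) > 0)
      stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in .LEX_COLUMNS) {
    if (!col %in% names(entries))
      entries[[col]] <- if (col == "frequency") integer(0)[seq_len(nrow(entries))] else
        rep(NA_character_, nrow(entries))
  }
  if (nrow(entries) > 0) {
    entries$form <- as.character(entries$form)
    entries$lemma <- as.character(entries$lemma)
    entries$case <- tolower(as.character(entries$case))
    entries$number <- tolower(as.character(entries$number))
    entries$gender <- tolower(as.character(entries$gender))
    entries$frequency <- as.integer(entries$frequency)
    entries$role <- as.character(entries$role)
    entries$definiteness <- as.character(entries$definiteness)
    entries$article <- as.character(entries$article)
    entries$syllables <- as.character(entries$syllables)
  }
  rownames(entries) <- NULL
  keep <- c(.LEX_COLUMNS, setdiff(names(entries), .LEX_COLUMNS))
  entries <- entries[, keep, drop = FALSE]
  alpha <- sort(unique(unlist(strsplit(entries$form, ""))))
  new("Lexicon", entries = entries, alphabet = as.character(alpha),
      source = as.character(source))
}

.detectSep <- function(header) {
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a paradigm lexicon from delimited text
#'
#' Expects UTF-8 tab- or comma-delimited text with a header row and at least
#' the columns form, lemma, case, number and frequency (additional columns
#' such as gender, role, definiteness and syllables are picked up when
#' present). \code{dialect} maps canonical column names to the file's own
#' header names, e.g. \code{c(form = "Pronunciation", lemma = "Lemma")}.
#'
#' @param path file path.
#' @param dialect optional named character vector, canonical name -> file
#'   column name.
#' @param sep field separator; autodetected from the header when NULL.
#' @return a \linkS4class{Lexicon}; row order of the file is preserved.
#' @export
readLexicon <- function(path, dialect = NULL, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0)
    stop("empty file (no header): ", path)
  if (is.null(sep)) sep <- .detectSep(header)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      fileCol <- dialect[[canon]]
      if (!fileCol %in% names(raw))
        stop("dialect column not in file: ", fileCol)
      names(raw)[names(raw) == fileCol] <- canon
    }
  }
  names(raw) <- tolower(names(raw))
  req <- c("form", "lemma", "case", "number", "frequency")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0)
    stop("lexicon file lacks required column(s): ",
         paste(missing, collapse = ", "))
  freq <- suppressWarnings(as.integer(raw$frequency))
  bad <- which(is.na(freq) & !is.na(raw$frequency))
  if (length(bad) > 0)
    stop("non-integer frequency at row ", bad[1], ": '", raw$frequency[bad[1]], "'")
  raw$frequency <- freq
  Lexicon(raw, source = path)
}

#' Write a lexicon as delimited text
#'
#' Emits the canonical column set (dropping all-NA optional columns) in the
#' same dialect \code{readLexicon} accepts, so write-then-read round-trips.
#'
#' @param lex a \linkS4class{Lexicon}.
#' @param path output file path.
#' @param sep field separator (tab by default).
#' @export
writeLexicon <- function(lex, path, sep = "\t") {
  e <- entries(lex)
  optional <- c("gender", "role", "definiteness", "article", "syllables")
  drop <- optional[vapply(optional, function(col) all(is.na(e[[col]])), logical(1))]
  e <- e[, setdiff(names(e), drop), drop = FALSE]
  utils::write.table(e, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Select a subset of lexicon entries
#'
#' @param lex a \linkS4class{Lexicon}.
#' @param idx integer or logical index into the entries.
#' @return a \linkS4class{Lexicon} with the selected entries, in index order.
#' @export
subsetLexicon <- function(lex, idx) {
  Lexicon(entries(lex)[idx, , drop = FALSE], source = lex@source)
}
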