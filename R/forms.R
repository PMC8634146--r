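#' Extract phone or letter n-gram cues from a form
#'
#' The form is padded with a single boundary symbol \code{#} on each side and
#' all length-n substrings are returned in order. For "al@" with n = 3 the
#' cues are #al, al@, l@#; with n = 2 they are #a, al, l@, @#. A form shorter
#' than n - 2 symbols collapses to the single padded cue #form#.
#'
#' @param form non-empty character string (one character per phone, or an
#'   orthographic string in letter mode).
#' @param n n-gram size, >= 2.
#' @return ordered character vector of cues.
#' @export
extractNgramCues <- function(form, n) {
  if (length(form) != 1 || is.na(form) || !nzchar(form))
    stop("form must be a single non-empty string")
  if (n < 2) stop("n must be >= 2")
  padded <- paste0(.BOUNDARY, form, .BOUNDARY)
  L <- nchar(padded)
  if (L <= n) return(padded)
  substring(padded, 1:(L - n + 1), n:L)
}

#' Extract syllable n-gram cues
#'
#' The syllable list is padded with a boundary element on each side and all
#' length-n windows are returned, elements joined by "-". For syllables
#' ("a", "l@") with n = 2 the cues are #-a, a-l@, l@-#.
#'
#' @param syllables non-empty character vector of syllable strings.
#' @param n window size, >= 2.
#' @return ordered character vector of cues.
#' @export
extractSyllableCues <- function(syllables, n) {
  if (length(syllables) == 0 || any(is.na(syllables)))
    stop("syllable list must be non-empty")
  if (n < 2) stop("n must be >= 2")
  elems <- c(.BOUNDARY, syllables, .BOUNDARY)
  m <- length(elems)
  if (m <= n) return(paste(elems, collapse = .SYL_SEP))
  vapply(1:(m - n + 1),
         function(i) paste(elems[i:(i + n - 1)], collapse = .SYL_SEP),
         character(1))
}

.entryCues <- function(e, unit, n) {
  if (unit %in% c("phone", "letter")) {
    lapply(e$form, extractNgramCues, n = n)
  } else {
    if (any(is.na(e$syllables)))
      stop("syllable cues need a syllables column for every entry")
    lapply(strsplit(e$syllables, ".", fixed = TRUE), extractSyllableCues, n = n)
  }
}

#' Build the binary cue matrix C
#'
#' Each lexicon entry becomes a binary row vector over the cue inventory: 1
#' codes presence of the cue in the entry's form (presence/absence coding; a
#' cue repeated within one form still sets its bit once). Without a frozen
#' inventory the inventory is built in first-occurrence order over the
#' lexicon. With a frozen inventory (vectorizing validation or nonce forms)
#' cues absent from it are dropped and reported per entry; an entry whose
#' cues are all novel yields a zero row.
#'
#' @param lex a \linkS4class{Lexicon}.
#' @param unit "phone", "letter" or "syllable".
#' @param n n-gram size.
#' @param inventory optional frozen \linkS4class{CueInventory}.
#' @return a \linkS4class{CueMatrix} (the inventory is in its
#'   \code{cueInventory()}; per-entry novel cues in \code{novelCues()}).
#' @export
buildCueMatrix <- function(lex, unit = c("phone", "letter", "syllable"),
                           n = 3L, inventory = NULL) {
  unit <- match.arg(unit)
  n <- as.integer(n)
  e <- entries(lex)
  cueList <- .entryCues(e, unit, n)
  if (is.null(inventory)) {
    inventory <- new("CueInventory", unit = unit, n = n,
                     cues = unique(unlist(cueList)))
    novel <- rep(list(character(0)), nrow(e))
  } else {
    if (inventory@unit != unit || inventory@n != n)
      stop("frozen inventory has unit/n mismatch")
    novel <- lapply(cueList, function(cc) unique(cc[!(cc %in% inventory@cues)]))
  }
  idx <- lapply(cueList, function(cc) {
    j <- match(unique(cc), inventory@cues)
    j[!is.na(j)]
  })
  allNovel <- vapply(idx, length, integer(1)) == 0 & nrow(e) > 0
  if (any(allNovel))
    warning(sum(allNovel), " entr(ies) have only novel cues (zero row): ",
            paste(utils::head(e$form[allNovel], 5), collapse = ", "))
  i <- rep(seq_along(idx), lengths(idx))
  j <- unlist(idx)
  values <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(nrow(e), length(inventory@cues)),
                                 dimnames = list(NULL, inventory@cues))
  new("CueMatrix", values = values, inventory = inventory,
      rowKeys = seq_len(nrow(e)), novel = novel)
}

#' Vectorize a single form against a frozen inventory
#'
#' @param form a form string, or a character vector of syllables when the
#'   inventory is syllable-based.
#' @param inventory a frozen \linkS4class{CueInventory}.
#' @return list with \code{vector} (binary numeric vector over the inventory,
#'   zero bits for unknown cues) and \code{novel} (cues of the form absent
#'   from the inventory, in order of occurrence).
#' @export
vectorizeForm <- function(form, inventory) {
  cc <- if (inventory@unit == "syllable")
    extractSyllableCues(form, inventory@n)
  else
    extractNgramCues(paste(form, collapse = ""), inventory@n)
  j <- match(cc, inventory@cues)
  v <- numeric(length(inventory@cues))
  names(v) <- inventory@cues
  v[unique(j[!is.na(j)])] <- 1
  list(vector = v, novel = unique(cc[is.na(j)]))
}

#' Ordered cue path of a form
#'
#' The cues of a form in left-to-right order (the path through the cue graph
#' that spells the form). Used by positional production modeling and by the
#' surface-reconstruction round trip.
#'
#' @inheritParams vectorizeForm
#' @return character vector of cues in order (unknown cues included).
#' @export
cuePath <- function(form, inventory) {
  if (inventory@unit == "syllable")
    extractSyllableCues(form, inventory@n)
  else
    extractNgramCues(paste(form, collapse = ""), inventory@n)
}
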