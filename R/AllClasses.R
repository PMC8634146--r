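#' @import methods
#' @importFrom Matrix sparseMatrix Matrix t colSums rowSums
NULL

.CASES <- c("nominative", "genitive", "dative", "accusative")
.NUMBERS <- c("singular", "plural")
.GENDERS <- c("m", "f", "n")
.BOUNDARY <- "#"
.SYL_SEP <- "-"

.LEX_COLUMNS <- c("form", "lemma", "case", "number", "gender", "frequency",
                  "role", "definiteness", "article", "syllables")

#' Lexicon of inflected word forms
#'
#' One row per paradigm cell realization: a surface form (a string with one
#' character per phone, or an orthographic string in letter mode), its lemma,
#' case, number, optional gender, a non-negative token frequency, and optional
#' semantic role, definiteness, article and syllabification annotations.
#'
#' @slot entries data.frame with columns \code{form}, \code{lemma},
#'   \code{case}, \code{number}, \code{gender}, \code{frequency}, \code{role},
#'   \code{definiteness}, \code{article}, \code{syllables} (syllables as a
#'   "."-separated string).
#' @slot alphabet character vector of symbols occurring in the forms.
#' @slot source free-text description of where the data came from.
#' @exportClass Lexicon
setClass("Lexicon",
         slots = c(entries = "data.frame",
                   alphabet = "character",
                   source = "character"))

setValidity("Lexicon", function(object) {
  e <- object@entries
  missing <- setdiff(.LEX_COLUMNS, names(e))
  if (length(missing) > 0)
    return(paste("missing entry columns:", paste(missing, collapse = ", ")))
  if (nrow(e) == 0) return(TRUE)
  if (any(is.na(e$form)) || any(!nzchar(e$form)))
    return("every entry must have a non-empty form")
  if (any(is.na(e$frequency)) || any(e$frequency < 0))
    return("frequencies must be non-negative")
  bad <- !(e$case %in% .CASES)
  if (any(bad))
    return(paste("unknown case label(s):", paste(unique(e$case[bad]), collapse = ", ")))
  bad <- !(e$number %in% .NUMBERS)
  if (any(bad))
    return(paste("unknown number label(s):", paste(unique(e$number[bad]), collapse = ", ")))
  key <- paste(e$lemma, e$case, e$number, e$role, e$definiteness, sep = "\r")
  if (anyDuplicated(key))
    return("(lemma, case, number, role, definiteness) combinations must be unique")
  syl <- !is.na(e$syllables)
  if (any(syl)) {
    flat <- gsub(".", "", e$syllables[syl], fixed = TRUE)
    if (!all(flat == e$form[syl]))
      return("syllables must concatenate to the form")
  }
  TRUE
})

#' Inventory of sublexical cues
#'
#' The ordered vocabulary of n-gram cues extracted from a training lexicon.
#' Cue order is first-occurrence order, which makes rebuilding the inventory
#' from the same lexicon deterministic.
#'
#' @slot unit "phone", "letter" or "syllable".
#' @slot n n-gram size (>= 2).
#' @slot cues ordered character vector of distinct cue strings.
#' @exportClass CueInventory
setClass("CueInventory",
         slots = c(unit = "character", n = "integer", cues = "character"))

setValidity("CueInventory", function(object) {
  if (!(object@unit %in% c("phone", "letter", "syllable")))
    return("unit must be one of phone, letter, syllable")
  if (length(object@n) != 1 || object@n < 2)
    return("n must be a single integer >= 2")
  if (anyDuplicated(object@cues)) return("cues must be distinct")
  TRUE
})

#' Binary cue matrix C
#'
#' Sparse binary matrix with one row per lexicon entry and one column per
#' inventory cue; 1 codes presence of the cue in the entry's form. Homophonous
#' entries have identical rows by construction.
#'
#' @slot values sparse binary matrix (rows = entries, columns = cues).
#' @slot inventory the \linkS4class{CueInventory} defining the columns.
#' @slot rowKeys integer indices of the lexicon entries the rows describe.
#' @slot novel list (per row) of cues present in the form but absent from a
#'   frozen inventory; empty when the inventory was built from the same data.
#' @exportClass CueMatrix
setClass("CueMatrix",
         slots = c(values = "Matrix", inventory = "CueInventory",
                   rowKeys = "integer", novel = "list"))

setValidity("CueMatrix", function(object) {
  v <- object@values
  if (ncol(v) != length(object@inventory@cues))
    return("column count must equal inventory size")
  if (nrow(v) != length(object@rowKeys))
    return("rowKeys must have one entry per row")
  x <- v@x
  if (length(x) && !all(x %in% c(0, 1))) return("values must be binary")
  TRUE
})

#' Semantic space of lexeme and inflectional-feature vectors
#'
#' Holds one real vector per lexeme and one per inflectional feature
#' (SINGULAR, PLURAL, case or semantic-role labels, DEFINITE, INDEFINITE).
#' The meaning of an inflected word is composed by summing its lexeme vector
#' with the vectors of its inflectional features.
#'
#' @slot d dimensionality of the space.
#' @slot lexemeVectors numeric matrix, rows named by lemma.
#' @slot featureVectors numeric matrix, rows named by feature label.
#' @slot params list with sdLexeme, sdFeature, sdNoise, featureScale, seed.
#' @exportClass SemanticSpace
setClass("SemanticSpace",
         slots = c(d = "integer", lexemeVectors = "matrix",
                   featureVectors = "matrix", params = "list"))

setValidity("SemanticSpace", function(object) {
  if (nrow(object@lexemeVectors) > 0 && ncol(object@lexemeVectors) != object@d)
    return("lexeme vectors must have dimension d")
  if (nrow(object@featureVectors) > 0 && ncol(object@featureVectors) != object@d)
    return("feature vectors must have dimension d")
  TRUE
})

#' Semantic matrix S
#'
#' Real-valued matrix with one row (semantic vector) per lexicon entry.
#'
#' @slot values numeric matrix (rows = entries, columns = dimensions).
#' @slot rowKeys integer indices of the lexicon entries the rows describe.
#' @exportClass SemanticMatrix
setClass("SemanticMatrix",
         slots = c(values = "matrix", rowKeys = "integer"))

setValidity("SemanticMatrix", function(object) {
  if (nrow(object@values) != length(object@rowKeys))
    return("rowKeys must have one entry per row")
  if (length(object@values) && !all(is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' Linear form/meaning mapping
#'
#' A weight matrix mapping cue vectors to semantic vectors (comprehension, F)
#' or semantic vectors to cue supports (production, G), together with how it
#' was estimated: as the least-squares end-state of learning or incrementally
#' with the Widrow-Hoff rule.
#'
#' @slot weights numeric matrix (input dimension x output dimension).
#' @slot direction "comprehension" or "production".
#' @slot training list: mode ("endstate"/"incremental"), eta, eventsSeen, epochs.
#' @exportClass LinearMapping
setClass("LinearMapping",
         slots = c(weights = "matrix", direction = "character",
                   training = "list"))

setValidity("LinearMapping", function(object) {
  if (!(object@direction %in% c("comprehension", "production")))
    return("direction must be comprehension or production")
  if (length(object@weights) && !all(is.finite(object@weights)))
    return("weights must be finite")
  TRUE
})

#' Train/validation split of a lexicon
#'
#' The validation entries are partitioned into homophones (surface form also
#' occurs in training), new forms (unseen surface whose lemma is represented
#' in training) and excluded novel lemmas (unseen surface, unseen lemma).
#' Index slots index into the validation lexicon.
#'
#' @slot train training \linkS4class{Lexicon}.
#' @slot validation validation \linkS4class{Lexicon}.
#' @slot valHomophones integer indices (into validation) of homophones.
#' @slot valNewforms integer indices of new forms with known lemmas.
#' @slot excludedNovelLemmas integer indices of entries with novel lemmas.
#' @slot mode "random" or "no_novel_cues".
#' @slot seed integer seed the split was drawn with.
#' @exportClass SplitResult
setClass("SplitResult",
         slots = c(train = "Lexicon", validation = "Lexicon",
                   valHomophones = "integer", valNewforms = "integer",
                   excludedNovelLemmas = "integer",
                   mode = "character", seed = "integer"))

setValidity("SplitResult", function(object) {
  nv <- nrow(object@validation@entries)
  all3 <- sort(c(object@valHomophones, object@valNewforms,
                 object@excludedNovelLemmas))
  if (!identical(all3, seq_len(nv)))
    return("category indices must partition the validation entries")
  TRUE
})
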