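#' Accessors for discrimlex classes
#'
#' \code{entries} returns the entry table of a Lexicon; \code{alphabet} its
#' symbol inventory; \code{cues} the ordered cue vocabulary; \code{rowKeys}
#' the lexicon indices behind matrix rows; \code{novelCues} the per-row novel
#' cue report of a CueMatrix vectorized against a frozen inventory;
#' \code{mappingWeights} the weight matrix of a LinearMapping.
#'
#' @param x,object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setMethod("entries", "Lexicon", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setMethod("alphabet", "Lexicon", function(x) x@alphabet)

#' @rdname accessors
#' @export
setGeneric("cues", function(x) standardGeneric("cues"))
#' @rdname accessors
#' @export
setMethod("cues", "CueInventory", function(x) x@cues)
#' @rdname accessors
#' @export
setMethod("cues", "CueMatrix", function(x) x@inventory@cues)

#' @rdname accessors
#' @export
setGeneric("cueInventory", function(x) standardGeneric("cueInventory"))
#' @rdname accessors
#' @export
setMethod("cueInventory", "CueMatrix", function(x) x@inventory)

#' @rdname accessors
#' @export
setGeneric("rowKeys", function(x) standardGeneric("rowKeys"))
#' @rdname accessors
#' @export
setMethod("rowKeys", "CueMatrix", function(x) x@rowKeys)
#' @rdname accessors
#' @export
setMethod("rowKeys", "SemanticMatrix", function(x) x@rowKeys)

#' @rdname accessors
#' @export
setGeneric("novelCues", function(x) standardGeneric("novelCues"))
#' @rdname accessors
#' @export
setMethod("novelCues", "CueMatrix", function(x) x@novel)

#' @rdname accessors
#' @export
setGeneric("mappingWeights", function(x) standardGeneric("mappingWeights"))
#' @rdname accessors
#' @export
setMethod("mappingWeights", "LinearMapping", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname accessors
#' @export
setMethod("direction", "LinearMapping", function(x) x@direction)

#' @rdname accessors
#' @export
setGeneric("trainingInfo", function(x) standardGeneric("trainingInfo"))
#' @rdname accessors
#' @export
setMethod("trainingInfo", "LinearMapping", function(x) x@training)

#' @rdname accessors
#' @export
setGeneric("lexemeVectors", function(x) standardGeneric("lexemeVectors"))
#' @rdname accessors
#' @export
setMethod("lexemeVectors", "SemanticSpace", function(x) x@lexemeVectors)

#' @rdname accessors
#' @export
setGeneric("featureVectors", function(x) standardGeneric("featureVectors"))
#' @rdname accessors
#' @export
setMethod("featureVectors", "SemanticSpace", function(x) x@featureVectors)

#' @rdname accessors
#' @export
setGeneric("trainLexicon", function(x) standardGeneric("trainLexicon"))
#' @rdname accessors
#' @export
setMethod("trainLexicon", "SplitResult", function(x) x@train)

#' @rdname accessors
#' @export
setGeneric("validationLexicon", function(x) standardGeneric("validationLexicon"))
#' @rdname accessors
#' @export
setMethod("validationLexicon", "SplitResult", function(x) x@validation)

#' @rdname accessors
#' @export
setGeneric("valHomophones", function(x) standardGeneric("valHomophones"))
#' @rdname accessors
#' @export
setMethod("valHomophones", "SplitResult", function(x) x@valHomophones)

#' @rdname accessors
#' @export
setGeneric("valNewforms", function(x) standardGeneric("valNewforms"))
#' @rdname accessors
#' @export
setMethod("valNewforms", "SplitResult", function(x) x@valNewforms)

#' @rdname accessors
#' @export
setGeneric("excludedNovelLemmas", function(x) standardGeneric("excludedNovelLemmas"))
#' @rdname accessors
#' @export
setMethod("excludedNovelLemmas", "SplitResult", function(x) x@excludedNovelLemmas)

#' @export
setMethod("length", "Lexicon", function(x) nrow(x@entries))

#' Coerce a CueMatrix or SemanticMatrix to a base matrix
#' @param x the object.
#' @param ... unused.
#' @export
setMethod("as.matrix", "CueMatrix", function(x, ...) as.matrix(x@values))
#' @rdname as.matrix-CueMatrix-method
#' @export
setMethod("as.matrix", "SemanticMatrix", function(x, ...) x@values)

setMethod("show", "Lexicon", function(object) {
  e <- object@entries
  cat(sprintf("Lexicon with %d entries (%d distinct forms, %d lemmas)\n",
              nrow(e), length(unique(e$form)), length(unique(e$lemma))))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
  cat("  alphabet:", paste(object@alphabet, collapse = " "), "\n")
  if (nrow(e) > 0) {
    cat(sprintf("  total token frequency: %d\n", sum(e$frequency)))
    print(utils::head(e[, c("form", "lemma", "case", "number", "frequency")], 5))
    if (nrow(e) > 5) cat("  ...\n")
  }
})

setMethod("show", "CueInventory", function(object) {
  cat(sprintf("CueInventory: %d %s %d-gram cues\n",
              length(object@cues), object@unit, object@n))
  cat("  first cues:", paste(utils::head(object@cues, 8), collapse = " "), "\n")
})

setMethod("show", "CueMatrix", function(object) {
  cat(sprintf("CueMatrix: %d entries x %d cues (%s %d-grams), density %.3f\n",
              nrow(object@values), ncol(object@values),
              object@inventory@unit, object@inventory@n,
              length(object@values@x) / max(1, prod(dim(object@values)))))
  nNov <- sum(lengths(object@novel) > 0)
  if (nNov > 0) cat(sprintf("  %d entries carry novel cues\n", nNov))
})

setMethod("show", "SemanticSpace", function(object) {
  cat(sprintf("SemanticSpace: d = %d, %d lexemes, %d features\n",
              object@d, nrow(object@lexemeVectors), nrow(object@featureVectors)))
  p <- object@params
  cat(sprintf("  sdLexeme = %s, sdFeature = %s, sdNoise = %s, featureScale = %s\n",
              format(p$sdLexeme), format(p$sdFeature), format(p$sdNoise),
              format(p$featureScale)))
})

setMethod("show", "SemanticMatrix", function(object) {
  cat(sprintf("SemanticMatrix: %d entries x %d dimensions\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "LinearMapping", function(object) {
  cat(sprintf("LinearMapping (%s): %d x %d weights, %s",
              object@direction, nrow(object@weights), ncol(object@weights),
              object@training$mode))
  if (identical(object@training$mode, "incremental"))
    cat(sprintf(" (eta = %s, %d events)", format(object@training$eta),
                object@training$eventsSeen))
  cat("\n")
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult (%s, seed %d): %d train / %d validation\n",
              object@mode, object@seed,
              nrow(object@train@entries), nrow(object@validation@entries)))
  cat(sprintf("  validation: %d homophones, %d new forms, %d novel lemmas\n",
              length(object@valHomophones), length(object@valNewforms),
              length(object@excludedNovelLemmas)))
})
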