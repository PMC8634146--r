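#' Demonstration nonce forms
#'
#' The twelve nonce nouns used for wug-task demonstration runs (all have
#' existing German rhymes). Any character vector of nonce forms can be used
#' instead.
#'
#' @return character vector of 12 nonce forms.
#' @export
wugNonceForms <- function() {
  c("Bral", "Kach", "Klot", "Mur", "Nuhl", "Pind",
    "Pisch", "Pund", "Raun", "Spand", "Spert", "Vag")
}

#' Estimate nonce-word meanings through the comprehension mapping
#'
#' Vectorizes each nonce against the frozen training inventory (novel cues
#' are dropped and reported) and maps the cue vector into semantic space:
#' shat = c F. A nonce sharing no cues with the training data yields a zero
#' cue vector and is rejected, since nothing can be estimated for it.
#'
#' @param nonces character vector of nonce forms.
#' @param F comprehension \linkS4class{LinearMapping} trained on the full
#'   word lexicon.
#' @param inventory the frozen training \linkS4class{CueInventory}.
#' @return list with \code{meanings} (matrix, one row per nonce),
#'   \code{novel} (per-nonce novel cues) and \code{vectors} (binary cue
#'   matrix of the nonces).
#' @export
estimateNonceMeaning <- function(nonces, F, inventory) {
  vs <- lapply(nonces, vectorizeForm, inventory = inventory)
  known <- vapply(vs, function(v) sum(v$vector) > 0, logical(1))
  if (any(!known))
    stop("nonce(s) share no cues with the training data: ",
         paste(nonces[!known], collapse = ", "))
  V <- do.call(rbind, lapply(vs, `[[`, "vector"))
  rownames(V) <- nonces
  list(meanings = predictSemantics(V, F),
       novel = stats::setNames(lapply(vs, `[[`, "novel"), nonces),
       vectors = V)
}

#' Simulate the wug task: produce plural candidates for nonce words
#'
#' The five-step nonce-plural pipeline: (1) train a comprehension mapping
#' on the full real-word lexicon; (2) estimate each nonce's nominative
#' singular meaning by mapping its cue vector into semantic space; (3)
#' re-estimate the production (and comprehension) mappings on the real
#' words plus the nonces with their estimated meanings; (4) shift each
#' nonce meaning to plural by adding the PLURAL vector and subtracting the
#' SINGULAR vector; (5) synthesize ranked plural candidates with
#' \code{\link{learnPaths}}. Letter bigrams are the default cue unit, and a
#' small feature scale (default 1/110) keeps the inflectional vectors from
#' dominating the lexeme, which yields a more diverse candidate set.
#'
#' @param nonces character vector of nonce forms (nominative singular).
#' @param lex real-word training \linkS4class{Lexicon} (without articles).
#' @param space a \linkS4class{SemanticSpace} providing SINGULAR and PLURAL
#'   vectors (build it with the desired \code{featureScale}).
#' @param config a \code{\link{productionConfig}}.
#' @param unit,n cue unit and size (default letter bigrams).
#' @param numberCoding passed to \code{\link{buildSemanticMatrix}}.
#' @param seed seed for the semantic noise draws.
#' @return list of per-nonce results: each with \code{nonce},
#'   \code{sSg}, \code{sPl} (estimated singular / target plural meaning)
#'   and \code{candidates} (ranked data.frame from \code{learnPaths}).
#' @export
wugProducePlural <- function(nonces, lex, space,
                             config = productionConfig(),
                             unit = "letter", n = 2L,
                             numberCoding = "equipollent", seed = 1L) {
  if (!all(c("SINGULAR", "PLURAL") %in% rownames(space@featureVectors)))
    stop("space must provide SINGULAR and PLURAL feature vectors")
  cm <- buildCueMatrix(lex, unit = unit, n = n)
  inventory <- cueInventory(cm)
  S <- buildSemanticMatrix(lex, space, numberCoding = numberCoding,
                           seed = seed)
  Fmap <- estimateEndstate(cm, S, direction = "comprehension")
  est <- estimateNonceMeaning(nonces, Fmap, inventory)

  # retrain on real words plus nonces (known only in the singular)
  Cfull <- rbind(.asDense(cm), est$vectors)
  Sfull <- rbind(as.matrix(S), est$meanings)
  G <- estimateEndstate(Sfull, Cfull, direction = "production")
  F2 <- estimateEndstate(Cfull, Sfull, direction = "comprehension")

  shift <- space@featureVectors["PLURAL", ] - space@featureVectors["SINGULAR", ]
  sPl <- sweep(est$meanings, 2, -shift)
  trainPaths <- lapply(entries(lex)$form, function(f)
    match(cuePath(f, inventory), cues(inventory)))
  cands <- learnPaths(sPl, G, F2, inventory, config = config, mode = "graph",
                      trainPaths = trainPaths)
  lapply(seq_along(nonces), function(i)
    list(nonce = nonces[i], sSg = est$meanings[i, ], sPl = sPl[i, ],
         candidates = cands[[i]]))
}
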