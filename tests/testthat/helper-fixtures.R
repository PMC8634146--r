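# shared fixtures, all built in code

# the eel paradigm: 7 cells, 3 distinct surfaces (heavy homophony)
table3Entries <- function() {
  data.frame(
    form = c("al", "al", "al", "al@", "al@", "al@n", "al@n"),
    lemma = "Aal",
    case = c("nominative", "dative", "accusative",
             "nominative", "genitive", "dative", "accusative"),
    number = c(rep("singular", 3), rep("plural", 4)),
    gender = "m",
    frequency = c(29L, 29L, 29L, 34L, 34L, 17L, 17L),
    stringsAsFactors = FALSE)
}

table3Lexicon <- function() Lexicon(table3Entries(), source = "eel paradigm")

# fully regular, homophone-free lexicon: one singular (stem) and one plural
# (stem + "e") per lemma, all surfaces distinct
separableLexicon <- function(nLemmas = 10, seed = 1) {
  set.seed(seed)
  cons <- c("b", "d", "k", "l", "m", "n", "p", "r", "s", "t")
  vow <- c("a", "i", "o", "u")
  stems <- character(0)
  while (length(stems) < nLemmas) {
    s <- paste0(sample(cons, 1), sample(vow, 1), sample(cons, 1),
                sample(vow, 1), sample(cons, 1))
    if (!(s %in% stems) && !(paste0(s, "e") %in% stems)) stems <- c(stems, s)
  }
  e <- data.frame(
    form = c(stems, paste0(stems, "e")),
    lemma = rep(stems, 2),
    case = "nominative",
    number = rep(c("singular", "plural"), each = nLemmas),
    gender = "m",
    frequency = rep(sample(1:50, nLemmas, replace = TRUE), 2),
    stringsAsFactors = FALSE)
  Lexicon(e, source = "separable fixture")
}

# noise-free semantic space over a lexicon, for exact-arithmetic tests
exactSpace <- function(lex, d = 30, seed = 5, featureScale = 1) {
  simulateSemanticSpace(unique(entries(lex)$lemma), semanticFeatures(lex),
                        d = d, sdNoise = 0, featureScale = featureScale,
                        seed = seed)
}

# build a SplitResult that puts everything in train except the given
# validation indices (categories recomputed exactly as the splitter does)
manualSplit <- function(lex, valIdx = integer(0)) {
  n <- length(lex)
  trainLex <- subsetLexicon(lex, setdiff(seq_len(n), valIdx))
  valLex <- subsetLexicon(lex, valIdx)
  tv <- entries(trainLex); vv <- entries(valLex)
  isH <- vv$form %in% tv$form
  known <- vv$lemma %in% tv$lemma
  new("SplitResult", train = trainLex, validation = valLex,
      valHomophones = which(isH), valNewforms = which(!isH & known),
      excludedNovelLemmas = which(!isH & !known),
      mode = "random", seed = 0L)
}

# end-state comprehension/production models for a training lexicon
fitEndstate <- function(trainLex, unit = "phone", n = 3, d = 40, seed = 5,
                        sdNoise = 0) {
  cm <- buildCueMatrix(trainLex, unit = unit, n = n)
  inv <- cueInventory(cm)
  space <- simulateSemanticSpace(unique(entries(trainLex)$lemma),
                                 semanticFeatures(trainLex), d = d,
                                 sdNoise = sdNoise, seed = seed)
  S <- buildSemanticMatrix(trainLex, space, seed = seed)
  list(cm = cm, inv = inv, space = space, S = S,
       Fmap = estimateEndstate(cm, S, "comprehension"),
       G = estimateEndstate(S, cm, "production"),
       paths = lapply(entries(trainLex)$form,
                      function(f) match(cuePath(f, inv), cues(inv))))
}
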