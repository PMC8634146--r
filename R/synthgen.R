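#' Specification for the synthetic paradigm-lexicon generator
#'
#' The generator emulates the structural properties of the German noun
#' system that drive the modeling results: five declension classes with the
#' corpus-derived type-frequency mix (-en 56.5\%, -e 23.9\%, -er 2.3\%,
#' zero 13.3\%, -s 2.6\%), optional stem-vowel fronting, heavy
#' within-paradigm homophony (nominative/dative/accusative singular
#' identical; masculine/neuter genitive singular adds -s; feminine
#' singulars all identical; nominative/genitive/accusative plural
#' identical; dative plural adds -n unless the plural already ends in n or
#' s), Zipf-distributed token frequencies shared by all cells that realize
#' the same form, a gender distribution, and CV-maximal-onset
#' syllabification so syllable cues are testable.
#'
#' @param nLemmas number of lemmas.
#' @param vowels,consonants the phone alphabet.
#' @param stemLengthRange min/max stem length (alternating CVC... pattern).
#' @param classes data.frame with columns class, suffix, umlautProb, prob
#'   (probabilities sum to 1); default mirrors the five-class system above.
#' @param genderProbs named numeric (m, f, n) summing to 1.
#' @param zipfExponent exponent a of the frequency law P(f = k) ~ k^-a.
#' @param maxFrequency frequency support 1..maxFrequency.
#' @param stems optional explicit stems (length nLemmas) instead of random
#'   ones.
#' @param seed integer seed.
#' @return a list of class "GeneratorSpec".
#' @export
generatorSpec <- function(nLemmas = 50L,
                          vowels = c("a", "e", "i", "o", "u"),
                          consonants = c("b", "d", "f", "g", "k", "l", "m",
                                         "n", "p", "r", "s", "t", "v", "z"),
                          stemLengthRange = c(3L, 5L),
                          classes = data.frame(
                            class = c("en", "e", "er", "zero", "s"),
                            suffix = c("en", "e", "er", "", "s"),
                            umlautProb = c(0, 0.5, 0.5, 0.5, 0),
                            prob = c(0.565, 0.239, 0.023, 0.133, 0.026),
                            stringsAsFactors = FALSE),
                          genderProbs = c(m = 0.35, f = 0.45, n = 0.20),
                          zipfExponent = 1,
                          maxFrequency = 1000L,
                          stems = NULL,
                          seed = 1L) {
  stopifnot(all(classes$prob > 0), abs(sum(genderProbs) - 1) < 1e-8,
            stemLengthRange[1] >= 2)
  # published class type-frequencies omit minor classes; renormalize
  classes$prob <- classes$prob / sum(classes$prob)
  if (!is.null(stems) && length(stems) != nLemmas)
    stop("stems must have length nLemmas")
  structure(list(nLemmas = as.integer(nLemmas), vowels = vowels,
                 consonants = consonants,
                 stemLengthRange = as.integer(stemLengthRange),
                 classes = classes, genderProbs = genderProbs,
                 zipfExponent = zipfExponent,
                 maxFrequency = as.integer(maxFrequency),
                 stems = stems,
                 seed = as.integer(seed)),
            class = "GeneratorSpec")
}

# fronting map for the stem-vowel change (every vowel maps to a different one)
.UMLAUT <- c(a = "e", o = "e", u = "i", e = "i", i = "e")

.applyUmlaut <- function(stem, vowels) {
  chars <- strsplit(stem, "")[[1]]
  vpos <- which(chars %in% vowels)
  if (length(vpos) == 0) return(stem)
  p <- vpos[length(vpos)]
  if (!chars[p] %in% names(.UMLAUT)) return(stem)
  chars[p] <- .UMLAUT[[chars[p]]]
  paste(chars, collapse = "")
}

# CV syllabification with maximal onsets: consonants between vowels attach
# to the following vowel; trailing consonants close the last syllable
.syllabify <- function(form, vowels) {
  chars <- strsplit(form, "")[[1]]
  isV <- chars %in% vowels
  if (!any(isV)) return(form)
  vpos <- which(isV)
  starts <- c(1L, vpos[-length(vpos)] + 1L)
  ends <- c(vpos[-length(vpos)], length(chars))
  vapply(seq_along(starts), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
}

.zipfSample <- function(n, exponent, maxFrequency) {
  p <- (1:maxFrequency)^(-exponent)
  sample.int(maxFrequency, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic German-like paradigm lexicon
#'
#' Every lemma receives a full eight-cell paradigm (4 cases x 2 numbers)
#' laid out by the homophony template of its gender and declension class
#' (see \code{\link{generatorSpec}}). Cells realizing the same surface form
#' share one Zipf-drawn token frequency. Ground truth (class and umlaut per
#' lemma, per-lemma homophone groups) is returned for oracle tests.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @return list with \code{lexicon} (a \linkS4class{Lexicon}),
#'   \code{classes} (data.frame lemma/class/umlaut/gender) and
#'   \code{homophoneGroups} (named list of entry indices by surface form).
#' @export
generateToyLexicon <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nLemmas
  if (n == 0)
    return(list(lexicon = Lexicon(), classes = data.frame(),
                homophoneGroups = list()))
  lens <- sample(seq(spec$stemLengthRange[1], spec$stemLengthRange[2]),
                 n, replace = TRUE)
  nc <- length(spec$consonants); nv <- length(spec$vowels)
  capacity <- sum(vapply(seq(spec$stemLengthRange[1], spec$stemLengthRange[2]),
                         function(L) prod(ifelse(seq_len(L) %% 2 == 1, nc, nv)),
                         numeric(1)))
  if (is.null(spec$stems) && n > capacity)
    stop("alphabet too small for ", n, " distinct stems (capacity ", capacity, ")")
  mkStems <- function(lens) vapply(lens, function(len)
    # alternating CVCV... so stems are pronounceable and syllabifiable
    paste(vapply(seq_len(len), function(i)
      sample(if (i %% 2 == 1) spec$consonants else spec$vowels, 1),
      character(1)), collapse = ""), character(1))
  if (is.null(spec$stems)) {
    stems <- mkStems(lens)
    for (round in 1:200) {
      dup <- which(duplicated(stems))
      if (length(dup) == 0) break
      # resample lengths too: a single length class may be exhausted
      lens[dup] <- sample(seq(spec$stemLengthRange[1], spec$stemLengthRange[2]),
                          length(dup), replace = TRUE)
      stems[dup] <- mkStems(lens[dup])
      if (round == 200) stop("alphabet too small for requested distinct stems")
    }
  } else {
    stems <- as.character(spec$stems)
    if (anyDuplicated(stems)) stop("explicit stems must be distinct")
  }
  cls <- sample(spec$classes$class, n, replace = TRUE,
                prob = spec$classes$prob)
  umlProb <- spec$classes$umlautProb[match(cls, spec$classes$class)]
  uml <- stats::runif(n) < umlProb
  gender <- sample(names(spec$genderProbs), n, replace = TRUE,
                   prob = spec$genderProbs)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    stem <- stems[i]
    suffix <- spec$classes$suffix[spec$classes$class == cls[i]]
    plBase <- paste0(if (uml[i]) .applyUmlaut(stem, spec$vowels) else stem,
                     suffix)
    genSg <- if (gender[i] == "f") stem else paste0(stem, "s")
    datPl <- if (grepl("[ns]$", plBase)) plBase else paste0(plBase, "n")
    cells <- data.frame(
      case = rep(.CASES, 2),
      number = rep(.NUMBERS, each = 4),
      form = c(stem, genSg, stem, stem, plBase, plBase, datPl, plBase),
      stringsAsFactors = FALSE)
    freqs <- .zipfSample(length(unique(cells$form)), spec$zipfExponent,
                         spec$maxFrequency)
    names(freqs) <- unique(cells$form)
    cells$frequency <- as.integer(freqs[cells$form])
    cells$lemma <- stem
    cells$gender <- gender[i]
    cells$syllables <- vapply(cells$form, function(f)
      paste(.syllabify(f, spec$vowels), collapse = "."), character(1))
    rows[[i]] <- cells
  }
  lex <- Lexicon(do.call(rbind, rows), source = "synthetic paradigm generator")
  list(lexicon = lex,
       classes = data.frame(lemma = stems, class = cls, umlaut = uml,
                            gender = gender, stringsAsFactors = FALSE),
       homophoneGroups = findHomophones(lex))
}

#' Generate nonce (wug) forms rhyming with a lexicon
#'
#' Each nonce shares its final \code{rhymeLength} symbols with at least one
#' form of the lexicon but is itself absent from the lexicon (nonce forms
#' with existing rhymes keep most of their cues trainable).
#'
#' @param spec a \code{\link{generatorSpec}} (alphabet source).
#' @param n number of nonces.
#' @param rhymeWith a non-empty \linkS4class{Lexicon}.
#' @param rhymeLength number of shared final symbols (default 2).
#' @param seed integer seed.
#' @return character vector of nonce forms.
#' @export
generateWugNonces <- function(spec, n, rhymeWith, rhymeLength = 2L,
                              seed = 1L) {
  if (n == 0) return(character(0))
  forms <- unique(entries(rhymeWith)$form)
  if (length(forms) == 0) stop("rhymeWith lexicon is empty")
  set.seed(seed)
  pool <- forms[nchar(forms) >= rhymeLength + 1]
  if (length(pool) == 0) stop("no forms long enough to rhyme with")
  out <- character(0)
  # swap the onset consonant of an attested form, keeping its whole rhyme,
  # so the nonce matches the lexicon's phonotactics
  for (tries in 1:(1000 * n)) {
    base <- sample(pool, 1)
    onset <- sample(setdiff(spec$consonants, substring(base, 1, 1)), 1)
    nonce <- paste0(onset, substring(base, 2))
    if (!(nonce %in% forms) && !(nonce %in% out)) out <- c(out, nonce)
    if (length(out) == n) return(out)
  }
  stop("could not satisfy the rhyme constraint for ", n, " nonces")
}
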