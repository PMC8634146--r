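#' Default German definite and indefinite article map
#'
#' One article string per (gender, case, number, definiteness) combination,
#' in plain orthographic transcription (replace the article column to use a
#' phonological transcription). Indefinite articles exist only in the
#' singular; indefinite plurals are bare and are handled by
#' \code{\link{attachArticles}} directly.
#'
#' @return data.frame with columns gender, case, number, definiteness, article.
#' @export
germanArticles <- function() {
  sg <- expand.grid(gender = .GENDERS, case = .CASES,
                    stringsAsFactors = FALSE)
  defSg <- c(m.nominative = "der", m.genitive = "des", m.dative = "dem",
             m.accusative = "den",
             n.nominative = "das", n.genitive = "des", n.dative = "dem",
             n.accusative = "das",
             f.nominative = "die", f.genitive = "der", f.dative = "der",
             f.accusative = "die")
  defPl <- c(nominative = "die", genitive = "der", dative = "den",
             accusative = "die")
  indefSg <- c(m.nominative = "ein", m.genitive = "eines", m.dative = "einem",
               m.accusative = "einen",
               n.nominative = "ein", n.genitive = "eines", n.dative = "einem",
               n.accusative = "ein",
               f.nominative = "eine", f.genitive = "einer", f.dative = "einer",
               f.accusative = "eine")
  key <- paste(sg$gender, sg$case, sep = ".")
  rbind(
    data.frame(sg, number = "singular", definiteness = "definite",
               article = unname(defSg[key]), stringsAsFactors = FALSE),
    data.frame(sg, number = "plural", definiteness = "definite",
               article = unname(defPl[sg$case]), stringsAsFactors = FALSE),
    data.frame(sg, number = "singular", definiteness = "indefinite",
               article = unname(indefSg[key]), stringsAsFactors = FALSE)
  )
}

#' Prefix article forms onto noun forms
#'
#' Concatenates the article directly onto the form with no separator (as in
#' auditory input, where no pause separates article and noun). Under
#' \code{definite_and_indefinite} every entry is emitted twice, once definite
#' and once indefinite; indefinite plurals carry an empty article (the bare
#' form), since indefinite articles are restricted to the singular.
#'
#' @param lex a \linkS4class{Lexicon}; every entry needs a gender.
#' @param articleMap data.frame as returned by \code{\link{germanArticles}}.
#' @param mode "definite_only" or "definite_and_indefinite".
#' @return a new \linkS4class{Lexicon} with article-prefixed forms, the
#'   article and definiteness columns filled in.
#' @export
attachArticles <- function(lex, articleMap = germanArticles(),
                           mode = c("definite_only", "definite_and_indefinite")) {
  mode <- match.arg(mode)
  e <- entries(lex)
  if (nrow(e) == 0) return(lex)
  noGender <- is.na(e$gender) | !(e$gender %in% .GENDERS)
  if (any(noGender))
    stop("gender missing for lemma(s): ",
         paste(unique(e$lemma[noGender]), collapse = ", "))
  mapKey <- paste(articleMap$gender, articleMap$case, articleMap$number,
                  articleMap$definiteness, sep = ".")
  lookup <- function(rows, definiteness) {
    key <- paste(rows$gender, rows$case, rows$number, definiteness, sep = ".")
    art <- articleMap$article[match(key, mapKey)]
    bare <- is.na(art) & definiteness == "indefinite" & rows$number == "plural"
    art[bare] <- ""
    if (anyNA(art))
      stop("article map lacks key(s): ",
           paste(unique(key[is.na(art)]), collapse = ", "))
    art
  }
  apply1 <- function(rows, definiteness) {
    art <- lookup(rows, definiteness)
    rows$article <- art
    rows$form <- paste0(art, rows$form)
    rows$definiteness <- definiteness
    hasSyl <- !is.na(rows$syllables) & nzchar(art)
    rows$syllables[hasSyl] <- paste(art[hasSyl], rows$syllables[hasSyl],
                                    sep = ".")
    rows
  }
  out <- if (mode == "definite_only") apply1(e, "definite") else
    rbind(apply1(e, "definite"), apply1(e, "indefinite"))
  Lexicon(out, source = lex@source)
}

#' Group lexicon entries by surface form
#'
#' @param lex a \linkS4class{Lexicon}.
#' @return named list (one element per distinct form, in first-occurrence
#'   order) of integer entry indices sharing that exact form string. When
#'   articles are attached the article is part of the form and hence of the
#'   homophone key.
#' @export
findHomophones <- function(lex) {
  forms <- entries(lex)$form
  split(seq_along(forms), factor(forms, levels = unique(forms)))
}

#' Split a lexicon into training and validation data
#'
#' Under \code{mode = "no_novel_cues"} the validation set is adjusted so that
#' every cue of every validation form already occurs in some training form:
#' validation candidates are visited rarest-cue-first and moved into training
#' whenever one of their cues is not yet covered. Validation entries are then
#' partitioned into homophones (form also in training), new forms (unseen
#' form, lemma known) and excluded novel lemmas.
#'
#' @param lex a \linkS4class{Lexicon}.
#' @param trainFraction proportion of entries assigned to training (0 < f < 1).
#' @param mode "random" or "no_novel_cues".
#' @param cueExtractor function(form) -> character vector of cues; required
#'   under "no_novel_cues" (e.g. \code{function(f) extractNgramCues(f, 3)}).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return a \linkS4class{SplitResult}.
#' @export
splitTrainValidation <- function(lex, trainFraction = 0.8,
                                 mode = c("random", "no_novel_cues"),
                                 cueExtractor = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(trainFraction > 0, trainFraction < 1)
  e <- entries(lex)
  n <- nrow(e)
  if (n < 2) stop("need at least 2 entries to split")
  if (mode == "no_novel_cues" && is.null(cueExtractor))
    stop("no_novel_cues mode requires a cueExtractor")
  set.seed(seed)
  perm <- sample.int(n)
  nTrain <- round(trainFraction * n)
  nTrain <- max(1L, min(n - 1L, nTrain))
  trainIdx <- perm[seq_len(nTrain)]
  valIdx <- perm[-seq_len(nTrain)]

  if (mode == "no_novel_cues") {
    cueList <- lapply(e$form, cueExtractor)
    cueCount <- table(unlist(lapply(cueList, unique)))
    trainCues <- unique(unlist(cueList[trainIdx]))
    # rarest-cue-first: forms whose rarest cue is least frequent go first, so
    # forcing them into training covers later forms and minimizes moves
    rarity <- vapply(valIdx, function(i) min(cueCount[cueList[[i]]]), numeric(1))
    moved <- integer(0)
    for (i in valIdx[order(rarity)]) {
      if (!all(cueList[[i]] %in% trainCues)) {
        moved <- c(moved, i)
        trainCues <- union(trainCues, cueList[[i]])
      }
    }
    if (length(moved) > 0) {
      message(length(moved),
              " validation candidate(s) forced into training to avoid novel cues")
      trainIdx <- c(trainIdx, moved)
      valIdx <- setdiff(valIdx, moved)
      if (length(valIdx) == 0) stop("no validation entries left after forcing")
    }
  }

  trainLex <- subsetLexicon(lex, sort(trainIdx))
  valLex <- subsetLexicon(lex, sort(valIdx))
  tv <- entries(trainLex)
  vv <- entries(valLex)
  isHomophone <- vv$form %in% tv$form
  lemmaKnown <- vv$lemma %in% tv$lemma
  new("SplitResult", train = trainLex, validation = valLex,
      valHomophones = which(isHomophone),
      valNewforms = which(!isHomophone & lemmaKnown),
      excludedNovelLemmas = which(!isHomophone & !lemmaKnown),
      mode = mode, seed = as.integer(seed))
}

#' Semantic-role probabilities per case
#'
#' The default table assigns the most prominent semantic roles to each case:
#' nominative realizes agent (50\%), theme (40\%) and patient (10\%);
#' genitive possessive (90\%) and partitive (10\%); dative beneficiary and
#' location (50\% each); accusative patient (40\%), motion (30\%) and
#' experiencer (30\%).
#'
#' @return data.frame with columns case, role, probability; probabilities sum
#'   to 1 within each case.
#' @export
defaultRoleTable <- function() {
  data.frame(
    case = c(rep("nominative", 3), rep("genitive", 2), rep("dative", 2),
             rep("accusative", 3)),
    role = c("agent", "theme", "patient",
             "possessive", "partitive",
             "beneficiary", "location",
             "patient", "motion", "experiencer"),
    probability = c(0.5, 0.4, 0.1, 0.9, 0.1, 0.5, 0.5, 0.4, 0.3, 0.3),
    stringsAsFactors = FALSE)
}

.checkRoleTable <- function(roles) {
  stopifnot(all(c("case", "role", "probability") %in% names(roles)))
  sums <- tapply(roles$probability, roles$case, sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("role probabilities must sum to 1 within each case")
  invisible(roles)
}

#' Expand each entry into one entry per semantic role
#'
#' Deterministic cross-product: an entry whose case lists K roles becomes K
#' entries, one per role, each initially keeping the parent form frequency
#' (role-level frequencies are simulated separately with
#' \code{\link{simulateRoleFrequencies}}).
#'
#' @param lex a \linkS4class{Lexicon} without roles.
#' @param roles role table as from \code{\link{defaultRoleTable}}.
#' @return role-expanded \linkS4class{Lexicon}.
#' @export
expandRoles <- function(lex, roles = defaultRoleTable()) {
  .checkRoleTable(roles)
  e <- entries(lex)
  unknown <- setdiff(unique(e$case), unique(roles$case))
  if (length(unknown) > 0)
    stop("case(s) missing from role table: ", paste(unknown, collapse = ", "))
  byCase <- split(roles$role, roles$case)
  k <- lengths(byCase)[e$case]
  out <- e[rep(seq_len(nrow(e)), k), , drop = FALSE]
  out$role <- unlist(byCase[e$case], use.names = FALSE)
  Lexicon(out, source = lex@source)
}

#' Simulate role-level token frequencies
#'
#' Each (form, lemma, case, number, definiteness) paradigm cell receives an
#' equal share freq_p of its form's token frequency, freq_p = form frequency
#' divided by the number of cells realizing that exact form string. Within a
#' cell, each of its K roles is independently dropped with probability 1/K
#' (so on average one role per cell is omitted); the surviving roles share
#' freq_p proportionally to their renormalized probabilities, rounded up to
#' the nearest integer. Dropped roles get frequency 0.
#'
#' @param lex a role-expanded \linkS4class{Lexicon} (see
#'   \code{\link{expandRoles}}).
#' @param roles role table used for the expansion.
#' @param seed integer seed for the drop draws.
#' @param drops optional logical vector (one element per entry, in entry
#'   order): TRUE drops that entry's role. Overrides the random draws; used
#'   to replay a known drop pattern.
#' @return a \linkS4class{Lexicon} whose \code{frequency} column holds the
#'   role-level frequencies; the parent form frequency is kept in a
#'   \code{form_frequency} column.
#' @export
simulateRoleFrequencies <- function(lex, roles = defaultRoleTable(), seed = 1L,
                                    drops = NULL) {
  .checkRoleTable(roles)
  e <- entries(lex)
  if (any(is.na(e$role))) stop("lexicon is not role-expanded")
  probKey <- paste(roles$case, roles$role, sep = ".")
  prob <- roles$probability[match(paste(e$case, e$role, sep = "."), probKey)]
  if (anyNA(prob)) stop("entry role not found in role table")

  cellKey <- paste(e$form, e$lemma, e$case, e$number, e$definiteness,
                   sep = "\r")
  # cells realizing a form: distinct cells sharing the exact surface string
  cellOfForm <- !duplicated(cellKey)
  nCellsPerForm <- table(e$form[cellOfForm])
  freqP <- e$frequency / as.numeric(nCellsPerForm[e$form])

  if (is.null(drops)) {
    set.seed(seed)
    cellF <- factor(cellKey, levels = unique(cellKey))
    k <- as.numeric(table(cellF)[cellF])
    drops <- stats::rbinom(nrow(e), 1L, 1 / k) == 1L
  } else {
    stopifnot(length(drops) == nrow(e))
    cellF <- factor(cellKey, levels = unique(cellKey))
  }

  survProb <- ifelse(drops, 0, prob)
  survSum <- stats::ave(survProb, cellF, FUN = sum)
  newFreq <- integer(nrow(e))
  ok <- !drops & survSum > 0
  newFreq[ok] <- as.integer(ceiling(freqP[ok] * survProb[ok] / survSum[ok]))
  allDropped <- tapply(drops, cellF, all)
  if (any(allDropped))
    message(sum(allDropped), " cell(s) had every role dropped (frequency 0)")

  e$form_frequency <- e$frequency
  e$frequency <- newFreq
  Lexicon(e, source = lex@source)
}
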