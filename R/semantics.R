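.FEATURE <- function(x) toupper(x)

#' Inflectional feature labels needed for a lexicon
#'
#' Number values always get a feature; case labels are replaced by semantic
#' roles when roles are present (or when \code{useRoles = TRUE}); DEFINITE /
#' INDEFINITE are added when the definiteness column is populated.
#'
#' @param lex a \linkS4class{Lexicon}.
#' @param useRoles use the role column instead of case labels.
#' @return character vector of (uppercase) feature labels.
#' @export
semanticFeatures <- function(lex, useRoles = !all(is.na(entries(lex)$role))) {
  e <- entries(lex)
  feats <- .FEATURE(unique(e$number))
  feats <- c(feats,
             .FEATURE(unique(if (useRoles) e$role else e$case)))
  if (!all(is.na(e$definiteness)))
    feats <- c(feats, .FEATURE(unique(stats::na.omit(e$definiteness))))
  unique(feats)
}

#' Simulate a Gaussian semantic space
#'
#' Lexeme vectors are drawn i.i.d. Normal(0, sdLexeme^2) per dimension, and
#' inflectional feature vectors Normal(0, (sdFeature * featureScale)^2).
#' With the default sd of 4 for both, inflected words' vectors are
#' numerically dominated by their inflectional features; a small
#' featureScale (e.g. 1/110) shrinks the feature vectors so that the lexeme
#' dominates, which matters for nonce-word production. Simulated lexeme
#' vectors are pairwise near-orthogonal in high dimensions.
#'
#' @param lemmas character vector of lemma identifiers.
#' @param features character vector of feature labels (see
#'   \code{\link{semanticFeatures}}).
#' @param d dimensionality (conventionally set to the number of cues).
#' @param sdLexeme,sdFeature standard deviations (defaults 4).
#' @param sdNoise sd of the per-entry noise added at composition time
#'   (default 1); stored here so composition can read it.
#' @param featureScale multiplier on sdFeature (default 1).
#' @param seed integer seed; the space is reproducible from it.
#' @return a \linkS4class{SemanticSpace}.
#' @export
simulateSemanticSpace <- function(lemmas, features, d,
                                  sdLexeme = 4, sdFeature = 4, sdNoise = 1,
                                  featureScale = 1, seed = 1L) {
  stopifnot(d >= 1)
  d <- as.integer(d)
  features <- .FEATURE(features)
  set.seed(seed)
  lx <- matrix(stats::rnorm(length(lemmas) * d, 0, sdLexeme),
               nrow = length(lemmas), ncol = d,
               dimnames = list(lemmas, NULL))
  fx <- matrix(stats::rnorm(length(features) * d, 0, sdFeature * featureScale),
               nrow = length(features), ncol = d,
               dimnames = list(features, NULL))
  new("SemanticSpace", d = d, lexemeVectors = lx, featureVectors = fx,
      params = list(sdLexeme = sdLexeme, sdFeature = sdFeature,
                    sdNoise = sdNoise, featureScale = featureScale,
                    seed = as.integer(seed)))
}

.entryFeatures <- function(entry, numberCoding, useRoles) {
  feats <- character(0)
  if (!(numberCoding == "privative" && entry$number == "singular"))
    feats <- c(feats, entry$number)
  feats <- c(feats, if (useRoles && !is.na(entry$role)) entry$role else entry$case)
  if (!is.na(entry$definiteness)) feats <- c(feats, entry$definiteness)
  .FEATURE(feats)
}

#' Compose the semantic vector of one inflected word
#'
#' vector = lexeme + number vector (omitted for singulars under privative
#' coding) + case-or-role vector + optional definiteness vector + Gaussian
#' noise with sd \code{sdNoise} from the space parameters. Noise is drawn
#' once per call; pass \code{noiseSeed} for reproducibility or set the
#' space's sdNoise to 0 for exact additivity.
#'
#' @param entry a single-row data.frame (or list) with lemma, number, case
#'   and optional role / definiteness fields.
#' @param space a \linkS4class{SemanticSpace}.
#' @param numberCoding "equipollent" (both numbers marked) or "privative"
#'   (singular unmarked).
#' @param noiseSeed optional integer seed for the noise draw.
#' @return numeric vector of length d.
#' @export
composeMeaning <- function(entry, space,
                           numberCoding = c("equipollent", "privative"),
                           noiseSeed = NULL) {
  numberCoding <- match.arg(numberCoding)
  entry <- as.list(entry)
  for (f in c("role", "definiteness"))
    if (is.null(entry[[f]])) entry[[f]] <- NA_character_
  if (!entry$lemma %in% rownames(space@lexemeVectors))
    stop("unknown lexeme: ", entry$lemma)
  feats <- .entryFeatures(entry, numberCoding,
                          useRoles = !is.na(entry$role))
  missing <- setdiff(feats, rownames(space@featureVectors))
  if (length(missing) > 0)
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  v <- space@lexemeVectors[entry$lemma, ]
  for (f in feats) v <- v + space@featureVectors[f, ]
  sdNoise <- space@params$sdNoise
  if (sdNoise > 0) {
    if (!is.null(noiseSeed)) set.seed(noiseSeed)
    v <- v + stats::rnorm(space@d, 0, sdNoise)
  }
  unname(v)
}

#' Build the semantic matrix S for a lexicon
#'
#' Row i is the composed meaning of entry i; noise is drawn independently
#' per entry (deterministically from \code{seed}), so homophonous entries in
#' different paradigm cells still receive distinct vectors.
#'
#' @param lex a \linkS4class{Lexicon}.
#' @param space a \linkS4class{SemanticSpace}.
#' @param numberCoding see \code{\link{composeMeaning}}.
#' @param seed integer seed for the noise draws.
#' @return a \linkS4class{SemanticMatrix}.
#' @export
buildSemanticMatrix <- function(lex, space,
                                numberCoding = c("equipollent", "privative"),
                                seed = 1L) {
  numberCoding <- match.arg(numberCoding)
  e <- entries(lex)
  n <- nrow(e)
  useRoles <- !all(is.na(e$role))
  vals <- matrix(0, nrow = n, ncol = space@d)
  badLemma <- setdiff(unique(e$lemma), rownames(space@lexemeVectors))
  if (length(badLemma) > 0)
    stop("unknown lexeme(s): ", paste(utils::head(badLemma, 5), collapse = ", "))
  if (n > 0) {
    vals <- space@lexemeVectors[e$lemma, , drop = FALSE]
    featList <- lapply(seq_len(n), function(i)
      .entryFeatures(e[i, ], numberCoding, useRoles))
    missing <- setdiff(unique(unlist(featList)), rownames(space@featureVectors))
    if (length(missing) > 0)
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    for (i in seq_len(n))
      for (f in featList[[i]])
        vals[i, ] <- vals[i, ] + space@featureVectors[f, ]
    if (space@params$sdNoise > 0) {
      set.seed(seed)
      vals <- vals + matrix(stats::rnorm(n * space@d, 0, space@params$sdNoise),
                            nrow = n)
    }
  }
  dimnames(vals) <- NULL
  new("SemanticMatrix", values = as.matrix(vals), rowKeys = seq_len(n))
}

#' Load word2vec-format embeddings for a lexicon
#'
#' Reads word2vec text format ("word v1 v2 ..." lines, with or without the
#' "count dim" header; plain or gzip). Each entry is looked up by its
#' surface form, so every set of homophones receives the identical vector.
#' Entries whose form is absent from the file are dropped with a warning.
#'
#' @param path path to the embeddings file.
#' @param lex a \linkS4class{Lexicon}.
#' @return list with \code{matrix} (a \linkS4class{SemanticMatrix} over the
#'   covered entries; \code{rowKeys()} maps rows back to lexicon indices),
#'   and \code{missing} (character vector of uncovered forms).
#' @export
loadEmbeddings <- function(path, lex) {
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) stop("empty embeddings file")
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[`, character(1), 1)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  d <- unique(lengths(vecs))
  if (length(d) != 1) stop("inconsistent embedding dimensions")
  emb <- do.call(rbind, vecs)
  rownames(emb) <- words

  e <- entries(lex)
  hit <- e$form %in% words
  if (!all(hit))
    warning(sum(!hit), " entr(ies) dropped: form not in embeddings (",
            paste(utils::head(unique(e$form[!hit]), 5), collapse = ", "), ")")
  keep <- which(hit)
  vals <- emb[e$form[keep], , drop = FALSE]
  dimnames(vals) <- NULL
  list(matrix = new("SemanticMatrix", values = vals, rowKeys = keep),
       missing = unique(e$form[!hit]), d = d)
}

#' Reconstruct lexeme and feature vectors from embeddings
#'
#' A lexeme vector is the mean over that lemma's entry vectors; each
#' inflectional feature vector is the mean over the entry vectors carrying
#' the feature (each entry counts once). A paradigm cell is then
#' reconstructed as lexeme + number + case, and the per-entry Pearson
#' correlation between reconstruction and original vector measures how
#' compositional the embeddings are.
#'
#' @param embeddings a \linkS4class{SemanticMatrix} (e.g. from
#'   \code{\link{loadEmbeddings}}) whose rowKeys index \code{lex}.
#' @param lex the \linkS4class{Lexicon}.
#' @return list with \code{space} (an analytical \linkS4class{SemanticSpace}
#'   with sdNoise = 0), \code{reconstructed} (matrix of reconstructed entry
#'   vectors), \code{r} (per-entry Pearson correlations) and \code{meanR}.
#' @export
deriveAnalyticalVectors <- function(embeddings, lex) {
  e <- entries(lex)[rowKeys(embeddings), , drop = FALSE]
  V <- as.matrix(embeddings)
  d <- ncol(V)
  groupMean <- function(f) {
    idx <- split(seq_len(nrow(V)), f)
    out <- matrix(0, nrow = length(idx), ncol = d,
                  dimnames = list(names(idx), NULL))
    for (g in names(idx))
      out[g, ] <- colMeans(V[idx[[g]], , drop = FALSE])
    out
  }
  lx <- groupMean(e$lemma)
  feats <- .FEATURE(c(e$number, e$case))
  fx <- matrix(0, nrow = 0, ncol = d)
  for (f in unique(feats)) {
    carriers <- which(.FEATURE(e$number) == f | .FEATURE(e$case) == f)
    row <- if (length(carriers) > 0)
      colMeans(V[carriers, , drop = FALSE])
    else {
      warning("feature without carriers: ", f)
      numeric(d)
    }
    fx <- rbind(fx, row)
    rownames(fx)[nrow(fx)] <- f
  }
  recon <- lx[e$lemma, , drop = FALSE] +
    fx[.FEATURE(e$number), , drop = FALSE] +
    fx[.FEATURE(e$case), , drop = FALSE]
  r <- vapply(seq_len(nrow(V)),
              function(i) .safeCor(recon[i, ], V[i, ]), numeric(1))
  space <- new("SemanticSpace", d = as.integer(d),
               lexemeVectors = lx, featureVectors = fx,
               params = list(sdLexeme = NA_real_, sdFeature = NA_real_,
                             sdNoise = 0, featureScale = 1, seed = NA_integer_))
  list(space = space, reconstructed = unname(recon), r = r, meanR = mean(r))
}

#' Write / read a semantic space as delimited text
#'
#' One line per vector: a LEXEME/FEATURE tag, the label, then d floats,
#' tab-separated; parameters on a leading comment line.
#'
#' @param space a \linkS4class{SemanticSpace}.
#' @param path file path.
#' @export
writeSemanticSpace <- function(space, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  p <- space@params
  writeLines(sprintf("# d=%d sdLexeme=%s sdFeature=%s sdNoise=%s featureScale=%s seed=%s",
                     space@d, p$sdLexeme, p$sdFeature, p$sdNoise,
                     p$featureScale, p$seed), con)
  emit <- function(tag, m) {
    for (nm in rownames(m))
      writeLines(paste(c(tag, nm, formatC(m[nm, ], format = "g", digits = 17)),
                       collapse = "\t"), con)
  }
  emit("LEXEME", space@lexemeVectors)
  emit("FEATURE", space@featureVectors)
  invisible(path)
}

#' @rdname writeSemanticSpace
#' @export
readSemanticSpace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[1]
  kv <- regmatches(hdr, gregexpr("[A-Za-z]+=[^ ]+", hdr))[[1]]
  params <- as.list(vapply(kv, function(x) sub("^[A-Za-z]+=", "", x), character(1)))
  names(params) <- vapply(kv, function(x) sub("=.*$", "", x), character(1))
  num <- function(x) suppressWarnings(as.numeric(x))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  tag <- vapply(body, `[`, character(1), 1)
  lab <- vapply(body, `[`, character(1), 2)
  vec <- lapply(body, function(p) as.numeric(p[-(1:2)]))
  toM <- function(sel) {
    if (!any(sel)) return(matrix(0, 0, as.integer(num(params$d))))
    m <- do.call(rbind, vec[sel]); rownames(m) <- lab[sel]; m
  }
  new("SemanticSpace", d = as.integer(num(params$d)),
      lexemeVectors = toM(tag == "LEXEME"),
      featureVectors = toM(tag == "FEATURE"),
      params = list(sdLexeme = num(params$sdLexeme),
                    sdFeature = num(params$sdFeature),
                    sdNoise = num(params$sdNoise),
                    featureScale = num(params$featureScale),
                    seed = as.integer(num(params$seed))))
}
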