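#' Predict semantic vectors from cue vectors
#'
#' Shat = C F: the matrix product of cue rows with the comprehension
#' mapping, rows aligned with the input rows.
#'
#' @param C cue rows (matrix or \linkS4class{CueMatrix}).
#' @param F a comprehension \linkS4class{LinearMapping}.
#' @return numeric matrix of predicted semantic vectors.
#' @export
predictSemantics <- function(C, F) {
  C <- .asDense(C)
  W <- mappingWeights(F)
  if (ncol(C) != nrow(W)) stop("dimension mismatch: ncol(C) != nrow(weights)")
  C %*% W
}

#' Nearest gold meaning by Pearson correlation
#'
#' Correlates a predicted semantic vector with every gold row and returns
#' the argmax (ties broken by lowest row index). A zero-variance vector has
#' r defined as 0 against every row.
#'
#' @param shat predicted semantic vector.
#' @param Sgold gold semantic matrix (all candidate rows).
#' @return list with \code{index}, \code{r} (correlation with the winner)
#'   and \code{ranking} (row indices in decreasing correlation order).
#' @export
nearestMeaning <- function(shat, Sgold) {
  Sgold <- .asDense(Sgold)
  if (nrow(Sgold) < 1) stop("need at least one gold row")
  rs <- drop(.rowCorMatrix(matrix(shat, nrow = 1), Sgold))
  best <- which.max(rs)   # ties: lowest index
  list(index = best, r = rs[best], ranking = order(rs, decreasing = TRUE))
}

# nearest-row indices and correlations for a block of predictions
.nearestAll <- function(Shat, Sgold) {
  rs <- .rowCorMatrix(Shat, Sgold)
  nearest <- max.col(rs, ties.method = "first")
  list(nearest = nearest,
       rNearest = rs[cbind(seq_len(nrow(rs)), nearest)],
       cor = rs)
}

#' Evaluate comprehension under the strict/lenient taxonomy
#'
#' Each evaluated entry's predicted vector is compared against the full gold
#' matrix (training and validation rows). Strict: the nearest gold row is
#' the entry's own row. Lenient: the nearest gold row belongs to any entry
#' sharing the entry's surface form. Reported accuracies: \code{train}
#' (lenient over training entries, with \code{train_strict} alongside),
#' \code{val_all} (lenient over every validation entry, novel lemmas
#' included), \code{val_lenient} (homophone subset), \code{val_newform}
#' (unseen-form subset), \code{val_strict} (strict over all validation).
#'
#' @param F comprehension \linkS4class{LinearMapping}.
#' @param Ctrain,Cval cue rows for training / validation entries.
#' @param SgoldTrain,SgoldVal gold semantic rows, aligned with the split's
#'   train and validation lexicons.
#' @param split a \linkS4class{SplitResult}.
#' @return list with \code{accuracies} (named numeric; NA for empty
#'   categories), \code{counts}, and \code{perEntry} (data.frame with
#'   per-entry nearest index, correlation with nearest and with target,
#'   target rank, strict/lenient flags and evaluation set).
#' @export
evaluateComprehension <- function(F, Ctrain, Cval, SgoldTrain, SgoldVal,
                                  split) {
  SgoldTrain <- .asDense(SgoldTrain); SgoldVal <- .asDense(SgoldVal)
  Sgold <- rbind(SgoldTrain, SgoldVal)
  nTrain <- nrow(SgoldTrain)
  forms <- c(entries(trainLexicon(split))$form,
             entries(validationLexicon(split))$form)

  scoreBlock <- function(C, ownGold) {
    if (length(ownGold) == 0)
      return(data.frame(nearest = integer(0), rNearest = numeric(0),
                        rTarget = numeric(0), rankTarget = integer(0),
                        strict = logical(0), lenient = logical(0)))
    Shat <- predictSemantics(C, F)
    nn <- .nearestAll(Shat, Sgold)
    own <- ownGold
    strict <- nn$nearest == own
    lenient <- forms[nn$nearest] == forms[own]
    rTarget <- nn$cor[cbind(seq_len(nrow(Shat)), own)]
    rankTarget <- vapply(seq_len(nrow(Shat)), function(i)
      sum(nn$cor[i, ] > rTarget[i]) + 1L, integer(1))
    data.frame(nearest = nn$nearest, rNearest = nn$rNearest,
               rTarget = rTarget, rankTarget = rankTarget,
               strict = strict, lenient = lenient)
  }

  perTrain <- scoreBlock(Ctrain, seq_len(nTrain))
  perVal <- scoreBlock(Cval, nTrain + seq_len(nrow(SgoldVal)))
  perTrain$set <- rep("train", nrow(perTrain))
  perVal$set <- rep("validation", nrow(perVal))

  acc <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  vh <- valHomophones(split); vn <- valNewforms(split)
  accuracies <- c(
    train = acc(perTrain$lenient),
    train_strict = acc(perTrain$strict),
    val_all = acc(perVal$lenient),
    val_lenient = acc(perVal$lenient[vh]),
    val_newform = acc(perVal$lenient[vn]),
    val_strict = acc(perVal$strict))
  counts <- c(train = nrow(perTrain), val_all = nrow(perVal),
              val_lenient = length(vh), val_newform = length(vn),
              excluded_novel_lemmas = length(excludedNovelLemmas(split)))
  list(accuracies = accuracies, counts = counts,
       perEntry = rbind(perTrain, perVal))
}
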