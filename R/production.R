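#' Production configuration
#'
#' @param supportThreshold theta: minimum predicted semantic support a cue
#'   needs to enter the path search (\code{-Inf} admits every cue).
#' @param topK cues retained per position in positional mode.
#' @param tolerance t: maximum number of sub-threshold cues allowed per path
#'   (default 0); small positive values let the synthesizer bridge a cue
#'   that happens to be weakly supported.
#' @param maxPathLength maximum number of cues per candidate path; default
#'   NA means "longest training path + 2", resolved by \code{learnPaths}.
#' @param maxCandidates number of ranked candidates returned per target.
#' @param maxPaths search budget: abort with an error beyond this many
#'   enumerated paths.
#' @return a validated config list of class "ProductionConfig".
#' @export
productionConfig <- function(supportThreshold = -Inf, topK = 5L,
                             tolerance = 0L, maxPathLength = NA_integer_,
                             maxCandidates = 5L, maxPaths = 200000L) {
  stopifnot(tolerance >= 0, topK >= 1, maxCandidates >= 1)
  structure(list(supportThreshold = supportThreshold, topK = as.integer(topK),
                 tolerance = as.integer(tolerance),
                 maxPathLength = as.integer(maxPathLength),
                 maxCandidates = as.integer(maxCandidates),
                 maxPaths = as.integer(maxPaths)),
            class = "ProductionConfig")
}

#' Predict cue supports from semantic vectors
#'
#' Chat = S G: how much support each form cue receives from the semantics.
#'
#' @param S semantic rows (matrix or \linkS4class{SemanticMatrix}).
#' @param G a production \linkS4class{LinearMapping}.
#' @return numeric matrix of cue supports, rows aligned with input rows.
#' @export
predictFormSupports <- function(S, G) {
  S <- .asDense(S)
  W <- mappingWeights(G)
  if (ncol(S) != nrow(W)) stop("dimension mismatch: ncol(S) != nrow(weights)")
  S %*% W
}

# split a cue into its ordered symbols (characters, or syllables)
.cueSymbols <- function(cue, unit) {
  if (unit == "syllable") strsplit(cue, .SYL_SEP, fixed = TRUE)[[1]]
  else strsplit(cue, "")[[1]]
}

#' Build the directed cue-overlap graph
#'
#' Vertices are cues; there is an edge u -> v iff the length-(n-1) suffix of
#' u equals the length-(n-1) prefix of v (element-wise on syllables in
#' syllable mode), so that u and v can be merged into a string. A word form
#' is a path from a boundary-initial cue to a boundary-final cue.
#'
#' @param cueSet character vector of cues (same unit and n).
#' @param unit "phone", "letter" or "syllable".
#' @return list with \code{cues}, \code{succ} (adjacency: integer successor
#'   indices per cue; boundary-final cues have none), \code{initial} and
#'   \code{final} (indices of boundary-initial / boundary-final cues).
#' @export
buildCueGraph <- function(cueSet, unit = "phone") {
  syms <- lapply(cueSet, .cueSymbols, unit = unit)
  isInit <- vapply(syms, function(s) s[1] == .BOUNDARY, logical(1))
  isFin <- vapply(syms, function(s) s[length(s)] == .BOUNDARY, logical(1))
  # complete one-cue words (#...#, from forms shorter than n) may have any
  # length; all other cues must share the same n
  n <- unique(lengths(syms)[!(isInit & isFin)])
  if (length(n) > 1) stop("mixed cue sizes: ", paste(n, collapse = ", "))
  join <- function(x) paste(x, collapse = "\r")
  k <- lengths(syms)
  prefix <- vapply(syms, function(s) join(s[-length(s)]), character(1))
  suffix <- vapply(syms, function(s) join(s[-1]), character(1))
  succ <- lapply(seq_along(cueSet), function(i) {
    if (isFin[i]) return(integer(0))   # word-final cues terminate paths
    which(prefix == suffix[i] & !isInit)
  })
  list(cues = cueSet, succ = succ,
       initial = which(isInit), final = which(isFin))
}

# overlap-concatenate a cue path into its surface string (boundaries stripped)
.pathSurface <- function(path, cueSet, unit) {
  syms <- .cueSymbols(cueSet[path[1]], unit)
  for (p in path[-1]) {
    s <- .cueSymbols(cueSet[p], unit)
    syms <- c(syms, s[length(s)])
  }
  syms <- syms[syms != .BOUNDARY]
  paste(syms, collapse = "")
}

#' Enumerate all complete cue paths by brute force
#'
#' Exhaustive depth-first enumeration of boundary-to-boundary paths in the
#' cue graph, up to \code{maxPathLength} cues per path. Cycles are allowed
#' (bounded by the length cap). Exponential in the worst case; intended for
#' small inventories and as the oracle the faster search is checked against.
#'
#' @param graph result of \code{\link{buildCueGraph}}.
#' @param maxPathLength maximum cues per path.
#' @param unit cue unit for surface reconstruction.
#' @param maxPaths abort beyond this many paths.
#' @return data.frame with \code{surface} and \code{path} (list column of
#'   integer cue indices); surfaces deduplicated (first path kept).
#' @export
enumeratePathsBruteforce <- function(graph, maxPathLength, unit = "phone",
                                     maxPaths = 200000L) {
  paths <- list()
  count <- 0L
  dfs <- function(path) {
    last <- path[length(path)]
    if (last %in% graph$final) {
      count <<- count + 1L
      if (count > maxPaths) stop("path budget exceeded (", maxPaths, ")")
      paths[[count]] <<- path
      return(invisible())
    }
    if (length(path) >= maxPathLength) return(invisible())
    for (nxt in graph$succ[[last]]) dfs(c(path, nxt))
  }
  for (s in graph$initial) dfs(s)
  if (count == 0L)
    return(data.frame(surface = character(0), path = I(list())))
  surfaces <- vapply(paths, .pathSurface, character(1),
                     cueSet = graph$cues, unit = unit)
  keep <- !duplicated(surfaces)
  data.frame(surface = surfaces[keep], path = I(paths[keep]),
             stringsAsFactors = FALSE)
}

# positional support model: one end-state mapping per word position from the
# semantics to "cue x occurs at position p" indicators
.fitPositionalSupports <- function(Strain, trainPaths, nCues, maxPathLength) {
  lapply(seq_len(maxPathLength), function(p) {
    ind <- matrix(0, nrow = nrow(Strain), ncol = nCues)
    for (i in seq_along(trainPaths)) {
      pp <- trainPaths[[i]]
      if (length(pp) >= p) ind[i, pp[p]] <- 1
    }
    mappingWeights(estimateEndstate(Strain, ind, direction = "production"))
  })
}

#' Synthesize ranked word-form candidates from meanings (learn_paths)
#'
#' For each target semantic vector, candidate cue paths are assembled over
#' the cue-overlap graph and ranked by synthesis by analysis: a candidate's
#' binary cue vector is projected back into semantic space through the
#' comprehension mapping and correlated (Pearson) with the target; the best
#' match is selected for articulation.
#'
#' In \code{graph} mode the admissible cues are those whose predicted
#' support S G reaches the threshold theta, plus at most \code{tolerance}
#' sub-threshold cues per path. In \code{positional} mode a separate
#' end-state mapping per word position predicts which cues are best
#' supported at that position, and each step of the search is restricted to
#' the top-k cues for its position (requires \code{trainS} and
#' \code{trainPaths}).
#'
#' @param targets matrix of target semantic vectors (rows), or a
#'   \linkS4class{SemanticMatrix}.
#' @param G production \linkS4class{LinearMapping} (S to C).
#' @param F comprehension \linkS4class{LinearMapping} (C to S) used for
#'   synthesis-by-analysis scoring.
#' @param inventory the \linkS4class{CueInventory}.
#' @param config a \code{\link{productionConfig}}.
#' @param mode "graph" or "positional".
#' @param trainPaths list of integer cue-index paths of the training forms
#'   (positional mode; also used to resolve a default maxPathLength).
#' @param trainS training semantic matrix (positional mode).
#' @return list (one element per target row) of data.frames with columns
#'   \code{surface}, \code{r} (synthesis correlation), \code{nCues},
#'   \code{tolerated}, \code{path} (list column), ranked by decreasing r
#'   (ties: shorter path, then lexicographic surface), truncated to
#'   \code{maxCandidates}. Empty data.frame (with a "diagnostic" attribute)
#'   when no complete path exists.
#' @export
learnPaths <- function(targets, G, F, inventory,
                       config = productionConfig(),
                       mode = c("graph", "positional"),
                       trainPaths = NULL, trainS = NULL) {
  mode <- match.arg(mode)
  targets <- .asDense(targets)
  cueSet <- cues(inventory)
  unit <- inventory@unit
  maxLen <- config$maxPathLength
  if (is.na(maxLen)) {
    if (is.null(trainPaths))
      stop("maxPathLength is NA and no trainPaths to derive it from")
    maxLen <- max(lengths(trainPaths)) + 2L
  }
  graph <- buildCueGraph(cueSet, unit)
  supports <- predictFormSupports(targets, G)
  Wf <- mappingWeights(F)

  positional <- NULL
  if (mode == "positional") {
    if (is.null(trainPaths) || is.null(trainS))
      stop("positional mode requires trainPaths and trainS")
    positional <- .fitPositionalSupports(.asDense(trainS), trainPaths,
                                         length(cueSet), maxLen)
  }

  lapply(seq_len(nrow(targets)), function(rowI) {
    sup <- supports[rowI, ]
    admissible <- sup >= config$supportThreshold
    posAdmissible <- NULL
    if (mode == "positional") {
      posAdmissible <- lapply(positional, function(Wp) {
        ps <- drop(targets[rowI, , drop = FALSE] %*% Wp)
        ord <- order(ps, decreasing = TRUE)
        ord[seq_len(min(config$topK, length(ord)))]
      })
    }
    found <- list(); nFound <- 0L; nVisited <- 0L
    dfs <- function(path, tol) {
      nVisited <<- nVisited + 1L
      if (nVisited > config$maxPaths)
        stop("path budget exceeded (", config$maxPaths, ")")
      last <- path[length(path)]
      if (last %in% graph$final) {
        nFound <<- nFound + 1L
        found[[nFound]] <<- list(path = path, tolerated = tol)
        return(invisible())
      }
      if (length(path) >= maxLen) return(invisible())
      for (nxt in graph$succ[[last]]) {
        if (mode == "positional" &&
            !(nxt %in% posAdmissible[[min(length(path) + 1L, maxLen)]]))
          next
        nTol <- tol + !admissible[nxt]
        if (nTol > config$tolerance) next
        dfs(c(path, nxt), nTol)
      }
    }
    starts <- graph$initial
    if (mode == "positional")
      starts <- intersect(starts, posAdmissible[[1]])
    for (s in starts) {
      tol0 <- as.integer(!admissible[s])
      if (tol0 <= config$tolerance) dfs(s, tol0)
    }
    if (nFound == 0L) {
      out <- data.frame(surface = character(0), r = numeric(0),
                        nCues = integer(0), tolerated = integer(0),
                        path = I(list()))
      attr(out, "diagnostic") <- if (length(starts) == 0)
        "no admissible boundary-initial cue" else
          "no complete boundary-to-boundary path under the current threshold/tolerance"
      return(out)
    }
    surfaces <- vapply(found, function(f)
      .pathSurface(f$path, cueSet, unit), character(1))
    keep <- !duplicated(surfaces)
    found <- found[keep]; surfaces <- surfaces[keep]
    # synthesis by analysis: project each candidate's cue vector through F
    vecs <- matrix(0, nrow = length(found), ncol = length(cueSet))
    for (i in seq_along(found)) vecs[i, unique(found[[i]]$path)] <- 1
    rs <- .rowCorMatrix(vecs %*% Wf, targets[rowI, , drop = FALSE])[, 1]
    lens <- vapply(found, function(f) length(f$path), integer(1))
    ord <- order(-rs, lens, surfaces)
    ord <- ord[seq_len(min(config$maxCandidates, length(ord)))]
    data.frame(surface = surfaces[ord], r = rs[ord], nCues = lens[ord],
               tolerated = vapply(found, function(f) f$tolerated,
                                  integer(1))[ord],
               path = I(lapply(found[ord], `[[`, "path")),
               stringsAsFactors = FALSE)
  })
}

#' Calibrate the production support threshold
#'
#' Picks theta so that the median training form retains all of its own cues
#' under its predicted supports (theta = the median over training entries of
#' the minimum support among the entry's own cues, minus a small epsilon).
#'
#' @param G production \linkS4class{LinearMapping}.
#' @param S training semantic matrix.
#' @param paths list of integer cue-index paths of the training forms.
#' @return numeric threshold.
#' @export
calibrateThreshold <- function(G, S, paths) {
  supports <- predictFormSupports(S, G)
  mins <- vapply(seq_along(paths), function(i)
    min(supports[i, paths[[i]]]), numeric(1))
  stats::median(mins) - 1e-9
}

#' Evaluate production accuracy
#'
#' A target counts as correctly produced when the top-ranked candidate
#' surface exactly matches the target form; an empty candidate list counts
#' as incorrect. Accuracies are reported for the same evaluation sets as
#' comprehension: train, val_all, val_lenient (validation homophones) and
#' val_newform.
#'
#' @param trainCandidates,valCandidates lists of ranked candidate
#'   data.frames from \code{\link{learnPaths}}, aligned with the split's
#'   train and validation entries (either may be NULL to skip that set).
#' @param split a \linkS4class{SplitResult}.
#' @return list with \code{accuracies}, \code{counts} and \code{perEntry}.
#' @export
evaluateProduction <- function(trainCandidates = NULL, valCandidates = NULL,
                               split) {
  top1 <- function(cands) vapply(cands, function(df)
    if (nrow(df) == 0) NA_character_ else df$surface[1], character(1))
  score <- function(cands, forms) {
    produced <- top1(cands)
    correct <- !is.na(produced) & produced == forms
    data.frame(produced = produced, target = forms, correct = correct,
               stringsAsFactors = FALSE)
  }
  acc <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  perTrain <- perVal <- NULL
  accuracies <- c(train = NA_real_, val_all = NA_real_,
                  val_lenient = NA_real_, val_newform = NA_real_)
  counts <- c(train = 0L, val_all = 0L, val_lenient = 0L, val_newform = 0L)
  if (!is.null(trainCandidates)) {
    perTrain <- score(trainCandidates, entries(trainLexicon(split))$form)
    perTrain$set <- "train"
    accuracies["train"] <- acc(perTrain$correct)
    counts["train"] <- nrow(perTrain)
  }
  if (!is.null(valCandidates)) {
    perVal <- score(valCandidates, entries(validationLexicon(split))$form)
    perVal$set <- "validation"
    vh <- valHomophones(split); vn <- valNewforms(split)
    accuracies["val_all"] <- acc(perVal$correct)
    accuracies["val_lenient"] <- acc(perVal$correct[vh])
    accuracies["val_newform"] <- acc(perVal$correct[vn])
    counts["val_all"] <- nrow(perVal)
    counts["val_lenient"] <- length(vh)
    counts["val_newform"] <- length(vn)
  }
  list(accuracies = accuracies, counts = counts,
       perEntry = rbind(perTrain, perVal))
}
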