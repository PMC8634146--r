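#' Estimate the end-state (least squares) mapping
#'
#' Solves Y = X W in the least-squares sense, returning the minimum-norm
#' solution W = X^+ Y (Moore-Penrose pseudoinverse), which is well-defined
#' even when X is rank-deficient -- the typical situation when homophones
#' give identical rows. No intercept column is used: the network
#' formulation S = C F has none. This is the "end-state of learning" that
#' infinite-epoch incremental training converges to; it is type-based and
#' frequency-blind.
#'
#' @param X input matrix (rows = entries), e.g. a \linkS4class{CueMatrix}.
#' @param Y output matrix with the same row count.
#' @param direction "comprehension" (C to S) or "production" (S to C).
#' @return a \linkS4class{LinearMapping}.
#' @export
estimateEndstate <- function(X, Y, direction = c("comprehension", "production")) {
  direction <- match.arg(direction)
  X <- .asDense(X); Y <- .asDense(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  W <- MASS::ginv(X) %*% Y
  dimnames(W) <- list(colnames(X), colnames(Y))
  new("LinearMapping", weights = W, direction = direction,
      training = list(mode = "endstate", eta = NA_real_,
                      eventsSeen = NA_integer_, epochs = NA_integer_))
}

#' One Widrow-Hoff update
#'
#' Returns W + t(c) (o - c W) eta for a single learning event with cue row
#' vector c and outcome row vector o: the weights move so that the next
#' presentation of c predicts o a little better. The input matrix is not
#' modified.
#'
#' @param W weight matrix (length(c) x length(o)).
#' @param c numeric cue vector (binary in practice).
#' @param o numeric outcome vector.
#' @param eta learning rate, > 0.
#' @return the updated weight matrix.
#' @export
widrowHoffUpdate <- function(W, c, o, eta) {
  stopifnot(eta > 0)
  if (length(c) != nrow(W) || length(o) != ncol(W))
    stop("dimension mismatch: need length(c) == nrow(W), length(o) == ncol(W)")
  pred <- drop(crossprod(c, W))
  W + eta * outer(c, o - pred)
}

#' Largest stable learning rate for Widrow-Hoff training
#'
#' Widrow-Hoff iterations on inputs X are stable for eta below 2 / lambda_max
#' where lambda_max is the largest eigenvalue of X'X. Returns that bound;
#' use a fraction of it (e.g. half) in practice.
#'
#' @param X input matrix.
#' @return the stability bound 2 / lambda_max.
#' @export
stableLearningRate <- function(X) {
  X <- .asDense(X)
  2 / (svd(X, nu = 0, nv = 0)$d[1]^2)
}

#' Sample a token stream from lexicon frequencies
#'
#' "shuffled_census" emits every entry exactly frequency-many times in a
#' random order (one pass over the attested tokens);
#' "frequency_proportional" samples nEvents tokens i.i.d. with probability
#' proportional to frequency.
#'
#' @param lex a \linkS4class{Lexicon} with positive total frequency.
#' @param nEvents number of events (frequency_proportional only).
#' @param scheme "shuffled_census" or "frequency_proportional".
#' @param seed integer seed.
#' @return integer vector of entry indices with attributes seed and scheme.
#' @export
sampleTokenStream <- function(lex, nEvents = NULL,
                              scheme = c("shuffled_census",
                                         "frequency_proportional"),
                              seed = 1L) {
  scheme <- match.arg(scheme)
  freq <- entries(lex)$frequency
  if (sum(freq) == 0) stop("total frequency must be positive")
  set.seed(seed)
  stream <- if (scheme == "shuffled_census") {
    sample(rep.int(seq_along(freq), freq))
  } else {
    if (is.null(nEvents)) stop("nEvents required for frequency_proportional")
    sample.int(length(freq), nEvents, replace = TRUE, prob = freq)
  }
  structure(as.integer(stream), seed = as.integer(seed), scheme = scheme)
}

#' Train a mapping incrementally with the Widrow-Hoff rule
#'
#' Weights start at zero and receive one Widrow-Hoff update per event in the
#' stream (optionally repeated for several epochs). Unlike the end-state
#' solution, the result depends on token frequencies and presentation
#' order: frequent pairs are learned better after a single pass. With many
#' epochs over a fixed set, the weights converge to the end-state
#' least-squares solution.
#'
#' @param C input matrix (rows indexed by the stream), e.g. a
#'   \linkS4class{CueMatrix}.
#' @param S output matrix with matching rows.
#' @param stream integer entry indices (see \code{\link{sampleTokenStream}}).
#' @param eta learning rate (default 0.001; see
#'   \code{\link{stableLearningRate}}).
#' @param direction "comprehension" or "production".
#' @param checkpoints event counts at which to snapshot the mapping.
#' @param epochs number of passes over the stream (default 1; multi-epoch
#'   mode exists for convergence checks).
#' @return list with \code{mapping} (final \linkS4class{LinearMapping}) and
#'   \code{checkpoints} (named list of snapshot mappings).
#' @export
trainIncremental <- function(C, S, stream, eta = 0.001,
                             direction = c("comprehension", "production"),
                             checkpoints = integer(0), epochs = 1L) {
  direction <- match.arg(direction)
  C <- .asDense(C); S <- .asDense(S)
  if (nrow(C) != nrow(S)) stop("C and S must have equal row counts")
  if (length(stream) > 0 && (min(stream) < 1 || max(stream) > nrow(C)))
    stop("stream indices out of range")
  stopifnot(eta > 0, epochs >= 1)
  W <- matrix(0, nrow = ncol(C), ncol = ncol(S))
  nz <- apply(C != 0, 1, which, simplify = FALSE)
  snaps <- vector("list", length(checkpoints))
  names(snaps) <- as.character(checkpoints)
  total <- length(stream) * epochs
  t <- 0L
  mk <- function(W, seen) new("LinearMapping", weights = W,
                              direction = direction,
                              training = list(mode = "incremental", eta = eta,
                                              eventsSeen = seen,
                                              epochs = as.integer(epochs)))
  for (ep in seq_len(epochs)) {
    for (i in stream) {
      t <- t + 1L
      idx <- nz[[i]]
      if (length(idx) > 0) {
        err <- S[i, ] - colSums(W[idx, , drop = FALSE])
        W[idx, ] <- W[idx, ] + eta * rep(err, each = length(idx))
      }
      if (t %% 5000L == 0L || t == total) {
        if (!all(is.finite(W)) || max(abs(W)) > 1e10)
          stop("Widrow-Hoff training diverged (eta = ", eta,
               " too large; see stableLearningRate)")
      }
      pos <- which(checkpoints == t)
      for (p in pos) snaps[[p]] <- mk(W, t)
    }
  }
  dimnames(W) <- list(colnames(C), colnames(S))
  list(mapping = mk(W, t), checkpoints = snaps)
}

#' Prune small weights from a mapping
#'
#' Sets every weight with absolute value below the threshold to zero and
#' reports the fraction of weights affected. Many weights in a trained
#' mapping are near zero (cues of low discriminative value), so a
#' substantial fraction can typically be pruned with little accuracy loss.
#'
#' @param m a \linkS4class{LinearMapping}.
#' @param theta threshold >= 0.
#' @return list with \code{mapping} (pruned copy) and \code{fractionPruned}.
#' @export
pruneWeights <- function(m, theta) {
  stopifnot(theta >= 0)
  W <- m@weights
  kill <- abs(W) < theta
  W[kill] <- 0
  training <- m@training
  training$pruneTheta <- theta
  list(mapping = new("LinearMapping", weights = W, direction = m@direction,
                     training = training),
       fractionPruned = mean(kill))
}
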