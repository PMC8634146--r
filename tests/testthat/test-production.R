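test_that("cue supports are the plain matrix product", {
  W <- matrix(rnorm(15), 3, 5)
  G <- new("LinearMapping", weights = W, direction = "production",
           training = list(mode = "endstate"))
  expect_equal(predictFormSupports(diag(3), G), W)
  expect_equal(predictFormSupports(matrix(0, 1, 3), G), matrix(0, 1, 5))
  set.seed(3)
  S <- matrix(rnorm(6), 2, 3)
  expect_equal(predictFormSupports(S, G), S %*% W)
})

test_that("cue graph edges require proper overlap", {
  g <- buildCueGraph(c("ab", "bc"))
  expect_equal(g$succ[[1]], 2L)
  expect_equal(buildCueGraph(c("ab", "cd"))$succ[[1]], integer(0))
  chain <- buildCueGraph(c("#al", "al@", "l@#"))
  expect_equal(chain$succ[[1]], 2L)
  expect_equal(chain$succ[[2]], 3L)
  expect_equal(chain$initial, 1L)
  expect_equal(chain$final, 3L)
  expect_error(buildCueGraph(c("ab", "abc")), "mixed")
  # syllable cues overlap element-wise
  sg <- buildCueGraph(c("#-a", "a-l@", "l@-#"), unit = "syllable")
  expect_equal(sg$succ[[1]], 2L)
  expect_equal(sg$succ[[2]], 3L)
})

test_that("brute-force enumeration finds exactly the legal complete paths", {
  one <- buildCueGraph("#a#")
  got <- enumeratePathsBruteforce(one, 4)
  expect_equal(got$surface, "a")

  tri <- buildCueGraph(c("#ab", "aba", "ba#"))
  got <- enumeratePathsBruteforce(tri, 5)
  expect_equal(got$surface, "aba")
  expect_equal(got$path[[1]], c(1L, 2L, 3L))

  # cyclic pair: hand enumeration up to 6 cues
  cyc <- buildCueGraph(c("#ab", "aba", "bab", "ab#", "ba#"))
  got <- enumeratePathsBruteforce(cyc, 6)
  expect_setequal(got$surface, c("ab", "aba", "abab", "ababa", "ababab"))

  expect_error(enumeratePathsBruteforce(cyc, 50, maxPaths = 10), "budget")
})

test_that("unconstrained learnPaths equals brute-force enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    # random small inventory built from random short forms
    forms <- unique(replicate(sample(3:6, 1), paste(
      sample(c("a", "b", "c"), sample(2:4, 1), TRUE), collapse = "")))
    inv <- new("CueInventory", unit = "phone", n = 2L,
               cues = unique(unlist(lapply(forms, extractNgramCues, n = 2))))
    k <- length(cues(inv))
    d <- 6
    G <- new("LinearMapping", weights = matrix(rnorm(d * k), d, k),
             direction = "production", training = list(mode = "endstate"))
    Fm <- new("LinearMapping", weights = matrix(rnorm(k * d), k, d),
              direction = "comprehension", training = list(mode = "endstate"))
    target <- matrix(rnorm(d), 1, d)
    cfg <- productionConfig(supportThreshold = -Inf, maxPathLength = 6,
                            maxCandidates = 10000)
    cands <- learnPaths(target, G, Fm, inv, cfg, mode = "graph")[[1]]
    brute <- enumeratePathsBruteforce(buildCueGraph(cues(inv)), 6)
    expect_setequal(cands$surface, brute$surface)
    # well-formedness: boundary start/end and n-1 overlap for every path
    for (p in cands$path) {
      cs <- cues(inv)[p]
      expect_true(startsWith(cs[1], "#"))
      expect_true(endsWith(cs[length(cs)], "#"))
      if (length(cs) > 1)
        for (i in seq_len(length(cs) - 1))
          expect_equal(substring(cs[i], 2), substring(cs[i + 1], 1, 1))
    }
    # surface reconstruction round-trip
    for (i in seq_len(nrow(cands)))
      expect_equal(cuePath(cands$surface[i], inv),
                   cues(inv)[cands$path[[i]]], ignore_attr = TRUE)
  }
})

test_that("end-state synthesis reproduces trained forms", {
  lex <- separableLexicon(8, seed = 6)
  fit <- fitEndstate(lex, d = 40, sdNoise = 0)
  cfg <- productionConfig(supportThreshold = 0.5, maxCandidates = 3,
                          maxPathLength = max(lengths(fit$paths)) + 2)
  cands <- learnPaths(fit$S, fit$G, fit$Fmap, fit$inv, cfg, mode = "graph")
  top <- vapply(cands, function(d) d$surface[1], character(1))
  expect_equal(top, entries(lex)$form)

  split <- manualSplit(lex)
  ev <- evaluateProduction(cands, NULL, split)
  expect_equal(ev$accuracies[["train"]], 1)
})

test_that("positional mode restricts the search to per-position top-k cues", {
  lex <- separableLexicon(8, seed = 6)
  fit <- fitEndstate(lex, d = 40, sdNoise = 0)
  cfg <- productionConfig(supportThreshold = -Inf, topK = 3, maxCandidates = 3,
                          maxPathLength = max(lengths(fit$paths)) + 2)
  cands <- learnPaths(fit$S, fit$G, fit$Fmap, fit$inv, cfg,
                      mode = "positional", trainPaths = fit$paths,
                      trainS = fit$S)
  top <- vapply(cands, function(d)
    if (nrow(d) > 0) d$surface[1] else NA_character_, character(1))
  expect_equal(top, entries(lex)$form)
})

test_that("raising the threshold or lowering tolerance never adds candidates", {
  lex <- separableLexicon(6, seed = 9)
  fit <- fitEndstate(lex, d = 30, sdNoise = 0)
  maxLen <- max(lengths(fit$paths)) + 2
  surf <- function(theta, tol)
    learnPaths(as.matrix(fit$S)[3, , drop = FALSE], fit$G, fit$Fmap,
               fit$inv,
               productionConfig(supportThreshold = theta, tolerance = tol,
                                maxPathLength = maxLen,
                                maxCandidates = 100000),
               mode = "graph")[[1]]$surface
  s1 <- surf(-Inf, 0); s2 <- surf(0.3, 0); s3 <- surf(0.9, 0)
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
  t0 <- surf(0.5, 0); t1 <- surf(0.5, 1); t2 <- surf(0.5, 2)
  expect_true(all(t0 %in% t1))
  expect_true(all(t1 %in% t2))
})

test_that("tolerance mode bridges a single unsupported cue", {
  # the validation form "teka" has exactly one cue ("tek") that occurs in no
  # training form and hence can receive no support at all
  e <- data.frame(form = c("taka", "tema", "meka", "teka"),
                  lemma = c("taka", "tema", "meka", "teka"),
                  case = "nominative", number = "singular", frequency = 1L)
  lex <- Lexicon(e)
  cmAll <- buildCueMatrix(lex, "phone", 3)
  inv <- cueInventory(cmAll)
  train <- subsetLexicon(lex, 1:3)
  Ctrain <- buildCueMatrix(train, "phone", 3, inventory = inv)
  space <- exactSpace(lex, d = 20, seed = 2)
  Strain <- as.matrix(buildSemanticMatrix(train, space, seed = 1))
  G <- estimateEndstate(Strain, Ctrain, "production")
  Fm <- estimateEndstate(Ctrain, Strain, "comprehension")
  # target meaning: midpoint of tema and meka, so its predicted supports are
  # exactly 0.5 for every cue of those forms and exactly 0 for "tek"
  target <- matrix(colMeans(Strain[2:3, , drop = FALSE]), 1)
  sup <- predictFormSupports(target, G)[1, ]
  own <- match(cuePath("teka", inv), cues(inv))
  expect_equal(sum(abs(sup[own]) < 1e-8), 1)   # exactly "tek" unsupported
  theta <- 0.25
  run <- function(tol)
    learnPaths(target, G, Fm, inv,
               productionConfig(supportThreshold = theta, tolerance = tol,
                                maxPathLength = 8, maxCandidates = 1000),
               mode = "graph")[[1]]$surface
  expect_false("teka" %in% run(0))
  expect_true("teka" %in% run(1))
  expect_true("teka" %in% run(2))
})

test_that("production scoring is exact-match with category breakdown", {
  g <- generateToyLexicon(generatorSpec(nLemmas = 10, seed = 3))
  sp <- splitTrainValidation(g$lexicon, 0.8, seed = 1)
  nV <- length(validationLexicon(sp))
  mk <- function(s) data.frame(surface = s, r = rep(1, length(s)),
                               nCues = rep(1L, length(s)),
                               tolerated = rep(0L, length(s)),
                               stringsAsFactors = FALSE)
  # hand-scored: first validation candidate right, the rest wrong or empty
  forms <- entries(validationLexicon(sp))$form
  cands <- c(list(mk(forms[1])),
             rep(list(mk("wrong")), nV - 2),
             list(mk(character(0))))
  ev <- evaluateProduction(NULL, cands, sp)
  expect_equal(ev$accuracies[["val_all"]], 1 / nV)
  expect_equal(ev$counts[["val_all"]], nV)
  expect_true(is.na(ev$accuracies[["train"]]))
})

test_that("threshold calibration keeps the median training form intact", {
  lex <- separableLexicon(10, seed = 12)
  fit <- fitEndstate(lex, d = 40, sdNoise = 0)
  theta <- calibrateThreshold(fit$G, fit$S, fit$paths)
  sup <- predictFormSupports(fit$S, fit$G)
  keepsAll <- vapply(seq_along(fit$paths), function(i)
    all(sup[i, fit$paths[[i]]] >= theta), logical(1))
  expect_gte(mean(keepsAll), 0.5)
})
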