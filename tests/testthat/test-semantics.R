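test_that("simulated spaces have the requested scale and are seeded", {
  lemmas <- paste0("L", 1:100)
  feats <- c("SINGULAR", "PLURAL", "NOMINATIVE")
  sp <- simulateSemanticSpace(lemmas, feats, d = 300, seed = 42)
  sp2 <- simulateSemanticSpace(lemmas, feats, d = 300, seed = 42)
  expect_identical(sp@lexemeVectors, sp2@lexemeVectors)
  expect_identical(sp@featureVectors, sp2@featureVectors)

  draws <- as.vector(sp@lexemeVectors)
  seSd <- 4 / sqrt(2 * length(draws))
  expect_lt(abs(stats::sd(draws) - 4), 3 * seSd)

  zeroF <- simulateSemanticSpace(lemmas, feats, d = 20, sdFeature = 0, seed = 1)
  expect_true(all(zeroF@featureVectors == 0))

  # featureScale rescales the feature draws exactly (same seed)
  base <- simulateSemanticSpace(lemmas, feats, d = 50, seed = 7)
  scaled <- simulateSemanticSpace(lemmas, feats, d = 50, featureScale = 1 / 110,
                                  seed = 7)
  expect_equal(mean(abs(scaled@featureVectors["PLURAL", ])),
               mean(abs(base@featureVectors["PLURAL", ])) / 110)
})

test_that("simulated lexeme vectors are pairwise near-orthogonal", {
  sp <- simulateSemanticSpace(paste0("L", 1:80), "PLURAL", d = 300, seed = 3)
  lx <- sp@lexemeVectors
  set.seed(1)
  pairs <- cbind(sample(80, 1000, TRUE), sample(80, 1000, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  cosines <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- lx[pairs[i, 1], ]; b <- lx[pairs[i, 2], ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_lt(mean(abs(cosines)), 3 / sqrt(300))
})

test_that("meaning composition is additive over lexeme and features", {
  space <- new("SemanticSpace", d = 2L,
               lexemeVectors = matrix(c(1, 0), 1, 2, dimnames = list("Aal", NULL)),
               featureVectors = rbind(PLURAL = c(0, 1), SINGULAR = c(5, 5),
                                      DATIVE = c(1, 1)),
               params = list(sdLexeme = 4, sdFeature = 4, sdNoise = 0,
                             featureScale = 1, seed = 1L))
  entry <- list(lemma = "Aal", number = "plural", case = "dative")
  expect_equal(composeMeaning(entry, space), c(2, 2))

  sg <- list(lemma = "Aal", number = "singular", case = "dative")
  expect_equal(composeMeaning(sg, space, "privative"), c(1, 0) + c(1, 1))
  # equipollent and privative singulars differ by exactly the SINGULAR vector
  expect_equal(composeMeaning(sg, space, "equipollent") -
                 composeMeaning(sg, space, "privative"),
               space@featureVectors["SINGULAR", ], ignore_attr = TRUE)

  expect_error(composeMeaning(list(lemma = "Aal", number = "plural",
                                   case = "ablative"), space), "ABLATIVE")
  expect_error(composeMeaning(list(lemma = "Eel", number = "plural",
                                   case = "dative"), space), "Eel")
})

test_that("semantic matrices distinguish homophones via cell features and noise", {
  lex <- table3Lexicon()
  space <- simulateSemanticSpace("Aal", semanticFeatures(lex), d = 25, seed = 2)
  S <- buildSemanticMatrix(lex, space, seed = 9)
  m <- as.matrix(S)
  expect_equal(nrow(m), 7)
  dists <- as.matrix(stats::dist(m))
  expect_true(all(dists[upper.tri(dists)] > 0))
  # determinism
  expect_identical(as.matrix(buildSemanticMatrix(lex, space, seed = 9)), m)

  # without noise the matrix is exactly additive per entry
  sp0 <- simulateSemanticSpace("Aal", semanticFeatures(lex), d = 10,
                               sdNoise = 0, seed = 3)
  S0 <- as.matrix(buildSemanticMatrix(lex, sp0, seed = 1))
  e <- entries(lex)
  for (i in c(1, 4, 6)) {
    expected <- sp0@lexemeVectors["Aal", ] +
      sp0@featureVectors[toupper(e$number[i]), ] +
      sp0@featureVectors[toupper(e$case[i]), ]
    expect_equal(S0[i, ], unname(expected))
  }
  # homophones in the same paradigm cell layout but different cells differ
  expect_false(identical(S0[1, ], S0[2, ]))
})

test_that("word2vec text embeddings are loaded by surface form", {
  f <- tempfile()
  writeLines(c("3 4",
               "al 1 2 3 4",
               "al@ 0 1 0 1",
               "al@n -1 0 0.5 2"), f)
  lex <- table3Lexicon()
  got <- loadEmbeddings(f, lex)
  expect_equal(got$d, 4)
  m <- as.matrix(got$matrix)
  expect_equal(nrow(m), 7)
  expect_equal(m[1, ], c(1, 2, 3, 4))        # "al"
  expect_equal(m[1, ], m[2, ])               # homophones share vectors
  expect_equal(m[6, ], c(-1, 0, 0.5, 2))     # "al@n"

  # missing forms are dropped with a warning and a coverage report
  f2 <- tempfile()
  writeLines(c("al 1 0 0", "al@ 0 1 0"), f2)
  expect_warning(part <- loadEmbeddings(f2, lex), "dropped")
  expect_equal(part$missing, "al@n")
  expect_equal(rowKeys(part$matrix), 1:5)
})

fullParadigmLexicon <- function(nLemmas, seed) {
  set.seed(seed)
  cons <- c("b", "d", "k", "l", "m", "n", "p", "r", "s", "t")
  vow <- c("a", "i", "o", "u")
  stems <- character(0)
  while (length(stems) < nLemmas) {
    s <- paste0(sample(cons, 1), sample(vow, 1), sample(cons, 1),
                sample(vow, 1))
    if (!(s %in% stems)) stems <- c(stems, s)
  }
  e <- expand.grid(case = c("nominative", "genitive", "dative", "accusative"),
                   number = c("singular", "plural"), lemma = stems,
                   stringsAsFactors = FALSE)
  e$form <- paste0(e$lemma, ifelse(e$number == "plural", "e", ""),
                   substr(e$case, 1, 1))
  e$frequency <- 1L
  Lexicon(e)
}

test_that("analytical vectors recover compositional structure from embeddings", {
  # noise-free compositional embeddings: entry vector = lexeme + number + case
  lex <- fullParadigmLexicon(100, seed = 4)
  spaceOf <- function(fs)
    simulateSemanticSpace(unique(entries(lex)$lemma), semanticFeatures(lex),
                          d = 60, sdNoise = 0, featureScale = fs, seed = 6)
  # lexeme-dominant features: reconstruction is close to exact
  S <- buildSemanticMatrix(lex, spaceOf(1 / 8), seed = 1)
  an <- deriveAnalyticalVectors(S, lex)
  expect_gt(an$meanR, 0.95)

  # equal scales: plain-mean reconstruction double-counts the grand feature
  # means; for a balanced 4x2 paradigm the expected r has the closed form
  # cov / sqrt(varT * varR) = 72 / sqrt(48 * 144) = sqrt(3)/2
  Seq <- buildSemanticMatrix(lex, spaceOf(1), seed = 1)
  anEq <- deriveAnalyticalVectors(Seq, lex)
  expect_lt(abs(anEq$meanR - sqrt(3) / 2), 0.02)

  # a lemma with a single variant: lexeme vector equals that vector
  one <- subsetLexicon(lex, 1)
  S1 <- new("SemanticMatrix", values = as.matrix(S)[1, , drop = FALSE],
            rowKeys = 1L)
  an1 <- deriveAnalyticalVectors(S1, one)
  expect_equal(unname(an1$space@lexemeVectors[1, ]), as.matrix(S)[1, ])

  # two-lemma toy with hand-computable means
  V <- rbind(c(2, 0, 4), c(0, 2, 0), c(4, 4, 4), c(2, 2, 2))
  toy <- Lexicon(data.frame(form = c("ka", "kae", "mo", "moe"),
                            lemma = c("ka", "ka", "mo", "mo"),
                            case = "nominative",
                            number = rep(c("singular", "plural"), 2),
                            frequency = 1L))
  anT <- deriveAnalyticalVectors(new("SemanticMatrix", values = V,
                                     rowKeys = 1:4), toy)
  expect_equal(unname(anT$space@lexemeVectors["ka", ]), c(1, 1, 2))
  expect_equal(unname(anT$space@featureVectors["PLURAL", ]),
               colMeans(V[c(2, 4), ]))
})

test_that("semantic spaces round-trip through their text serialization", {
  sp <- simulateSemanticSpace(c("a", "b"), c("SINGULAR", "PLURAL"), d = 7,
                              featureScale = 1 / 110, seed = 13)
  f <- tempfile()
  writeSemanticSpace(sp, f)
  back <- readSemanticSpace(f)
  expect_equal(back@d, sp@d)
  expect_equal(back@lexemeVectors, sp@lexemeVectors)
  expect_equal(back@featureVectors, sp@featureVectors)
  expect_equal(back@params$featureScale, sp@params$featureScale)
})
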