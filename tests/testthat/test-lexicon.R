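test_that("reading a paradigm file preserves rows and finds the alphabet", {
  path <- system.file("extdata", "aal_paradigm.tsv", package = "discrimlex")
  lex <- readLexicon(path, dialect = c(form = "pronunciation"))
  expect_equal(length(lex), 7)
  expect_equal(length(unique(entries(lex)$form)), 3)
  expect_equal(entries(lex)$form[1:3], rep("al", 3))
  expect_equal(entries(lex)$frequency, c(29L, 29L, 29L, 34L, 34L, 17L, 17L))
  expect_setequal(alphabet(lex), c("a", "l", "@", "n"))

  empty <- tempfile(fileext = ".tsv")
  writeLines("form\tlemma\tcase\tnumber\tfrequency", empty)
  expect_equal(length(readLexicon(empty)), 0)

  noCol <- tempfile(fileext = ".tsv")
  writeLines(c("form\tlemma\tcase\tnumber", "al\tAal\tnominative\tsingular"),
             noCol)
  expect_error(readLexicon(noCol), "frequency")

  badFreq <- tempfile(fileext = ".tsv")
  writeLines(c("form\tlemma\tcase\tnumber\tfrequency",
               "al\tAal\tnominative\tsingular\tmany"), badFreq)
  expect_error(readLexicon(badFreq), "row 1")
})

test_that("write + read round-trips a generated lexicon field by field", {
  g <- generateToyLexicon(generatorSpec(nLemmas = 12, seed = 3))
  path <- tempfile(fileext = ".tsv")
  writeLexicon(g$lexicon, path)
  back <- readLexicon(path)
  for (col in c("form", "lemma", "case", "number", "gender", "frequency",
                "syllables"))
    expect_equal(entries(back)[[col]], entries(g$lexicon)[[col]], info = col)
  expect_equal(alphabet(back), alphabet(g$lexicon))
})

test_that("invalid entry tables are rejected", {
  expect_error(Lexicon(data.frame(form = "al", lemma = "x")), "required")
  bad <- table3Entries(); bad$frequency[1] <- -1L
  expect_error(Lexicon(bad), "non-negative")
  bad <- table3Entries(); bad$case[2] <- "vocative"
  expect_error(Lexicon(bad), "case")
  bad <- table3Entries()[c(1, 1), ]
  expect_error(Lexicon(bad), "unique")
})

test_that("attachArticles prefixes forms and handles indefinites", {
  e <- data.frame(form = "al", lemma = "Aal", case = "nominative",
                  number = "singular", gender = "m", frequency = 1L)
  withArt <- attachArticles(Lexicon(e), mode = "definite_only")
  expect_equal(entries(withArt)$form, "deral")
  expect_equal(entries(withArt)$definiteness, "definite")

  # empty articles leave forms unchanged
  nullMap <- germanArticles()
  nullMap$article <- ""
  same <- attachArticles(Lexicon(e), articleMap = nullMap)
  expect_equal(entries(same)$form, "al")

  # doubling: n entries become 2n; indefinite plurals stay bare
  g <- generateToyLexicon(generatorSpec(nLemmas = 6, seed = 2))
  both <- attachArticles(g$lexicon, mode = "definite_and_indefinite")
  expect_equal(length(both), 2 * length(g$lexicon))
  eb <- entries(both)
  indefPl <- eb$definiteness == "indefinite" & eb$number == "plural"
  expect_true(any(indefPl))
  expect_equal(eb$form[indefPl],
               entries(g$lexicon)$form[entries(g$lexicon)$number == "plural"])
  expect_true(all(eb$article[indefPl] == ""))

  noGender <- table3Entries(); noGender$gender <- NA
  expect_error(attachArticles(Lexicon(noGender)), "Aal")
})

test_that("homophone groups partition entries by exact surface form", {
  groups <- findHomophones(table3Lexicon())
  expect_equal(lengths(groups), c(al = 3L, "al@" = 2L, "al@n" = 2L))
  expect_equal(sort(unlist(groups)), 1:7, ignore_attr = TRUE)

  lex <- separableLexicon(8)
  expect_true(all(lengths(findHomophones(lex)) == 1))

  g <- generateToyLexicon(generatorSpec(nLemmas = 25, seed = 9))
  expect_equal(findHomophones(g$lexicon), g$homophoneGroups)
})

test_that("random splits are deterministic and partition validation", {
  g <- generateToyLexicon(generatorSpec(nLemmas = 30, seed = 5))
  lex <- g$lexicon
  ten <- subsetLexicon(lex, 1:10)
  s1 <- splitTrainValidation(ten, 0.8, seed = 11)
  expect_equal(length(trainLexicon(s1)), 8)
  expect_equal(length(validationLexicon(s1)), 2)
  s2 <- splitTrainValidation(ten, 0.8, seed = 11)
  expect_identical(entries(trainLexicon(s1)), entries(trainLexicon(s2)))

  sp <- splitTrainValidation(lex, 0.8, seed = 4)
  nv <- length(validationLexicon(sp))
  expect_equal(sort(c(valHomophones(sp), valNewforms(sp),
                      excludedNovelLemmas(sp))), seq_len(nv))
  # set-membership oracle for the categories
  vv <- entries(validationLexicon(sp)); tv <- entries(trainLexicon(sp))
  expect_equal(valHomophones(sp), which(vv$form %in% tv$form))
  expect_equal(valNewforms(sp),
               which(!(vv$form %in% tv$form) & vv$lemma %in% tv$lemma))
})

test_that("no_novel_cues splits leave no validation cue untrained", {
  g <- generateToyLexicon(generatorSpec(nLemmas = 40, seed = 6))
  tri <- function(f) extractNgramCues(f, 3)
  for (seed in 1:100) {
    sp <- suppressMessages(
      splitTrainValidation(g$lexicon, 0.8, "no_novel_cues", tri, seed = seed))
    trainCues <- unique(unlist(lapply(entries(trainLexicon(sp))$form, tri)))
    valCues <- unique(unlist(lapply(entries(validationLexicon(sp))$form, tri)))
    expect_true(all(valCues %in% trainCues), info = paste("seed", seed))
  }
})

test_that("a form with a unique cue is forced into training", {
  # homophone pairs share all their cues; only "qix" carries unique cues
  e <- data.frame(form = c("tan", "tan", "tam", "tam", "tak", "tak", "qix"),
                  lemma = c(rep("tan", 2), rep("tam", 2), rep("tak", 2), "qix"),
                  case = c("nominative", "dative", "nominative", "dative",
                           "nominative", "dative", "nominative"),
                  number = "singular", frequency = 1L)
  lex <- Lexicon(e)
  tri <- function(f) extractNgramCues(f, 3)
  # whatever the seed, "qix" must end up in training
  for (seed in 1:10) {
    sp <- suppressMessages(
      splitTrainValidation(lex, 0.55, "no_novel_cues", tri, seed = seed))
    expect_true("qix" %in% entries(trainLexicon(sp))$form)
  }
})

test_that("role expansion is a deterministic cross-product over the case", {
  lex <- table3Lexicon()
  ex <- expandRoles(lex)
  e <- entries(ex)
  expect_equal(sum(e$case == "nominative" & e$number == "singular"), 3)
  expect_equal(sort(e$role[e$case == "nominative" & e$number == "singular"]),
               c("agent", "patient", "theme"))
  expect_equal(sort(unique(e$role[e$case == "genitive"])),
               c("partitive", "possessive"))
  oneRole <- data.frame(case = unique(defaultRoleTable()$case),
                        role = "only", probability = 1)
  expect_equal(length(expandRoles(lex, oneRole)), length(lex))
  badRoles <- defaultRoleTable()[defaultRoleTable()$case != "dative", ]
  expect_error(expandRoles(lex, badRoles), "dative")
})

test_that("role frequency simulation reproduces the worked allocation", {
  roles <- defaultRoleTable()
  e <- data.frame(form = "Adresse", lemma = "Adresse",
                  case = c("nominative", "genitive", "dative", "accusative"),
                  number = "singular", gender = "f", frequency = 137L)
  rl <- expandRoles(Lexicon(e), roles)
  re <- entries(rl)
  # drop pattern of the worked example: nom patient, gen possessive,
  # acc patient and acc motion omitted
  drops <- (re$case == "nominative" & re$role == "patient") |
    (re$case == "genitive" & re$role == "possessive") |
    (re$case == "accusative" & re$role %in% c("patient", "motion"))
  out <- entries(simulateRoleFrequencies(rl, roles, drops = drops))
  got <- stats::setNames(out$frequency, paste(out$case, out$role))
  expect_equal(got[["nominative agent"]], 20L)
  expect_equal(got[["nominative theme"]], 16L)
  expect_equal(got[["nominative patient"]], 0L)
  expect_equal(got[["genitive possessive"]], 0L)
  expect_equal(got[["genitive partitive"]], 35L)
  expect_equal(got[["dative beneficiary"]], 18L)
  expect_equal(got[["dative location"]], 18L)
  expect_equal(got[["accusative patient"]], 0L)
  expect_equal(got[["accusative motion"]], 0L)
  expect_equal(got[["accusative experiencer"]], 35L)

  zero <- e; zero$frequency <- 0L
  z <- suppressMessages(
    simulateRoleFrequencies(expandRoles(Lexicon(zero), roles), roles, seed = 1))
  expect_true(all(entries(z)$frequency == 0))
})

test_that("on average one role per cell is dropped", {
  roles <- defaultRoleTable()
  nCells <- 10000
  e <- data.frame(form = paste0("f", 1:nCells),
                  lemma = paste0("f", 1:nCells),
                  case = rep(unique(roles$case), length.out = nCells),
                  number = "singular", frequency = 10L)
  rl <- expandRoles(Lexicon(e), roles)
  out <- suppressMessages(simulateRoleFrequencies(rl, roles, seed = 202))
  dropped <- entries(out)$frequency == 0
  cell <- entries(out)$lemma
  dropsPerCell <- tapply(dropped, cell, sum)
  se <- stats::sd(dropsPerCell) / sqrt(nCells)
  expect_lt(abs(mean(dropsPerCell) - 1), 3 * se)
})
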