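# Pearson r that is defined (as 0) for zero-variance vectors
.safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# correlations of each row of A against each row of B; zero-variance rows
# yield r = 0 rather than NA
.rowCorMatrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  out <- suppressWarnings(stats::cor(t(A), t(B)))
  out[is.na(out)] <- 0
  out
}

.asDense <- function(x) {
  if (is(x, "CueMatrix") || is(x, "SemanticMatrix")) x <- as.matrix(x)
  as.matrix(x)
}
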