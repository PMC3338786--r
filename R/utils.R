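IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of IUPAC DNA strings
#'
#' @param x Character vector of IUPAC DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a child seed from a root seed and a label
#'
#' One root seed fans out to per-stage, per-dataset child streams by stable
#' hashing of a label, so adding a stage or dataset does not perturb the
#' randomness of the others. The result is always a valid 32-bit seed.
#'
#' @param root Integer root seed.
#' @param label Character label of the stream.
#' @return Integer seed in \code{[1, 2^31 - 20]}.
#' @export
derive_seed <- function(root, label) {
  m <- 2147483629  # largest prime below 2^31
  h <- as.numeric(root %% m)
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
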