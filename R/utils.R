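## Internal helpers shared across modules.

#' Chain-group of a chain label
#'
#' IGH forms its own group; IGK and IGL are pooled into the joint light-chain
#' repertoire ("IgKL"), which is the denominator for all light-chain
#' frequencies (the kappa/lambda ratio and light-chain diversity are defined
#' on the pooled repertoire).
#'
#' @param chain character vector of chain labels ("IGH", "IGK", "IGL").
#' @return character vector, "IGH" or "IgKL".
#' @export
chainGroup <- function(chain) {
  ifelse(chain == "IGH", "IGH", "IgKL")
}

## Strip IMGT-style allele suffixes ("IGKV1-5*01" -> "IGKV1-5").
.stripAllele <- function(gene) {
  sub("\\*.*$", "", gene)
}

## Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## One fixed codon per amino acid, used to derive a deterministic cdr3_nt
## from a CDR3 amino-acid string in the synthetic generator.
.CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

.AA <- names(.CODON)

.aaToNt <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) paste(.CODON[ch], collapse = ""), "")
}

.randNt <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

## Hamming distance between two equal-length strings.
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
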