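# Internal helpers shared across modules.

# 95% interval multiplier is fixed at 1.96 by convention throughout.
Z95 <- 1.96

`%||%` <- function(a, b) if (is.null(a)) b else a

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Test whether an allele pair is palindromic
#'
#' A biallelic SNV is palindromic when its two alleles are complementary
#' (A/T or G/C), so the strand cannot be inferred from the allele labels
#' alone.
#'
#' @param a1,a2 Character vectors of single-nucleotide alleles (A/C/G/T).
#' @return Logical vector.
#' @export
#' @examples
#' is_palindromic(c("A", "A", "G"), c("T", "G", "C"))
is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

complement_allele <- function(a) {
  unname(COMPLEMENT[a])
}

two_sided_normal_p <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards so seeded internals (e.g. the weighted-median
# bootstrap) never perturb user-level reproducibility.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
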