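# Six-state epigenotype space and the two-stage observation model:
# bisulfite conversion (fragment strand -> post-PCR nucleotide Z) followed
# by the Phred-parameterized sequencing error channel (Z -> observed D).

#' @useDynLib methaplo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal integer codes, shared with the C++ engine:
# nucleotides/observed bases A=0 C=1 G=2 T=3 N=4; epigenotypes add M=4 (meC)
# and W=5 (meG = G whose complementary reverse-strand C is methylated).

.NUC <- c("A", "C", "G", "T")
.EPI <- c("A", "C", "G", "T", "M", "W")

.nuc_code <- function(x) {
  x <- toupper(as.character(x))
  i <- match(x, c("A", "C", "G", "T", "N"))
  if (anyNA(i)) stop("invalid nucleotide: ", paste(x[is.na(i)], collapse = ", "))
  i - 1L
}

.epi_code <- function(g) {
  g <- as.character(g)
  g[g == "meC"] <- "M"
  g[g == "meG"] <- "W"
  i <- match(toupper(g), .EPI)
  if (anyNA(i)) stop("invalid epigenotype: ", paste(g[is.na(i)], collapse = ", "))
  i - 1L
}

.strand_code <- function(r) {
  i <- match(as.character(r), c("fwd", "rev"))
  if (anyNA(i)) stop("strand must be 'fwd' or 'rev'")
  i - 1L
}

#' Nucleotide projection of an epigenotype
#'
#' Maps each of the six epigenotype states to its underlying nucleotide:
#' methylated C projects to C, methylated G (a G paired with a methylated
#' reverse-strand C) projects to G, and the four plain nucleotides map to
#' themselves.
#'
#' @param g Character vector of epigenotypes among
#'   `"A","C","G","T","M","W"` (`"meC"`/`"meG"` are accepted aliases).
#' @return Character vector of nucleotides among `"A","C","G","T"`.
#' @export
#' @examples
#' epi_projection(c("A", "M", "W"))
epi_projection <- function(g) {
  c("A", "C", "G", "T", "C", "G")[.epi_code(g) + 1L]
}

#' Bisulfite conversion and error-model parameters
#'
#' @param conversion_rate Probability that an unmethylated cytosine is
#'   successfully bisulfite converted (default 0.95).  The failed-conversion
#'   rate used by the conversion model is `1 - conversion_rate`.
#' @param beta Rate of inappropriate conversion, i.e. a methylated cytosine
#'   that is nonetheless converted (default 0.05).
#' @return An object of class `conversion_params` with elements
#'   `conversion_rate`, `alpha_fail`, and `beta`.
#' @export
conversion_params <- function(conversion_rate = 0.95, beta = 0.05) {
  stopifnot(
    is.numeric(conversion_rate), length(conversion_rate) == 1L,
    conversion_rate >= 0, conversion_rate <= 1,
    is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1
  )
  structure(
    list(
      conversion_rate = conversion_rate,
      alpha_fail = 1 - conversion_rate,
      beta = beta
    ),
    class = "conversion_params"
  )
}

#' Bisulfite conversion probability P(Z = z | g, r)
#'
#' Probability that position with epigenotype `g`, read from fragment strand
#' `r`, carries nucleotide `z` after bisulfite conversion, PCR amplification,
#' and forward-genome mapping.  An unmethylated C read from its own strand
#' converts to T unless conversion fails (rate `alpha_fail`); a methylated C
#' is protected unless inappropriately converted (rate `beta`); the
#' complementary strand sees the partner base unperturbed.  Reverse-strand
#' reads behave symmetrically on G (whose reverse-strand partner is the C
#' that gets converted).
#'
#' @param z Observed post-conversion nucleotide, one of `"A","C","G","T"`
#'   (vectorized).
#' @param g Epigenotype, one of `"A","C","G","T","M","W"` (scalar).
#' @param r Fragment strand, `"fwd"` or `"rev"` (scalar).
#' @param params A [conversion_params()] object.
#' @return Numeric vector of probabilities, one per element of `z`.
#' @export
#' @examples
#' p <- conversion_params(conversion_rate = 0.95, beta = 0.05)
#' conversion_prob("C", "C", "fwd", p)  # failed conversion: 0.05
#' conversion_prob("T", "M", "fwd", p)  # inappropriate conversion: 0.05
conversion_prob <- function(z, g, r, params = conversion_params()) {
  zi <- .nuc_code(z)
  if (any(zi == 4L)) stop("z must be one of A, C, G, T")
  gi <- .epi_code(g)
  stopifnot(length(gi) == 1L)
  ri <- .strand_code(r)
  stopifnot(length(ri) == 1L)
  m <- .conversion_matrix(ri, params)
  m[zi + 1L, gi + 1L]
}

# 4x6 matrix of P(Z = z | g, r); rows z = A,C,G,T, cols g = A,C,G,T,M,W.
# rho = 0 (fwd) or 1 (rev), rho_hat = 1 - rho.
.conversion_matrix <- function(rho, params) {
  a <- params$alpha_fail
  b <- params$beta
  rh <- 1 - rho
  m <- matrix(0, 4L, 6L, dimnames = list(.NUC, .EPI))
  m["A", "A"] <- 1
  m["T", "T"] <- 1
  m["C", "C"] <- rho + rh * a
  m["T", "C"] <- rh * (1 - a)
  m["G", "G"] <- rh + rho * a
  m["A", "G"] <- rho * (1 - a)
  m["C", "M"] <- 1 - rh * b
  m["T", "M"] <- rh * b
  m["G", "W"] <- 1 - rho * b
  m["A", "W"] <- rho * b
  m
}

#' Sequencing emission probability P(D = d | g, r)
#'
#' Composition of the conversion model with the per-base sequencing error
#' channel: `(1 - 4/3 eps) * P(Z = d | g, r) + eps/3` for `d` among
#' `A,C,G,T`, and 1 for `d = N` (an N carries no information and is
#' likelihood-neutral).
#'
#' @param d Observed base, one of `"A","C","G","T","N"` (vectorized).
#' @param g Epigenotype (scalar; see [conversion_prob()]).
#' @param r Fragment strand, `"fwd"` or `"rev"` (scalar).
#' @param epsilon Per-base error probability, typically from
#'   [phred_to_epsilon()].
#' @param params A [conversion_params()] object.
#' @return Numeric vector of probabilities.
#' @export
emission_prob <- function(d, g, r, epsilon, params = conversion_params()) {
  di <- .nuc_code(d)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0, epsilon <= 0.75)
  gi <- .epi_code(g)
  ri <- .strand_code(r)
  m <- .conversion_matrix(ri, params)
  out <- numeric(length(di))
  isn <- di == 4L
  out[isn] <- 1
  if (any(!isn)) {
    out[!isn] <- (1 - 4 / 3 * epsilon) * m[di[!isn] + 1L, gi + 1L] + epsilon / 3
  }
  out
}

#' Convert a Phred quality score to an error probability
#'
#' `eps = 10^(-q/10)`, clamped to `[1e-6, 0.75]`.  The upper clamp keeps a
#' Phred-0 base (raw error probability 1) inside the range where the
#' emission model remains a proper distribution; the lower clamp avoids
#' exact zeros in log-space.
#'
#' @param q Integer Phred score(s), `q >= 0`.
#' @return Numeric vector of error probabilities.
#' @export
#' @examples
#' phred_to_epsilon(c(10, 30))
phred_to_epsilon <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  pmin(pmax(10^(-q / 10), 1e-6), 0.75)
}

#' Enumerate the error-free observable read pairs
#'
#' With no sequencing errors and perfect bisulfite conversion, a fragment
#' with a given epigenotype produces a deterministic pair of mapped bases:
#' one from a forward-strand read and one from a reverse-strand read.  Only
#' six of the sixteen conceivable base pairs can occur, and the map from
#' epigenotype to pair is invertible.
#'
#' @return A data frame with columns `epigenotype`, `fwd` (base observed in
#'   a forward-strand read), and `rev` (base observed in a reverse-strand
#'   read), one row per epigenotype.
#' @export
enumerate_error_free_observables <- function() {
  p0 <- conversion_params(conversion_rate = 1, beta = 0)
  fwd <- .conversion_matrix(0, p0)
  rev <- .conversion_matrix(1, p0)
  data.frame(
    epigenotype = .EPI,
    fwd = .NUC[apply(fwd, 2L, which.max)],
    rev = .NUC[apply(rev, 2L, which.max)],
    stringsAsFactors = FALSE
  )
}

#' Decode an observed error-free base pair
#'
#' Maximum-likelihood inversion of the error-free observable map: given the
#' two bases observed at one position in two reads known to come from
#' opposite fragment strands (but without knowing which read is which),
#' returns the epigenotype(s) and read-to-strand assignment(s) achieving
#' maximal likelihood under zero error rates.
#'
#' @param base1,base2 Observed bases of the two reads.
#' @return A data frame with columns `epigenotype`, `read1_strand`,
#'   `read2_strand`; more than one row if the strand assignment is
#'   ambiguous (symmetric pairs such as A/A).
#' @export
decode_observable_pair <- function(base1, base2) {
  p0 <- conversion_params(conversion_rate = 1, beta = 0)
  out <- NULL
  for (g in .EPI) {
    for (assign in list(c("fwd", "rev"), c("rev", "fwd"))) {
      lik <- conversion_prob(base1, g, assign[1L], p0) *
        conversion_prob(base2, g, assign[2L], p0)
      if (lik > 0) {
        out <- rbind(out, data.frame(
          epigenotype = g, read1_strand = assign[1L],
          read2_strand = assign[2L], stringsAsFactors = FALSE
        ))
      }
    }
  }
  unique(out)
}
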