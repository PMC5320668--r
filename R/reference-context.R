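# Reference sequence access, CpG/GpC context classification, and the
# genotype prior support set (reference base plus optional known variants).

# Per-position context bit flags.
.CTX <- c(
  CPG_C = 1L, CPG_G = 2L, ISO_CPG_C = 4L, ISO_CPG_G = 8L,
  GPC_G = 16L, GPC_C = 32L, ISO_GPC_G = 64L, ISO_GPC_C = 128L
)

#' Construct a reference window
#'
#' A contiguous stretch of reference sequence over which reads are
#' clustered.  Either pass the sequence directly as a character string, or
#' a path to an (indexed) FASTA file together with a region.
#'
#' @param x A character string of bases over `A,C,G,T,N`, or a path to a
#'   FASTA file (a `.fai` index is created if missing).
#' @param chrom Chromosome/sequence name.  Required when `x` is a FASTA
#'   path; defaults to `"chr"` for literal sequences.
#' @param start 1-based start position of the window on `chrom`.
#' @param end 1-based inclusive end position (FASTA input only; defaults to
#'   the sequence length).
#' @return An object of class `reference_window` with elements `chrom`,
#'   `start`, `end`, `seq` (character scalar), `base` (integer codes),
#'   `context` (bit flags, see [classify_contexts()]), and `allowed`
#'   (per-position logical 4-column matrix of prior-supported nucleotides,
#'   initially the reference base only; see [add_known_variants()]).
#' @export
reference_window <- function(x, chrom = NULL, start = 1L, end = NULL) {
  if (length(x) == 1L && (grepl("\\.(fa|fasta|fna)(\\.gz)?$", x) || file.exists(x))) {
    fa <- Rsamtools::FaFile(x)
    if (!file.exists(paste0(x, ".fai"))) Rsamtools::indexFa(x)
    if (is.null(chrom)) {
      chrom <- as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(fa)))[1L]
    }
    if (is.null(end)) {
      idx <- Rsamtools::scanFaIndex(fa)
      end <- GenomicRanges::end(idx)[match(chrom, as.character(GenomicRanges::seqnames(idx)))]
    }
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    seq <- as.character(Rsamtools::scanFa(fa, gr)[[1L]])
  } else {
    seq <- toupper(as.character(x))
    if (is.null(chrom)) chrom <- "chr"
    if (is.null(end)) end <- start + nchar(seq) - 1L
  }
  base <- .nuc_code(strsplit(seq, "", fixed = TRUE)[[1L]])
  allowed <- matrix(FALSE, length(base), 4L, dimnames = list(NULL, .NUC))
  plain <- base < 4L
  allowed[cbind(which(plain), base[plain] + 1L)] <- TRUE
  allowed[!plain, ] <- TRUE  # reference N: any nucleotide allowed
  w <- structure(
    list(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      seq = seq, base = base, allowed = allowed, n_variants = 0L
    ),
    class = "reference_window"
  )
  w$context <- classify_contexts(w)
  w
}

#' @export
print.reference_window <- function(x, ...) {
  cat(sprintf(
    "<reference_window> %s:%d-%d (%d bp), %d CpG (%d isolated), %d GpC (%d isolated), %d known-variant position(s)\n",
    x$chrom, x$start, x$end, length(x$base),
    sum(bitwAnd(x$context, .CTX["CPG_C"]) > 0L),
    sum(bitwAnd(x$context, .CTX["ISO_CPG_C"]) > 0L),
    sum(bitwAnd(x$context, .CTX["GPC_G"]) > 0L),
    sum(bitwAnd(x$context, .CTX["ISO_GPC_G"]) > 0L),
    x$n_variants
  ))
  invisible(x)
}

#' Classify CpG/GpC contexts of a reference window
#'
#' Labels every CG dinucleotide (both its C and its G position) and every
#' GC dinucleotide.  A CpG is isolated when its four-base context is HCGD
#' (H = not G, D = not C); a GpC is isolated when the context is DGCH.
#' Isolation distinguishes endogenous CpG methylation from enzymatic GpC
#' methylation in NOMe-seq data.  Positions too close to the window edge
#' for a full context, or with an N in the context, are labeled
#' non-isolated.
#'
#' @param window A [reference_window()] (or plain character sequence).
#' @return Integer vector of per-position bit flags with bits `CPG_C = 1`,
#'   `CPG_G = 2`, `ISO_CPG_C = 4`, `ISO_CPG_G = 8`, `GPC_G = 16`,
#'   `GPC_C = 32`, `ISO_GPC_G = 64`, `ISO_GPC_C = 128`.
#' @export
#' @examples
#' classify_contexts("ACGT")  # isolated CpG at positions 2-3
classify_contexts <- function(window) {
  b <- if (inherits(window, "reference_window")) {
    window$base
  } else {
    .nuc_code(strsplit(toupper(as.character(window)), "", fixed = TRUE)[[1L]])
  }
  n <- length(b)
  ctx <- integer(n)
  if (n < 2L) return(ctx)
  j <- seq_len(n - 1L)
  # codes: A=0 C=1 G=2 T=3 N=4
  cg <- which(b[j] == 1L & b[j + 1L] == 2L)
  gc <- which(b[j] == 2L & b[j + 1L] == 1L)
  ctx[cg] <- bitwOr(ctx[cg], .CTX[["CPG_C"]])
  ctx[cg + 1L] <- bitwOr(ctx[cg + 1L], .CTX[["CPG_G"]])
  ctx[gc] <- bitwOr(ctx[gc], .CTX[["GPC_G"]])
  ctx[gc + 1L] <- bitwOr(ctx[gc + 1L], .CTX[["GPC_C"]])
  # HCGD: preceded by H (not G, not N), followed by D (not C, not N)
  iso_cg <- cg[cg > 1L & cg + 2L <= n &
    !(b[pmax(cg - 1L, 1L)] %in% c(2L, 4L)) &
    !(b[pmin(cg + 2L, n)] %in% c(1L, 4L))]
  # DGCH: preceded by D (not C, not N), followed by H (not G, not N)
  iso_gc <- gc[gc > 1L & gc + 2L <= n &
    !(b[pmax(gc - 1L, 1L)] %in% c(1L, 4L)) &
    !(b[pmin(gc + 2L, n)] %in% c(2L, 4L))]
  ctx[iso_cg] <- bitwOr(ctx[iso_cg], .CTX[["ISO_CPG_C"]])
  ctx[iso_cg + 1L] <- bitwOr(ctx[iso_cg + 1L], .CTX[["ISO_CPG_G"]])
  ctx[iso_gc] <- bitwOr(ctx[iso_gc], .CTX[["ISO_GPC_G"]])
  ctx[iso_gc + 1L] <- bitwOr(ctx[iso_gc + 1L], .CTX[["ISO_GPC_C"]])
  ctx
}

#' Test context flags at positions
#'
#' @param window A [reference_window()].
#' @param flag One of `"CPG_C"`, `"CPG_G"`, `"ISO_CPG_C"`, `"ISO_CPG_G"`,
#'   `"GPC_G"`, `"GPC_C"`, `"ISO_GPC_G"`, `"ISO_GPC_C"`.
#' @param pos Genomic positions (default: all window positions).
#' @return Logical vector.
#' @export
has_context <- function(window, flag, pos = NULL) {
  flag <- match.arg(flag, names(.CTX))
  ctx <- window$context
  if (!is.null(pos)) ctx <- ctx[pos - window$start + 1L]
  bitwAnd(ctx, .CTX[[flag]]) > 0L
}

#' Add known variants to the genotype prior support
#'
#' Extends the per-position set of prior-supported nucleotides with known
#' alternate alleles (emulating a reference SNP database).  Only SNV
#' records are used; indels and multi-nucleotide records are skipped with
#' a message.
#'
#' @param window A [reference_window()].
#' @param variants Either a path to a VCF file or a data frame with columns
#'   `pos` (1-based genomic position), `ref`, and `alt` (single bases; `alt`
#'   may be comma-separated).
#' @return The window with its `allowed` matrix extended and `n_variants`
#'   updated.
#' @export
add_known_variants <- function(window, variants) {
  stopifnot(inherits(window, "reference_window"))
  if (is.character(variants) && length(variants) == 1L) {
    v <- vcfR::read.vcfR(variants, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    variants <- data.frame(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
    )
    variants <- variants[variants$chrom == window$chrom, , drop = FALSE]
  }
  n_used <- 0L
  n_skip <- 0L
  for (k in seq_len(nrow(variants))) {
    pos <- variants$pos[k]
    if (pos < window$start || pos > window$end) next
    alts <- strsplit(variants$alt[k], ",", fixed = TRUE)[[1L]]
    if (nchar(variants$ref[k]) != 1L || any(nchar(alts) != 1L)) {
      n_skip <- n_skip + 1L
      next
    }
    alts <- alts[alts %in% .NUC]
    if (!length(alts)) next
    i <- pos - window$start + 1L
    window$allowed[i, alts] <- TRUE
    n_used <- n_used + 1L
  }
  if (n_skip > 0L) {
    message(n_skip, " non-SNV variant record(s) skipped")
  }
  window$n_variants <- window$n_variants + n_used
  window
}

#' Genotype prior indicator
#'
#' Returns 1 when the queried nucleotide at a position is in the prior
#' support set (reference base plus known variants when in use), else 0.
#' With `use_db = FALSE` only the reference base is supported.  Positions
#' with a reference N support any nucleotide.
#'
#' @param window A [reference_window()], possibly after
#'   [add_known_variants()].
#' @param pos 1-based genomic position(s) inside the window.
#' @param nucleotide Nucleotide(s) among `"A","C","G","T"`.
#' @param use_db Whether the known-variant set participates (default TRUE).
#' @return Integer vector of 0/1.
#' @export
prior_indicator <- function(window, pos, nucleotide, use_db = TRUE) {
  stopifnot(inherits(window, "reference_window"))
  if (any(pos < window$start | pos > window$end)) {
    stop("position outside window")
  }
  i <- pos - window$start + 1L
  ni <- .nuc_code(nucleotide)
  if (any(ni == 4L)) stop("nucleotide must be one of A, C, G, T")
  if (use_db) {
    as.integer(window$allowed[cbind(i, ni + 1L)])
  } else {
    refb <- window$base[i]
    as.integer(refb == 4L | refb == ni)
  }
}

# Per-position allowed-nucleotide matrix respecting use_db (internal).
.prior_allowed <- function(window, use_db) {
  if (use_db) return(window$allowed)
  allowed <- matrix(FALSE, length(window$base), 4L, dimnames = list(NULL, .NUC))
  plain <- window$base < 4L
  allowed[cbind(which(plain), window$base[plain] + 1L)] <- TRUE
  allowed[!plain, ] <- TRUE
  allowed
}

#' Reverse complement of a sequence string
#'
#' @param seq Character scalar over `A,C,G,T,N`.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
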