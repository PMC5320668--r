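# Read units: a mapped read (or mate pair) with per-base observed
# nucleotides and Phred-derived error probabilities.

#' Construct a read unit
#'
#' A read unit is one mapped read, or a properly paired mate pair treated
#' as a single inference unit (mates share a fragment strand and move
#' between chains together).  Alignments are strictly columnar: each base
#' sits at one genomic position (reads with indels or clipping are
#' excluded at load time).
#'
#' @param id Read name.
#' @param starts Integer vector of 1-based genomic start positions, one per
#'   segment (one segment for a single-end read, two for a mate pair).
#' @param bases Character vector of base strings over `A,C,G,T,N`, one per
#'   segment.
#' @param epsilon Per-base error probabilities: a single value, one value
#'   per segment, or a list of per-base vectors.
#' @return An object of class `read_unit` with elements `id`, `pos`
#'   (genomic position of every base), `base` (integer codes), `eps`,
#'   `segs` (segment start/end matrix), `lo`/`hi` (footprint span), and
#'   `n_bases`.
#' @export
#' @examples
#' read_unit("r1", 101L, "ACGT", 0.01)
read_unit <- function(id, starts, bases, epsilon = 0.001) {
  stopifnot(length(starts) == length(bases), length(bases) >= 1L)
  starts <- as.integer(starts)
  if (!is.list(epsilon)) {
    epsilon <- if (length(epsilon) == 1L) {
      lapply(nchar(bases), function(n) rep(epsilon, n))
    } else {
      as.list(epsilon)
    }
  }
  pos <- integer(0)
  base <- integer(0)
  eps <- numeric(0)
  seg_base <- vector("list", length(starts))
  seg_eps <- vector("list", length(starts))
  segs <- matrix(0L, length(starts), 2L, dimnames = list(NULL, c("start", "end")))
  for (k in seq_along(starts)) {
    bk <- .nuc_code(strsplit(toupper(bases[k]), "", fixed = TRUE)[[1L]])
    ek <- rep_len(epsilon[[k]], length(bk))
    stopifnot(all(ek > 0), all(ek <= 0.75))
    pos <- c(pos, seq.int(starts[k], length.out = length(bk)))
    base <- c(base, bk)
    eps <- c(eps, ek)
    seg_base[[k]] <- bk
    seg_eps[[k]] <- ek
    segs[k, ] <- c(starts[k], starts[k] + length(bk) - 1L)
  }
  o <- order(pos)
  structure(
    list(
      id = as.character(id), pos = pos[o], base = base[o], eps = eps[o],
      segs = segs, seg_base = seg_base, seg_eps = seg_eps,
      lo = min(segs[, 1L]), hi = max(segs[, 2L]),
      n_bases = length(pos)
    ),
    class = "read_unit"
  )
}

#' Collect read units
#'
#' @param units List of [read_unit()] objects.
#' @param chrom Chromosome name the units are mapped to.
#' @return An object of class `methaplo_reads` (a list with elements
#'   `units` and `chrom`), ordered by genomic start.
#' @export
methaplo_reads <- function(units, chrom = "chr") {
  stopifnot(all(vapply(units, inherits, logical(1L), "read_unit")))
  lo <- vapply(units, function(u) u$lo, integer(1L))
  units <- units[order(lo)]
  structure(list(units = units, chrom = chrom), class = "methaplo_reads")
}

#' @export
print.methaplo_reads <- function(x, ...) {
  n <- length(x$units)
  if (n == 0L) {
    cat("<methaplo_reads> 0 read units\n")
    return(invisible(x))
  }
  lo <- min(vapply(x$units, function(u) u$lo, integer(1L)))
  hi <- max(vapply(x$units, function(u) u$hi, integer(1L)))
  nb <- sum(vapply(x$units, function(u) u$n_bases, integer(1L)))
  npair <- sum(vapply(x$units, function(u) nrow(u$segs), integer(1L)) == 2L)
  cat(sprintf(
    "<methaplo_reads> %d read units (%d paired) on %s:%d-%d, %d bases\n",
    n, npair, x$chrom, lo, hi, nb
  ))
  invisible(x)
}

#' @export
length.methaplo_reads <- function(x) length(x$units)

# Flatten units for the C++ engine: list of list(pos, base, eps) plus
# per-unit footprint segment matrices.
.flatten_units <- function(reads) {
  lapply(reads$units, function(u) {
    list(
      pos = as.integer(u$pos), base = as.integer(u$base),
      eps = as.numeric(u$eps), segs = matrix(as.integer(u$segs), ncol = 2L)
    )
  })
}
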