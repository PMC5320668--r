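# Synthetic bisulfite/NOMe read generator with full ground truth.  The
# generative process mirrors the observation model exactly: per-fragment
# epi-allele and strand choice, bisulfite conversion with failed and
# inappropriate conversion rates, and a per-base Phred sequencing error
# channel.  Uses R's RNG: call set.seed() (or pass `seed`) to reproduce.

#' Specify an epi-allele
#'
#' @param freq Population frequency of the allele.
#' @param meth Logical vector: methylation state of each reference CpG of
#'   the window (in genomic order), or a single value recycled.
#' @param accessible Logical vector: accessibility (enzymatic GpC
#'   methylation) of each reference isolated GpC, or a single value
#'   recycled.  NOMe mode only.
#' @param snv Named character vector of single-nucleotide overrides,
#'   names are 1-based genomic positions.
#' @return An object of class `epiallele`.
#' @export
#' @examples
#' epiallele(0.5, meth = TRUE, snv = c("1575" = "T"))
epiallele <- function(freq, meth = FALSE, accessible = TRUE, snv = NULL) {
  stopifnot(freq >= 0, freq <= 1)
  structure(
    list(freq = freq, meth = meth, accessible = accessible, snv = snv),
    class = "epiallele"
  )
}

# Per-position epigenotype codes (0..5) of an allele over the window.
.allele_epigenotype <- function(window, allele, nome = FALSE) {
  epi <- window$base # plain nucleotides to start with (N stays 4 -> treated as A? no: keep)
  epi[epi == 4L] <- 0L # reference N: simulate as A
  if (!is.null(allele$snv)) {
    pos <- as.integer(names(allele$snv))
    epi[pos - window$start + 1L] <- .nuc_code(unname(allele$snv))
  }
  n <- length(epi)
  # CpGs of the allele sequence that coincide with reference CpGs
  cpg_ref <- which(bitwAnd(window$context, .CTX[["CPG_C"]]) > 0L)
  cpg <- cpg_ref[epi[cpg_ref] == 1L & epi[pmin(cpg_ref + 1L, n)] == 2L]
  meth <- rep_len(allele$meth, length(cpg_ref))[match(cpg, cpg_ref)]
  mcpg <- cpg[meth]
  epi[mcpg] <- 4L       # meC
  epi[mcpg + 1L] <- 5L  # meG
  if (nome) {
    gpc_ref <- which(bitwAnd(window$context, .CTX[["ISO_GPC_G"]]) > 0L)
    gpc <- gpc_ref[epi[gpc_ref] == 2L & epi[pmin(gpc_ref + 1L, n)] == 1L]
    acc <- rep_len(allele$accessible, length(gpc_ref))[match(gpc, gpc_ref)]
    agpc <- gpc[acc]
    epi[agpc] <- 5L       # meG
    epi[agpc + 1L] <- 4L  # meC
  }
  epi
}

#' Generate a random reference window
#'
#' Produces a random sequence with an approximately requested CpG (and
#' optionally GpC) density by planting CG (GC) dinucleotides among random
#' background bases chosen so that no unplanned motif arises; with
#' density 0 the sequence contains no CG at all.  Alternatively a literal
#' sequence is passed through unchanged.
#'
#' @param length Window length in bp (ignored when `seq` is given).
#' @param cpg_density Expected CG dinucleotides per bp, in `[0, 0.5]`.
#' @param gpc_density Expected GC dinucleotides per bp, or `NULL` to leave
#'   GC occurrence to the random background.
#' @param seq Optional literal sequence (passthrough).
#' @param chrom,start Window coordinates.
#' @param seed Optional RNG seed.
#' @return A [reference_window()].
#' @export
make_reference <- function(length = 1000L, cpg_density = 0.02,
                           gpc_density = NULL, seq = NULL,
                           chrom = "chr", start = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(seq)) {
    return(reference_window(seq, chrom = chrom, start = start))
  }
  stopifnot(cpg_density >= 0, cpg_density <= 0.5)
  theta_cg <- cpg_density / (1 - cpg_density)
  theta_gc <- if (is.null(gpc_density)) 0 else gpc_density / (1 - gpc_density)
  out <- character(length)
  i <- 1L
  prev <- ""
  while (i <= length) {
    u <- stats::runif(1)
    if (i < length && u < theta_cg) {
      out[i] <- "C"; out[i + 1L] <- "G"
      prev <- "G"; i <- i + 2L
    } else if (i < length && !is.null(gpc_density) && u < theta_cg + theta_gc) {
      out[i] <- "G"; out[i + 1L] <- "C"
      prev <- "C"; i <- i + 2L
    } else {
      cand <- c("A", "C", "G", "T")
      if (prev == "C") cand <- setdiff(cand, "G")
      if (!is.null(gpc_density) && prev == "G") cand <- setdiff(cand, "C")
      b <- sample(cand, 1L)
      out[i] <- b; prev <- b; i <- i + 1L
    }
  }
  reference_window(paste(out, collapse = ""), chrom = chrom, start = start)
}

#' Simulate bisulfite reads from epi-alleles
#'
#' For each fragment, an allele is chosen by frequency, the fragment
#' strand uniformly, and the start uniformly over the window; every
#' covered base is then passed through the bisulfite conversion model
#' (failed-conversion rate `1 - conversion_rate`, inappropriate rate
#' `beta`) and the sequencing error channel at the given Phred quality,
#' and emitted as a forward-mapped read exactly as a bisulfite mapper
#' would present it.
#'
#' @param window A [reference_window()].
#' @param alleles List of [epiallele()] objects; frequencies must sum
#'   to 1.
#' @param depth Mean read depth (bases per position).
#' @param read_len Read length in bp.
#' @param layout `"single"` or `"paired"`.
#' @param insert Fragment span in bp for paired layout (mates are the two
#'   ends of the fragment, on the same strand).
#' @param conversion_rate,beta Conversion parameters (see
#'   [conversion_params()]).
#' @param phred Constant Phred quality of every base, or a vector of
#'   length `read_len` for a per-cycle profile.
#' @param nome Simulate NOMe-seq (apply the alleles' GpC accessibility).
#' @param seed Optional RNG seed.
#' @return An object of class `methaplo_sim`: a list with `reads`
#'   ([methaplo_reads()]), `truth` (data frame: read id, allele,
#'   fragment strand), `alleles`, `epi` (per-allele true epigenotype
#'   codes), and `window`.
#' @export
simulate_reads <- function(window, alleles, depth = 20, read_len = 100L,
                           layout = c("paired", "single"), insert = 180L,
                           conversion_rate = 0.95, beta = 0.05, phred = 30,
                           nome = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layout <- match.arg(layout)
  stopifnot(inherits(window, "reference_window"))
  freqs <- vapply(alleles, function(a) a$freq, numeric(1L))
  stopifnot(abs(sum(freqs) - 1) < 1e-8)
  params <- conversion_params(conversion_rate, beta)
  L <- length(window$base)
  span <- if (layout == "paired") insert else read_len
  stopifnot(span <= L, !(layout == "paired" && insert < read_len))
  frag_bases <- if (layout == "paired") 2L * read_len else read_len
  n_frag <- max(1L, ceiling(depth * L / frag_bases))
  epi <- lapply(alleles, function(a) .allele_epigenotype(window, a, nome))
  cm <- list(
    apply(.conversion_matrix(0, params), 2L, cumsum),
    apply(.conversion_matrix(1, params), 2L, cumsum)
  )
  eps_profile <- phred_to_epsilon(rep_len(phred, read_len))

  frag_allele <- sample.int(length(alleles), n_frag, replace = TRUE, prob = freqs)
  frag_strand <- sample(c(0L, 1L), n_frag, replace = TRUE)
  frag_start <- window$start + sample.int(L - span + 1L, n_frag, replace = TRUE) - 1L

  sim_segment <- function(start, allele, rho) {
    idx <- (start:(start + read_len - 1L)) - window$start + 1L
    g <- epi[[allele]][idx]
    cmx <- t(cm[[rho + 1L]])[g + 1L, , drop = FALSE]
    z <- rowSums(stats::runif(read_len) > cmx)
    err <- stats::runif(read_len) < eps_profile
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      z[err] <- (z[err] + shift[seq_len(sum(err))]) %% 4L
    }
    paste(.NUC[z + 1L], collapse = "")
  }

  units <- vector("list", n_frag)
  for (f in seq_len(n_frag)) {
    id <- sprintf("frag%05d", f)
    if (layout == "single") {
      units[[f]] <- read_unit(
        id, frag_start[f],
        sim_segment(frag_start[f], frag_allele[f], frag_strand[f]),
        list(eps_profile)
      )
    } else {
      s2 <- frag_start[f] + insert - read_len
      units[[f]] <- read_unit(
        id, c(frag_start[f], s2),
        c(
          sim_segment(frag_start[f], frag_allele[f], frag_strand[f]),
          sim_segment(s2, frag_allele[f], frag_strand[f])
        ),
        list(eps_profile, eps_profile)
      )
    }
  }
  reads <- methaplo_reads(units, chrom = window$chrom)
  ids <- vapply(reads$units, function(u) u$id, character(1L))
  o <- match(ids, sprintf("frag%05d", seq_len(n_frag)))
  structure(
    list(
      reads = reads,
      truth = data.frame(
        id = ids, allele = frag_allele[o],
        strand = c("fwd", "rev")[frag_strand[o] + 1L],
        stringsAsFactors = FALSE
      ),
      alleles = alleles, epi = epi, window = window,
      params = params, layout = layout, nome = nome
    ),
    class = "methaplo_sim"
  )
}

#' @export
print.methaplo_sim <- function(x, ...) {
  cat(sprintf(
    "<methaplo_sim> %d read units from %d epi-allele(s) on %s:%d-%d (%s%s)\n",
    length(x$reads$units), length(x$alleles), x$window$chrom,
    x$window$start, x$window$end, x$layout, if (x$nome) ", NOMe" else ""
  ))
  invisible(x)
}

#' Method-of-moments estimates of the conversion rates
#'
#' Closes the loop on the conversion model: from forward-strand reads at
#' reference CpG C positions with known (simulated) methylation state,
#' estimates the failed-conversion rate as the fraction of C calls at
#' unmethylated sites, and the inappropriate-conversion rate as the
#' fraction of T calls at methylated sites.  Intended for `epsilon = 0`
#' (very high Phred) simulations.
#'
#' @param sim A `methaplo_sim` from [simulate_reads()].
#' @return List with `alpha_fail`, `beta`, and the site counts
#'   `n_unmeth`, `n_meth` (estimates are `NA` when a count is zero).
#' @export
empirical_conversion_rates <- function(sim) {
  win <- sim$window
  cpg_c <- which(bitwAnd(win$context, .CTX[["CPG_C"]]) > 0L)
  nC_u <- nT_u <- nC_m <- nT_m <- 0L
  for (k in seq_along(sim$reads$units)) {
    if (sim$truth$strand[k] != "fwd") next
    u <- sim$reads$units[[k]]
    epi <- sim$epi[[sim$truth$allele[k]]]
    idx <- u$pos - win$start + 1L
    at_cpg <- idx %in% cpg_c
    if (!any(at_cpg)) next
    g <- epi[idx[at_cpg]]
    d <- u$base[at_cpg]
    un <- g == 1L # plain C
    me <- g == 4L # meC
    nC_u <- nC_u + sum(un & d == 1L)
    nT_u <- nT_u + sum(un & d == 3L)
    nC_m <- nC_m + sum(me & d == 1L)
    nT_m <- nT_m + sum(me & d == 3L)
  }
  list(
    alpha_fail = if (nC_u + nT_u > 0L) nC_u / (nC_u + nT_u) else NA_real_,
    beta = if (nC_m + nT_m > 0L) nT_m / (nC_m + nT_m) else NA_real_,
    n_unmeth = nC_u + nT_u, n_meth = nC_m + nT_m
  )
}
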