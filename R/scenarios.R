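# Canned simulation scenarios used for validation: an allele-specific
# methylation (ASM) region, its homogeneous counterpart, a NOMe-seq
# protected block, and small random instances for optimizer checks.
# Conditions are fixed here so that validation runs are reproducible
# functions of the seed alone.

# 3 kb reference whose 30 CpGs form a central CpG island (C positions
# 850, 895, ..., 2155: one CpG per 45 bp, a typical island density),
# plus an A at the SNV position.  An island mirrors real ASM regions
# (imprinted DMRs sit in CpG islands); the locally dense CpGs give every
# overlapping fragment several methylation-informative positions, which
# both satisfies the two-CpG feasibility rule and keeps discordant
# epi-alleles apart.
.asm_reference <- function(L = 3000L, cpg_spacing = 45L, snv_pos = 1575L) {
  bases <- character(L)
  prev <- ""
  for (i in seq_len(L)) {
    cand <- c("A", "C", "G", "T")
    if (prev == "C") cand <- setdiff(cand, "G")
    b <- sample(cand, 1L)
    bases[i] <- b
    prev <- b
  }
  cpg_c <- seq.int(850L, by = cpg_spacing, length.out = 30L)
  bases[cpg_c] <- "C"
  bases[cpg_c + 1L] <- "G"
  # no accidental CG at the plant borders: a C right before a planted C is
  # harmless, a G right after a planted G is harmless
  bases[snv_pos] <- "A"
  win <- reference_window(paste(bases, collapse = ""))
  attr(win, "cpg_c") <- cpg_c
  attr(win, "snv_pos") <- snv_pos
  win
}

#' Simulate an allele-specific methylated region
#'
#' Two epi-alleles at equal frequency over a 3 kb window whose 30 CpGs
#' form a central CpG island (one CpG per 45 bp over ~1.3 kb): one allele
#' fully methylated, the other fully unmethylated and carrying one
#' distinguishing SNV (A>T, chosen so it cannot create or destroy a
#' CpG/GpC context).  Paired 100 bp reads with a 220 bp fragment span at
#' total depth 20, conversion rate 0.95, inappropriate-conversion rate
#' 0.05, Phred 30.
#'
#' @param seed RNG seed.
#' @param n_alleles 2 for the ASM region, 1 for a homogeneous (fully
#'   methylated) region with the same geometry.
#' @param depth Total read depth.
#' @return A `methaplo_sim` with attributes `cpg_c` (CpG C positions)
#'   and `snv_pos`.
#' @export
sim_asm_scenario <- function(seed, n_alleles = 2L, depth = 20) {
  set.seed(seed)
  win <- .asm_reference()
  snv_pos <- attr(win, "snv_pos")
  alleles <- if (n_alleles == 2L) {
    list(
      epiallele(0.5, meth = TRUE),
      epiallele(0.5, meth = FALSE, snv = stats::setNames("T", snv_pos))
    )
  } else {
    list(epiallele(1, meth = TRUE))
  }
  sim <- simulate_reads(
    win, alleles,
    depth = depth, read_len = 100L, layout = "paired", insert = 220L,
    conversion_rate = 0.95, beta = 0.05, phred = 30
  )
  attr(sim, "cpg_c") <- attr(win, "cpg_c")
  attr(sim, "snv_pos") <- snv_pos
  sim
}

#' Simulate a NOMe-seq region with a protected block
#'
#' An 800 bp CG-free reference built from a 10 bp repeat carrying one
#' isolated GpC every 10 bp; a single epi-allele accessible everywhere
#' except a central 147 bp block (a nucleosome/protein footprint) whose
#' GpCs are unmethylated.  Paired 100 bp reads at depth 30.
#'
#' @param seed RNG seed.
#' @param block_start,block_len Protected block (defaults 327 and 147).
#' @param depth Total read depth.
#' @return A `methaplo_sim` with attributes `block` (true inaccessible
#'   interval) and `gpc_g` (isolated GpC G positions).
#' @export
sim_nome_scenario <- function(seed, block_start = 327L, block_len = 147L,
                              depth = 30) {
  set.seed(seed)
  win <- reference_window(strrep("TGCAATTAGA", 80L))
  gpc_g <- which(bitwAnd(win$context, .CTX[["ISO_GPC_G"]]) > 0L)
  block <- c(block_start, block_start + block_len - 1L)
  acc <- !(gpc_g >= block[1L] & gpc_g <= block[2L])
  sim <- simulate_reads(
    win, list(epiallele(1, meth = FALSE, accessible = acc)),
    depth = depth, read_len = 100L, layout = "paired", insert = 180L,
    conversion_rate = 0.95, beta = 0.05, phred = 30, nome = TRUE
  )
  attr(sim, "block") <- block
  attr(sim, "gpc_g") <- gpc_g
  sim
}

#' Simulate a small random instance for optimizer checks
#'
#' A short random window with planted CpGs, one or two random
#' epi-alleles, and a handful of single-end reads; sized so that the
#' exhaustive-search oracle remains tractable.
#'
#' @param seed RNG seed.
#' @param n_reads Number of reads.
#' @param window_len Window length in bp.
#' @param read_len Read length (recycled-sampled range allowed).
#' @param cpg_density Planted CpG density.
#' @param phred Constant base quality.
#' @return List with `reads`, `window`, `config`, and the `sim` object.
#' @export
sim_random_instance <- function(seed, n_reads = 4L, window_len = 80L,
                                read_len = c(40L, 60L), cpg_density = 0.08,
                                phred = 20) {
  set.seed(seed)
  win <- make_reference(length = window_len, cpg_density = cpg_density)
  n_alleles <- sample(1:2, 1L)
  freqs <- if (n_alleles == 1L) 1 else c(0.5, 0.5)
  n_cpg <- sum(bitwAnd(win$context, .CTX[["CPG_C"]]) > 0L)
  alleles <- lapply(freqs, function(f) {
    epiallele(f, meth = sample(c(TRUE, FALSE), max(n_cpg, 1L), replace = TRUE))
  })
  rl <- if (length(read_len) == 2L) sample(read_len[1L]:read_len[2L], 1L) else read_len
  sim <- simulate_reads(
    win, alleles,
    depth = 1, read_len = rl, layout = "single",
    conversion_rate = 0.95, beta = 0.05, phred = phred
  )
  # resample to the requested number of reads
  starts <- win$start + sample.int(window_len - rl + 1L, n_reads, replace = TRUE) - 1L
  units <- vector("list", n_reads)
  epi <- sim$epi
  allele <- sample.int(n_alleles, n_reads, replace = TRUE, prob = freqs)
  strand <- sample(c(0L, 1L), n_reads, replace = TRUE)
  params <- conversion_params(0.95, 0.05)
  cm <- list(
    apply(.conversion_matrix(0, params), 2L, cumsum),
    apply(.conversion_matrix(1, params), 2L, cumsum)
  )
  eps <- phred_to_epsilon(phred)
  for (f in seq_len(n_reads)) {
    idx <- (starts[f]:(starts[f] + rl - 1L)) - win$start + 1L
    g <- epi[[allele[f]]][idx]
    cmx <- t(cm[[strand[f] + 1L]])[g + 1L, , drop = FALSE]
    z <- rowSums(stats::runif(rl) > cmx)
    err <- stats::runif(rl) < eps
    if (any(err)) z[err] <- (z[err] + sample.int(3L, sum(err), replace = TRUE)) %% 4L
    units[[f]] <- read_unit(
      sprintf("r%03d", f), starts[f],
      paste(.NUC[z + 1L], collapse = ""), eps
    )
  }
  list(
    reads = methaplo_reads(units, chrom = win$chrom),
    window = win,
    config = methaplo_config("wgbs-single"),
    truth = data.frame(allele = allele, strand = c("fwd", "rev")[strand + 1L])
  )
}
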