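# Standard-format IO and the end-to-end pipeline driver.

#' Load bisulfite-mapped alignments as read units
#'
#' Reads alignments overlapping a region from a coordinate-sorted BAM (or
#' SAM, converted on the fly) file.  Only ungapped, unclipped alignments
#' are usable (the model is strictly columnar); reads with indels or
#' clipping are skipped and counted.  In paired mode, mates are joined
#' into single read units by name and reads not properly paired are
#' removed.  Base qualities are converted to per-base error
#' probabilities.
#'
#' @param path Path to a BAM or SAM file.
#' @param chrom Chromosome name of the region.
#' @param start,end 1-based inclusive region bounds.
#' @param paired Join proper pairs into units (default from mode).
#' @return A [methaplo_reads()] object; skipped-read counts are attached
#'   as attribute `skipped`.
#' @export
load_alignments <- function(path, chrom, start, end, paired = TRUE) {
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
    !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
  if (!chrom %in% names(hdr)) stop("region chromosome not in alignment header")
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end)),
    what = c("qname", "flag", "pos", "cigar", "seq", "qual")
  )
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  n <- length(b$qname)
  skipped <- c(cigar = 0L, unpaired = 0L)
  keep <- rep(TRUE, n)
  ok_cigar <- grepl("^\\d+M$", b$cigar)
  skipped["cigar"] <- sum(!ok_cigar)
  keep <- keep & ok_cigar
  flags <- b$flag
  is_paired <- bitwAnd(flags, 1L) > 0L
  if (paired) {
    proper <- bitwAnd(flags, 2L) > 0L
    bad <- is_paired & !proper
    skipped["unpaired"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  idx <- which(keep)
  qname <- b$qname[idx]
  units <- list()
  seqs <- as.character(b$seq[idx])
  quals <- as(b$qual[idx], "IntegerList")
  for (grp in split(seq_along(idx), qname)) {
    i <- idx[grp]
    o <- order(b$pos[i])
    grp <- grp[o]
    i <- i[o]
    units[[length(units) + 1L]] <- read_unit(
      b$qname[i[1L]], b$pos[i], seqs[grp],
      lapply(grp, function(k) phred_to_epsilon(quals[[k]]))
    )
  }
  out <- methaplo_reads(units, chrom = chrom)
  if (sum(skipped) > 0L) {
    message(sprintf(
      "skipped %d read(s) with indels/clipping, %d improperly paired",
      skipped[["cigar"]], skipped[["unpaired"]]
    ))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write read units as SAM
#'
#' Emits coordinate-sorted, forward-mapped SAM records (one per segment;
#' mate pairs get proper-pair flags).  Qualities are reconstructed from
#' the stored error probabilities.
#'
#' @param reads A [methaplo_reads()] (or a `methaplo_sim`, whose reads
#'   are used).
#' @param path Output path (`.sam`).
#' @param ref_len Reference sequence length for the header (default: max
#'   read end).
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, path, ref_len = NULL) {
  if (inherits(reads, "methaplo_sim")) reads <- reads$reads
  stopifnot(inherits(reads, "methaplo_reads"))
  if (is.null(ref_len)) {
    ref_len <- max(vapply(reads$units, function(u) u$hi, integer(1L)), 1L)
  }
  recs <- list()
  for (u in reads$units) {
    nseg <- nrow(u$segs)
    for (k in seq_len(nseg)) {
      seq <- paste(c(.NUC, "N")[u$seg_base[[k]] + 1L], collapse = "")
      q <- round(-10 * log10(u$seg_eps[[k]]))
      qual <- intToUtf8(pmin(q, 93L) + 33L)
      if (nseg == 1L) {
        flag <- 0L
        rnext <- "*"
        pnext <- 0L
        tlen <- 0L
      } else {
        flag <- if (k == 1L) 99L else 147L
        rnext <- "="
        pnext <- u$segs[-k, 1L][1L]
        tlen <- (u$hi - u$lo + 1L) * (if (k == 1L) 1L else -1L)
      }
      recs[[length(recs) + 1L]] <- list(
        pos = u$segs[k, 1L],
        line = paste(
          u$id, flag, reads$chrom, u$segs[k, 1L], 60L,
          paste0(nchar(seq), "M"), rnext, pnext, tlen, seq, qual,
          sep = "\t"
        )
      )
    }
  }
  o <- order(vapply(recs, function(r) r$pos, numeric(1L)))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", reads$chrom, "\tLN:", ref_len),
    vapply(recs[o], function(r) r$line, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference window as FASTA (with index)
#'
#' @param window A [reference_window()].  The window must start at
#'   position 1 for the FASTA coordinates to match.
#' @param path Output path (`.fa`).
#' @return The path, invisibly.
#' @export
write_fasta <- function(window, path) {
  s <- Biostrings::DNAStringSet(window$seq)
  names(s) <- window$chrom
  Biostrings::writeXStringSet(s, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Write simulated SNVs as VCF
#'
#' @param window A [reference_window()].
#' @param snv Named character vector (position -> alternate base).
#' @param path Output path (`.vcf`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(window, snv, path) {
  pos <- as.integer(names(snv))
  ref <- substring(window$seq, pos - window$start + 1L, pos - window$start + 1L)
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", window$chrom, ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste(window$chrom, pos, ".", ref, unname(snv), ".", "PASS", ".", sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the output tables of a fit
#'
#' Emits the chains table (TSV), the read-assignment table (TSV), the
#' methylation call table (TSV), the chain spans (BED, 0-based
#' half-open), for NOMe fits the accessibility consensus (bedGraph), and
#' a JSON run report (log-posterior trajectory, chain counts before and
#' after filtering, parameter echo).
#'
#' @param fit A `methaplo_fit` (ideally after [filter_chains()]).
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(fit, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ct <- chains(fit)
  f <- paste0(prefix, ".chains.tsv")
  utils::write.table(ct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  ra <- data.frame(
    read = vapply(fit$reads$units, function(u) u$id, character(1L)),
    chain = fit$chain_of, strand = fit$strand, stringsAsFactors = FALSE
  )
  f <- paste0(prefix, ".reads.tsv")
  utils::write.table(ra, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  mc <- methylation_calls(fit)
  f <- paste0(prefix, ".calls.tsv")
  utils::write.table(mc, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  bed <- ct[ct$kept, , drop = FALSE]
  f <- paste0(prefix, ".chains.bed")
  writeLines(
    sprintf("%s\t%d\t%d\tchain%d\t%d\t.", bed$chrom, bed$start - 1L, bed$end,
      bed$chain, pmin(bed$n_reads, 1000L)),
    f
  )
  files <- c(files, f)

  if (fit$config$mode == "nome") {
    acc <- accessibility(fit)
    f <- paste0(prefix, ".accessibility.bedGraph")
    ok <- !is.na(acc$sites$read_consensus)
    writeLines(
      c(
        "track type=bedGraph name=gpc_accessibility",
        sprintf(
          "%s\t%d\t%d\t%.4f", acc$sites$chrom[ok], acc$sites$pos[ok] - 1L,
          acc$sites$pos[ok], acc$sites$read_consensus[ok]
        )
      ),
      f
    )
    files <- c(files, f)
  }

  report <- list(
    mode = fit$config$mode,
    n_reads = length(fit$reads$units),
    n_chains = length(fit$chains),
    n_chains_kept = if (is.null(fit$kept)) length(fit$chains) else sum(fit$kept),
    logLik = fit$logLik,
    trajectory = fit$trajectory,
    passes = fit$passes,
    converged = fit$converged,
    parameters = list(
      conversion_rate = fit$config$params$conversion_rate,
      alpha_fail = fit$config$params$alpha_fail,
      beta = fit$config$params$beta,
      K0 = fit$config$K0, K1 = fit$config$K1,
      K2 = fit$config$K2, K3 = fit$config$K3,
      q = fit$config$q,
      filter_a = fit$config$filter_a, filter_b = fit$config$filter_b
    )
  )
  f <- paste0(prefix, ".report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Run the full pipeline on files
#'
#' Load alignments and reference, fit the haplotype chains, apply the
#' noise filter, and write all output tables.
#'
#' @param alignments Path to BAM/SAM.
#' @param reference Path to FASTA.
#' @param region Region string `"chrom:start-end"`.
#' @param out_prefix Output path prefix.
#' @param config A [methaplo_config()].
#' @param variants Optional VCF of known variants.
#' @return The fitted `methaplo_fit`, invisibly; outputs on disk.
#' @export
run_pipeline <- function(alignments, reference, region, out_prefix,
                         config = methaplo_config(), variants = NULL) {
  m <- regmatches(region, regexec("^([^:]+):(\\d+)-(\\d+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must be chrom:start-end")
  chrom <- m[2L]
  start <- as.integer(m[3L])
  end <- as.integer(m[4L])
  window <- tryCatch(
    reference_window(reference, chrom = chrom, start = start, end = end),
    error = function(e) stop("reference stage: ", conditionMessage(e))
  )
  if (!is.null(variants)) {
    window <- tryCatch(add_known_variants(window, variants),
      error = function(e) stop("variants stage: ", conditionMessage(e))
    )
  }
  reads <- tryCatch(
    load_alignments(alignments, chrom, start, end,
      paired = config$mode != "wgbs-single"
    ),
    error = function(e) stop("alignment stage: ", conditionMessage(e))
  )
  # keep only reads fully inside the window (chains are windowed)
  inside <- vapply(reads$units, function(u) {
    u$lo >= start && u$hi <= end
  }, logical(1L))
  reads$units <- reads$units[inside]
  fit <- tryCatch(methaplo(reads, window, config),
    error = function(e) stop("fit stage: ", conditionMessage(e))
  )
  fit <- filter_chains(fit)
  tryCatch(write_outputs(fit, out_prefix),
    error = function(e) stop("output stage: ", conditionMessage(e))
  )
  invisible(fit)
}
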