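# Post-inference: noise filtering of chains, log fit-ratios, position-wise
# methylation and genotype calls, and NOMe accessibility profiling.

#' Chain summary table
#'
#' @param fit A `methaplo_fit`.
#' @param kept_only Restrict to chains kept by [filter_chains()] (all
#'   chains when the filter has not been applied).
#' @return Data frame with one row per chain: id, chrom, start, end,
#'   length, n_reads, total read bases, depth fraction, mean CpG
#'   methylation, kept flag, and the epigenotype string (A/C/G/T plus M
#'   for meC and W for meG).
#' @export
chains <- function(fit, kept_only = FALSE) {
  stopifnot(inherits(fit, "methaplo_fit"))
  df <- depth_fraction(fit)
  kept <- if (is.null(fit$kept)) rep(TRUE, length(fit$chains)) else fit$kept
  out <- data.frame(
    chain = vapply(fit$chains, function(c) c$id, integer(1L)),
    chrom = fit$window$chrom,
    start = vapply(fit$chains, function(c) c$start, integer(1L)),
    end = vapply(fit$chains, function(c) c$end, integer(1L)),
    n_reads = vapply(fit$chains, function(c) c$n_reads, integer(1L)),
    total_bases = vapply(fit$chains, function(c) c$total_bases, integer(1L)),
    depth_fraction = df,
    mean_methylation = vapply(fit$chains, function(c) {
      idx <- (c$start:c$end) - fit$window$start + 1L
      at <- bitwAnd(fit$window$context[idx], .CTX[["CPG_C"]]) > 0L
      if (!any(at)) return(NA_real_)
      mean(c$g[at] == "M")
    }, numeric(1L)),
    kept = kept,
    epigenotype = vapply(fit$chains, function(c) paste(c$g, collapse = ""), character(1L)),
    stringsAsFactors = FALSE
  )
  out$length <- out$end - out$start + 1L
  out <- out[, c(
    "chain", "chrom", "start", "end", "length", "n_reads", "total_bases",
    "depth_fraction", "mean_methylation", "kept", "epigenotype"
  )]
  if (kept_only) out <- out[out$kept, , drop = FALSE]
  out
}

#' Depth fraction of every chain
#'
#' Total read base pairs in a chain divided by the total read base pairs
#' of all chains whose ranges overlap it (including the chain itself, so
#' a lone chain has depth fraction 1); the noise-filter covariate.
#'
#' @param fit A `methaplo_fit`.
#' @return Numeric vector in (0, 1], one value per chain.
#' @export
depth_fraction <- function(fit) {
  stopifnot(inherits(fit, "methaplo_fit"))
  n <- length(fit$chains)
  if (n == 0L) return(numeric(0))
  starts <- vapply(fit$chains, function(c) c$start, integer(1L))
  ends <- vapply(fit$chains, function(c) c$end, integer(1L))
  tot <- vapply(fit$chains, function(c) c$total_bases, integer(1L))
  vapply(seq_len(n), function(k) {
    ov <- starts <= ends[k] & ends >= starts[k]
    tot[k] / sum(tot[ov])
  }, numeric(1L))
}

#' Noise-filter the fitted chains
#'
#' Minor epi-alleles and noise are removed post inference: a chain is
#' kept when `a <= chain length + b * depth fraction`.  Long chains and
#' chains holding a large share of the local reads survive.  Filtering
#' never re-runs the fit; the dominating chains are unaffected.
#'
#' @param fit A `methaplo_fit`.
#' @param a,b Filter constants in bp; default from the fit's
#'   configuration (mode-dependent, see [methaplo_config()]).
#' @return The fit with its `kept` logical updated.
#' @export
filter_chains <- function(fit, a = NULL, b = NULL) {
  stopifnot(inherits(fit, "methaplo_fit"))
  if (is.null(a)) a <- fit$config$filter_a
  if (is.null(b)) b <- fit$config$filter_b
  len <- vapply(fit$chains, function(c) c$end - c$start + 1L, integer(1L))
  fit$kept <- chain_keep_rule(len, depth_fraction(fit), a, b)
  fit
}

#' The chain noise-filter rule
#'
#' A chain is kept when `a <= length + b * depth_fraction` (boundary
#' inclusive).  Monotone in both length and depth fraction; with
#' `b >= a` any chain of depth fraction 1 is kept regardless of length.
#'
#' @param length Chain range length(s) in bp.
#' @param df Depth fraction(s).
#' @param a,b Filter constants in bp.
#' @return Logical vector.
#' @export
chain_keep_rule <- function(length, df, a, b) {
  a <= length + b * df
}

# 6 x L matrix of position log-likelihoods l(x) for one chain, pure R:
# per position, the sum over member-read bases of log emission.
.chain_loglik_matrix <- function(fit, chain_id) {
  ch <- fit$chains[[chain_id]]
  L <- ch$end - ch$start + 1L
  esum <- matrix(0, 6L, L, dimnames = list(.EPI, NULL))
  for (m in ch$members) {
    u <- fit$reads$units[[m]]
    em <- .emission_logmat(u, fit$strand[m], fit$config$params)
    for (i in seq_len(u$n_bases)) {
      j <- u$pos[i] - ch$start + 1L
      esum[, j] <- esum[, j] + em[, i]
    }
  }
  esum
}

#' Position log-likelihood of an epigenotype within a chain
#'
#' `l(x)`: the sum over the chain's reads covering the position of the
#' log emission probability of the observed base given epigenotype `x`
#' and the read's assigned strand.
#'
#' @param fit A `methaplo_fit`.
#' @param chain_id Chain index.
#' @param pos 1-based genomic position within the chain range.
#' @param x Epigenotype(s) among `"A","C","G","T","M","W"`; default all
#'   six.
#' @return Named numeric vector of log-likelihoods.
#' @export
position_loglik <- function(fit, chain_id, pos, x = .EPI) {
  ch <- fit$chains[[chain_id]]
  if (pos < ch$start || pos > ch$end) stop("position outside chain range")
  m <- .chain_loglik_matrix(fit, chain_id)
  m[.epi_code(x) + 1L, pos - ch$start + 1L]
}

#' Log fit-ratios of a chain at a position
#'
#' `F = 2 * (max over x outside {g, proj(g)} of l(x) - max over x in
#' {g, proj(g)} of l(x))` measures how well the inferred epigenotype (or
#' its unmethylated nucleotide) fits compared to any other state; `F_R`
#' makes the same comparison for the reference nucleotide (paired with
#' its methylated variant when it is C or G), and `F_A` for a known
#' alternative nucleotide when one exists.  All three can take any value.
#'
#' @param fit A `methaplo_fit`.
#' @param chain_id Chain index.
#' @param pos 1-based genomic position.
#' @param alt Optional alternative nucleotide; default: the known-variant
#'   alternate at `pos` if any.
#' @return List with `F`, `F_R`, `F_A` (`F_A` is `NA` without an
#'   alternative), the inferred `g`, and `ref`/`alt` nucleotides.
#' @export
fit_ratios <- function(fit, chain_id, pos, alt = NULL) {
  ch <- fit$chains[[chain_id]]
  ell <- position_loglik(fit, chain_id, pos)
  g <- ch$g[pos - ch$start + 1L]
  i <- pos - fit$window$start + 1L
  ref <- c(.NUC, "N")[fit$window$base[i] + 1L]
  if (is.null(alt)) {
    cand <- .NUC[fit$window$allowed[i, ] & .NUC != ref]
    alt <- if (length(cand)) cand[1L] else NA_character_
  }
  pair_set <- function(y) {
    if (y %in% c("C", "M")) c("C", "M")
    else if (y %in% c("G", "W")) c("G", "W")
    else y
  }
  ratio <- function(set) {
    set <- intersect(set, .EPI)
    2 * (max(ell[setdiff(.EPI, set)]) - max(ell[set]))
  }
  list(
    F = ratio(unique(c(g, epi_projection(g)))),
    F_R = if (ref %in% .NUC) ratio(pair_set(ref)) else NA_real_,
    F_A = if (!is.na(alt)) ratio(pair_set(alt)) else NA_real_,
    g = g, ref = ref, alt = alt
  )
}

#' Combined genotype at a position
#'
#' Aggregates the per-chain genotypes of the (kept) chains covering a
#' position, using only chains whose fit-ratios pass `F <= -threshold`
#' or `|F_R - F_A| >= threshold` (this guards the combined call against
#' chains with very few reads).  The combined genotype is the set of
#' nucleotide projections of the passing chains' epigenotypes:
#' homozygous when one distinct nucleotide remains, a heterozygous pair
#' when two.
#'
#' @param fit A `methaplo_fit`.
#' @param pos 1-based genomic position.
#' @param threshold Fit-ratio threshold (default 15).
#' @param kept_only Use only chains kept by [filter_chains()].
#' @return List with `genotype` (e.g. `"AA"`, `"CT"`, `NA` for no-call),
#'   `alleles` (distinct passing nucleotides), `n_chains` (passing
#'   chains), and `ambiguous` (more than two distinct nucleotides).
#' @export
combined_genotype <- function(fit, pos, threshold = 15, kept_only = TRUE) {
  kept <- if (is.null(fit$kept)) rep(TRUE, length(fit$chains)) else fit$kept
  nucs <- character(0)
  n_pass <- 0L
  for (k in seq_along(fit$chains)) {
    ch <- fit$chains[[k]]
    if (kept_only && !kept[k]) next
    if (pos < ch$start || pos > ch$end) next
    fr <- fit_ratios(fit, k, pos)
    pass <- (is.finite(fr$F) && fr$F <= -threshold) ||
      (!is.na(fr$F_A) && !is.na(fr$F_R) && abs(fr$F_R - fr$F_A) >= threshold)
    if (!pass) next
    n_pass <- n_pass + 1L
    nucs <- c(nucs, epi_projection(ch$g[pos - ch$start + 1L]))
  }
  distinct <- sort(unique(nucs))
  genotype <- if (length(distinct) == 1L) {
    paste0(distinct, distinct)
  } else if (length(distinct) == 2L) {
    paste(distinct, collapse = "")
  } else {
    NA_character_
  }
  list(
    genotype = genotype, alleles = distinct,
    n_chains = n_pass, ambiguous = length(distinct) > 2L
  )
}

#' Position-wise methylation level
#'
#' The fraction of reads covering a CpG position whose chain's inferred
#' epigenotype at that position is methylated (meC/meG), among the reads
#' of the (kept) chains.  Positions covered by no read, or only by N
#' base calls, give a no-call (`NA`).
#'
#' @param fit A `methaplo_fit`.
#' @param pos 1-based genomic position; must be a CpG C or G position in
#'   WGBS mode.
#' @param kept_only Use only chains kept by [filter_chains()].
#' @return List with `level` (fraction in `[0,1]` or `NA`) and
#'   `coverage` (number of informative reads).
#' @export
methylation_level <- function(fit, pos, kept_only = TRUE) {
  win <- fit$window
  i <- pos - win$start + 1L
  is_cpg <- bitwAnd(win$context[i], bitwOr(.CTX[["CPG_C"]], .CTX[["CPG_G"]])) > 0L
  if (!is_cpg && fit$config$mode != "nome") {
    stop("not a CpG position")
  }
  kept <- if (is.null(fit$kept)) rep(TRUE, length(fit$chains)) else fit$kept
  n_me <- 0L
  n_cov <- 0L
  for (k in seq_along(fit$chains)) {
    ch <- fit$chains[[k]]
    if (kept_only && !kept[k]) next
    if (pos < ch$start || pos > ch$end) next
    me <- ch$g[pos - ch$start + 1L] %in% c("M", "W")
    for (m in ch$members) {
      u <- fit$reads$units[[m]]
      at <- u$pos == pos & u$base != 4L # N calls are uninformative
      if (any(at)) {
        n_cov <- n_cov + 1L
        if (me) n_me <- n_me + 1L
      }
    }
  }
  list(
    level = if (n_cov > 0L) n_me / n_cov else NA_real_,
    coverage = n_cov
  )
}

#' Methylation call table
#'
#' One row per reference CpG (C position): methylation level, coverage,
#' and context label.
#'
#' @param fit A `methaplo_fit`.
#' @param kept_only Use only chains kept by [filter_chains()].
#' @return Data frame with columns chrom, pos, context, level, coverage.
#' @export
methylation_calls <- function(fit, kept_only = TRUE) {
  win <- fit$window
  cpg <- which(bitwAnd(win$context, .CTX[["CPG_C"]]) > 0L)
  pos <- cpg + win$start - 1L
  res <- lapply(pos, function(p) methylation_level(fit, p, kept_only))
  data.frame(
    chrom = rep(win$chrom, length(pos)), pos = pos,
    context = ifelse(bitwAnd(win$context[cpg], .CTX[["ISO_CPG_C"]]) > 0L,
      "HCGD", "CpG"
    ),
    level = vapply(res, function(r) r$level, numeric(1L)),
    coverage = vapply(res, function(r) r$coverage, numeric(1L)),
    stringsAsFactors = FALSE
  )
}

#' Genotype call table
#'
#' Combined genotypes at the requested positions (default: positions
#' where any kept chain's projection differs from the reference, plus
#' all known-variant positions).
#'
#' @param fit A `methaplo_fit`.
#' @param positions 1-based genomic positions, or `NULL` for the default
#'   set.
#' @param threshold Fit-ratio threshold (default 15).
#' @param kept_only Use only kept chains.
#' @return Data frame with chrom, pos, ref, genotype, n_chains,
#'   ambiguous.
#' @export
genotype_calls <- function(fit, positions = NULL, threshold = 15, kept_only = TRUE) {
  win <- fit$window
  kept <- if (is.null(fit$kept)) rep(TRUE, length(fit$chains)) else fit$kept
  if (is.null(positions)) {
    positions <- integer(0)
    for (k in seq_along(fit$chains)) {
      if (kept_only && !kept[k]) next
      ch <- fit$chains[[k]]
      idx <- (ch$start:ch$end) - win$start + 1L
      proj <- .nuc_code(epi_projection(ch$g))
      positions <- c(positions, (ch$start:ch$end)[proj != win$base[idx]])
    }
    var_pos <- which(rowSums(win$allowed) > 1L) + win$start - 1L
    positions <- sort(unique(c(positions, var_pos)))
  }
  if (!length(positions)) {
    return(data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      genotype = character(0), n_chains = integer(0), ambiguous = logical(0)
    ))
  }
  rows <- lapply(positions, function(p) {
    cg <- combined_genotype(fit, p, threshold, kept_only)
    data.frame(
      chrom = win$chrom, pos = p,
      ref = c(.NUC, "N")[win$base[p - win$start + 1L] + 1L],
      genotype = cg$genotype, n_chains = cg$n_chains,
      ambiguous = cg$ambiguous, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' NOMe accessibility profile
#'
#' Per kept chain, each isolated GpC site is accessible when its inferred
#' epigenotype is the enzymatically methylated pair (meG-meC), and
#' inaccessible otherwise.  Site-level consensus accessibility is
#' reported both as the fraction of covering chains and as the fraction
#' of covering reads that are accessible.  Within each chain, maximal
#' runs of consecutive inaccessible isolated GpCs become inaccessible
#' intervals, delimited by the midpoints between the run and its
#' flanking accessible sites (truncated at the chain ends when a run is
#' terminal).
#'
#' @param fit A `methaplo_fit` in NOMe mode.
#' @param kept_only Use only kept chains.
#' @return List with `sites` (data frame: chrom, pos of the GpC G,
#'   chain_consensus, read_consensus, n_chains, n_reads) and `intervals`
#'   (data frame: chain, chrom, start, end, span, n_gpc).
#' @export
accessibility <- function(fit, kept_only = TRUE) {
  stopifnot(fit$config$mode == "nome")
  win <- fit$window
  gpc <- which(bitwAnd(win$context, .CTX[["ISO_GPC_G"]]) > 0L) + win$start - 1L
  kept <- if (is.null(fit$kept)) rep(TRUE, length(fit$chains)) else fit$kept
  n_site <- length(gpc)
  acc_chain <- matrix(NA, 0L, n_site)
  wt <- matrix(0, 0L, n_site)
  intervals <- NULL
  for (k in seq_along(fit$chains)) {
    if (kept_only && !kept[k]) next
    ch <- fit$chains[[k]]
    here <- gpc >= ch$start & gpc <= ch$end
    row_acc <- rep(NA, n_site)
    row_wt <- rep(0, n_site)
    if (any(here)) {
      sites <- gpc[here]
      row_acc[here] <- ch$g[sites - ch$start + 1L] == "W"
      for (s in seq_along(sites)) {
        p <- sites[s]
        row_wt[which(here)[s]] <- sum(vapply(ch$members, function(m) {
          any(fit$reads$units[[m]]$pos == p)
        }, logical(1L)))
      }
      # inaccessible runs within this chain
      acc <- row_acc[here]
      r <- rle(!acc)
      endpos <- cumsum(r$lengths)
      startpos <- endpos - r$lengths + 1L
      for (j in which(r$values)) {
        i1 <- startpos[j]
        i2 <- endpos[j]
        left <- if (i1 > 1L) floor((sites[i1 - 1L] + sites[i1]) / 2) else ch$start
        right <- if (i2 < length(sites)) ceiling((sites[i2] + sites[i2 + 1L]) / 2) else ch$end
        intervals <- rbind(intervals, data.frame(
          chain = ch$id, chrom = win$chrom, start = left, end = right,
          span = right - left, n_gpc = i2 - i1 + 1L, stringsAsFactors = FALSE
        ))
      }
    }
    acc_chain <- rbind(acc_chain, row_acc)
    wt <- rbind(wt, row_wt)
  }
  chain_consensus <- if (nrow(acc_chain)) colMeans(acc_chain, na.rm = TRUE) else rep(NA_real_, n_site)
  read_num <- colSums(wt * replace(acc_chain, is.na(acc_chain), 0), na.rm = TRUE)
  read_den <- colSums(wt * !is.na(acc_chain))
  list(
    sites = data.frame(
      chrom = win$chrom, pos = gpc,
      chain_consensus = as.numeric(chain_consensus),
      read_consensus = ifelse(read_den > 0, read_num / read_den, NA_real_),
      n_chains = colSums(!is.na(acc_chain)),
      n_reads = as.numeric(read_den),
      stringsAsFactors = FALSE
    ),
    intervals = if (is.null(intervals)) {
      data.frame(
        chain = integer(0), chrom = character(0), start = integer(0),
        end = integer(0), span = integer(0), n_gpc = integer(0)
      )
    } else {
      intervals
    }
  )
}
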