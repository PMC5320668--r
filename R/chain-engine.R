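# Haplotype-chain inference: feasibility rules, structure and genotype
# priors, the posterior, the coordinate-ascent fit, and a brute-force
# oracle for small instances.

#' Overlap statistics between a chain range and a read unit
#'
#' Counts the base pairs shared by the chain's range and the read's
#' footprint (union of mate footprints), and the CpG, isolated-CpG, and
#' isolated-GpC dinucleotides whose first position (the C of a CpG, the G
#' of a GpC) lies in that overlap.
#'
#' @param chain_start,chain_end 1-based inclusive chain range.
#' @param unit A [read_unit()].
#' @param window A [reference_window()].
#' @return Named numeric vector with elements `bp`, `n_cpg`, `n_iso_cpg`,
#'   `n_iso_gpc`.
#' @export
overlap_stats <- function(chain_start, chain_end, unit, window) {
  out <- c(bp = 0L, n_cpg = 0L, n_iso_cpg = 0L, n_iso_gpc = 0L)
  segs <- unit$segs
  # merge mate footprints so overlapped mate columns count once
  o <- order(segs[, 1L])
  merged <- list()
  for (k in o) {
    s <- segs[k, ]
    if (length(merged) && s[1L] <= merged[[length(merged)]][2L] + 1L) {
      merged[[length(merged)]][2L] <- max(merged[[length(merged)]][2L], s[2L])
    } else {
      merged[[length(merged) + 1L]] <- as.integer(s)
    }
  }
  for (s in merged) {
    a <- max(s[1L], chain_start)
    b <- min(s[2L], chain_end)
    if (a > b) next
    idx <- (a:b) - window$start + 1L
    ctx <- window$context[idx]
    out["bp"] <- out["bp"] + (b - a + 1L)
    out["n_cpg"] <- out["n_cpg"] + sum(bitwAnd(ctx, .CTX[["CPG_C"]]) > 0L)
    out["n_iso_cpg"] <- out["n_iso_cpg"] + sum(bitwAnd(ctx, .CTX[["ISO_CPG_C"]]) > 0L)
    out["n_iso_gpc"] <- out["n_iso_gpc"] + sum(bitwAnd(ctx, .CTX[["ISO_GPC_G"]]) > 0L)
  }
  out
}

#' Is adding a read to a chain feasible?
#'
#' A read may extend a feasible chain when its overlap with the chain
#' spans at least `K0` bp and contains at least `K1` CpGs, `K2` isolated
#' CpGs, and `K3` isolated GpCs (all inclusive "at least" thresholds).
#'
#' @inheritParams overlap_stats
#' @param config A [methaplo_config()] supplying `K0`..`K3`.
#' @return Logical.
#' @export
is_feasible_addition <- function(chain_start, chain_end, unit, window, config) {
  s <- overlap_stats(chain_start, chain_end, unit, window)
  s[["bp"]] >= config$K0 && s[["n_cpg"]] >= config$K1 &&
    s[["n_iso_cpg"]] >= config$K2 && s[["n_iso_gpc"]] >= config$K3
}

#' Optimal epigenotype chain for a fixed set of reads and strands
#'
#' Maximizes, over strand-compatible epigenotype chains, the sum of read
#' emission log-likelihoods and genotype-prior log-weights.  Solved
#' exactly by a first-order dynamic program over the six-state alphabet
#' in which methylation is only representable as a CpG pair (meC followed
#' by meG) or, in NOMe mode, additionally a GpC pair (meG followed by
#' meC).
#'
#' @param reads A [methaplo_reads()] object (the members of one chain).
#' @param strands Character vector `"fwd"`/`"rev"`, one per read unit.
#' @param window A [reference_window()].
#' @param config A [methaplo_config()].
#' @return List with `start`, `end`, `g` (character epigenotypes over the
#'   chain range), and `score` (the DP objective).
#' @export
optimal_epigenotype_chain <- function(reads, strands, window, config = methaplo_config()) {
  stopifnot(inherits(reads, "methaplo_reads"), length(reads$units) >= 1L)
  res <- cpp_chain_score(
    .flatten_units(reads), .strand_code(strands),
    window$start, length(window$base),
    .prior_allowed(window, config$use_db), window$context,
    config$q, config$params$alpha_fail, config$params$beta,
    config$mode == "nome"
  )
  list(
    start = res$start, end = res$end,
    g = .EPI[res$g + 1L], score = res$dp
  )
}

#' Log structure prior of a haplotype structure
#'
#' The prior over read partitions weights, for every read, the square
#' root of its chain's length times the squared total read length of the
#' chain: each chain with `n` reads, range length `L`, and total read
#' bases `T` contributes `n * (log(L)/2 + 2*log(T))`.  The normalization
#' constant is ignored throughout.
#'
#' @param chain_lengths Numeric vector of chain range lengths.
#' @param read_lengths List of numeric vectors: per chain, the lengths of
#'   its member reads.
#' @return Log prior weight (up to an additive constant).
#' @export
log_prior_B <- function(chain_lengths, read_lengths) {
  stopifnot(length(chain_lengths) == length(read_lengths))
  tot <- 0
  for (k in seq_along(chain_lengths)) {
    L <- chain_lengths[k]
    l <- read_lengths[[k]]
    if (L < 1 || length(l) == 0L) stop("empty chain in structure prior")
    tot <- tot + length(l) * (0.5 * log(L) + 2 * log(sum(l)))
  }
  tot
}

#' Log genotype prior of an epigenotype assignment
#'
#' Per chain position, contributes `log(q)` when the nucleotide projection
#' of the epigenotype is in the prior support set (reference base plus
#' known variants when in use), else `log(1 - q)`.
#'
#' @param chains List of chains, each a list with `start`, `end`, and `g`
#'   (character epigenotypes over the range).
#' @param window A [reference_window()].
#' @param q Prior confidence weight.
#' @param use_db Whether known variants extend the support.
#' @return Log prior weight (up to an additive constant).
#' @export
log_prior_G <- function(chains, window, q = 0.9999, use_db = TRUE) {
  allowed <- .prior_allowed(window, use_db)
  tot <- 0
  for (ch in chains) {
    idx <- (ch$start:ch$end) - window$start + 1L
    proj <- .nuc_code(epi_projection(ch$g))
    ok <- allowed[cbind(idx, proj + 1L)]
    tot <- tot + sum(ifelse(ok, log(q), log(1 - q)))
  }
  tot
}

# log emission matrix (6 x n_bases) of one unit at one strand, pure R.
.emission_logmat <- function(unit, strand, params) {
  m <- .conversion_matrix(.strand_code(strand), params)
  out <- matrix(0, 6L, unit$n_bases)
  for (g in 1:6) {
    pz <- ifelse(unit$base == 4L, NA_real_, m[unit$base + 1L, g])
    e <- unit$eps
    v <- log((1 - 4 / 3 * e) * pz + e / 3)
    v[unit$base == 4L] <- 0
    out[g, ] <- v
  }
  out
}

#' Log posterior of a complete configuration (naive recomputation)
#'
#' Computes `log pi0(B) + log pi1(G|B) + log L(B, G, R)` from scratch in
#' plain R, with no caching and independently of the optimizer's internal
#' code path; intended for validation.  The uniform strand prior is
#' omitted, as are all normalization constants.
#'
#' @param reads A [methaplo_reads()] object.
#' @param window A [reference_window()].
#' @param config A [methaplo_config()].
#' @param chain_of Integer vector assigning each read unit to a chain.
#' @param strands Character vector `"fwd"`/`"rev"` per read unit.
#' @param chains List of chains, each with `start`, `end`, `g` (character
#'   epigenotypes covering the range).
#' @return Log posterior value.
#' @export
log_posterior <- function(reads, window, config, chain_of, strands, chains) {
  n <- length(reads$units)
  stopifnot(length(chain_of) == n, length(strands) == n)
  ll <- 0
  for (i in seq_len(n)) {
    u <- reads$units[[i]]
    ch <- chains[[chain_of[i]]]
    if (any(u$pos < ch$start) || any(u$pos > ch$end)) {
      stop("read base outside its chain range")
    }
    em <- .emission_logmat(u, strands[i], config$params)
    gidx <- .epi_code(ch$g[u$pos - ch$start + 1L])
    ll <- ll + sum(em[cbind(gidx + 1L, seq_len(u$n_bases))])
  }
  Ls <- vapply(chains, function(ch) ch$end - ch$start + 1, numeric(1L))
  rl <- lapply(seq_along(chains), function(k) {
    vapply(reads$units[chain_of == k], function(u) u$n_bases, integer(1L))
  })
  ll + log_prior_B(Ls, rl) +
    log_prior_G(chains, window, config$q, config$use_db)
}

#' Fit haplotype chains to bisulfite reads
#'
#' The main fitting function.  Starting from the all-singleton structure
#' (each read its own chain), the optimizer sweeps the read units in
#' genomic order and tentatively moves each unit - to its own singleton
#' chain or into any feasible chain, at either fragment strand - accepting
#' the move that most increases the log posterior; detaching a unit that
#' disconnects its chain splits the remainder into maximal covered
#' segments.  Sweeps repeat until a full pass accepts no move or the pass
#' limit is reached.  The log posterior is non-decreasing throughout and
#' the procedure terminates in finitely many steps.
#'
#' @param reads A [methaplo_reads()] object, e.g. from
#'   [load_alignments()] or [simulate_reads()].
#' @param window A [reference_window()] covering all reads.
#' @param config A [methaplo_config()].
#' @param verbose Print the conversion-parameter interpretation on start.
#' @return An object of class `methaplo_fit`; see [chains()],
#'   [methylation_calls()], [genotype_calls()], [accessibility()],
#'   [filter_chains()], and the `print`, `summary`, `plot`, `logLik`
#'   methods.
#' @export
methaplo <- function(reads, window, config = methaplo_config(), verbose = FALSE) {
  stopifnot(
    inherits(reads, "methaplo_reads"),
    inherits(window, "reference_window"),
    inherits(config, "methaplo_config")
  )
  if (verbose) {
    message(sprintf(
      "conversion success rate %g; model failed-conversion rate %g, inappropriate rate %g",
      config$params$conversion_rate, config$params$alpha_fail, config$params$beta
    ))
  }
  res <- cpp_fit(
    .flatten_units(reads), window$start, length(window$base),
    .prior_allowed(window, config$use_db), window$context,
    config$q, config$params$alpha_fail, config$params$beta,
    config$K0, config$K1, config$K2, config$K3,
    config$mode == "nome", config$max_passes, 1e-7
  )
  if (!res$converged && length(reads$units) > 0L) {
    warning("pass limit reached before convergence; estimates may be suboptimal")
  }
  chs <- lapply(seq_along(res$chains), function(k) {
    ch <- res$chains[[k]]
    members <- as.integer(ch$members)
    list(
      id = k, start = ch$start, end = ch$end, members = members,
      g = .EPI[ch$g + 1L], dp = ch$dp, pi0 = ch$pi0,
      n_reads = length(members),
      total_bases = sum(vapply(reads$units[members], function(u) u$n_bases, integer(1L)))
    )
  })
  structure(
    list(
      chains = chs,
      chain_of = as.integer(res$chain_of),
      strand = c("fwd", "rev")[res$strand + 1L],
      logLik = res$loglik,
      trajectory = as.numeric(res$trajectory),
      passes = res$passes,
      converged = res$converged,
      config = config, window = window, reads = reads,
      kept = NULL
    ),
    class = "methaplo_fit"
  )
}

# ---- pure-R oracle machinery (independent of the C++ path) -----------------

# R Viterbi over the same constrained state space; members is a list of
# read_unit, strands a character vector.
.chain_dp_r <- function(members, strands, window, config) {
  lo <- min(vapply(members, function(u) u$lo, integer(1L)))
  hi <- max(vapply(members, function(u) u$hi, integer(1L)))
  L <- hi - lo + 1L
  nome <- config$mode == "nome"
  esum <- matrix(0, 6L, L)
  for (k in seq_along(members)) {
    u <- members[[k]]
    em <- .emission_logmat(u, strands[k], config$params)
    for (i in seq_len(u$n_bases)) {
      j <- u$pos[i] - lo + 1L
      esum[, j] <- esum[, j] + em[, i]
    }
  }
  allowed <- .prior_allowed(window, config$use_db)
  idx <- (lo:hi) - window$start + 1L
  lq <- log(config$q)
  l1q <- log(1 - config$q)
  # internal states: 1..4 plain, 5 Mo, 6 Wc, 7 Wo, 8 Mc
  sg6 <- c(1L, 2L, 3L, 4L, 5L, 6L, 6L, 5L)
  proj <- c(1L, 2L, 3L, 4L, 2L, 3L, 3L, 2L)
  nstate <- if (nome) 8L else 6L
  val <- function(j, s) {
    esum[sg6[s], j] + if (allowed[idx[j], proj[s]]) lq else l1q
  }
  NEGV <- -1e18
  prev <- rep(NEGV, 8L)
  startok <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, nome, FALSE)
  for (s in seq_len(nstate)) if (startok[s]) prev[s] <- val(1L, s)
  bp <- matrix(NA_integer_, L, 8L)
  if (L >= 2L) {
    for (j in 2:L) {
      open_free <- setdiff(seq_len(nstate), c(5L, 7L))
      pbest <- which.max(prev[open_free])
      argP <- open_free[pbest]
      bestP <- prev[argP]
      cur <- rep(NEGV, 8L)
      for (s in seq_len(nstate)) {
        if (s == 6L) {
          cur[6L] <- prev[5L] + val(j, 6L)
          bp[j, 6L] <- 5L
        } else if (s == 8L) {
          cur[8L] <- prev[7L] + val(j, 8L)
          bp[j, 8L] <- 7L
        } else {
          cur[s] <- bestP + val(j, s)
          bp[j, s] <- argP
        }
      }
      prev <- cur
    }
  }
  endok <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, nome)
  fin <- which(endok[seq_len(nstate)])
  s <- fin[which.max(prev[fin])]
  score <- prev[s]
  g <- integer(L)
  for (j in L:1) {
    g[j] <- sg6[s]
    if (j > 1L) s <- bp[j, s]
  }
  list(start = lo, end = hi, g = .EPI[g], score = score)
}

# Can this set of units form one feasible chain in some addition order?
.block_feasible_r <- function(members, window, config) {
  n <- length(members)
  if (n == 1L) return(TRUE)
  seen <- logical(2^n)
  grow <- function(mask, lo, hi) {
    if (mask == 2^n - 1) return(TRUE)
    if (seen[mask + 1L]) return(FALSE)
    seen[mask + 1L] <<- TRUE
    for (k in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L) next
      u <- members[[k]]
      if (u$lo > hi + 1L || u$hi < lo - 1L) next # coverage gap
      if (!is_feasible_addition(lo, hi, u, window, config)) next
      if (grow(bitwOr(mask, bitwShiftL(1L, k - 1L)),
               min(lo, u$lo), max(hi, u$hi))) {
        return(TRUE)
      }
    }
    FALSE
  }
  for (k in seq_len(n)) {
    seen[] <- FALSE
    if (grow(bitwShiftL(1L, k - 1L), members[[k]]$lo, members[[k]]$hi)) return(TRUE)
  }
  FALSE
}

.set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in .set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    p[[length(p) + 1L]] <- n
    out[[length(out) + 1L]] <- p
  }
  out
}

#' Exhaustive-search fit for small instances
#'
#' Enumerates every partition of the reads into chains and every strand
#' assignment, keeps the feasible structures (each block buildable by
#' single-read additions under the feasibility rules, with positive
#' coverage), computes each chain's optimal epigenotype sequence, and
#' returns the configuration with maximal log posterior.  Pure R,
#' independent of the coordinate-ascent optimizer; intended as a test
#' oracle.
#'
#' @param reads A [methaplo_reads()] with at most 6 read units.
#' @param window A [reference_window()] of at most 200 bp.
#' @param config A [methaplo_config()].
#' @return List with `logLik`, `chain_of`, `strand`, and `chains` (each
#'   with `start`, `end`, `g`, `score`).
#' @export
brute_force_fit <- function(reads, window, config = methaplo_config()) {
  n <- length(reads$units)
  stopifnot(n >= 1L, n <= 6L, length(window$base) <= 200L)
  best <- list(logLik = -Inf)
  for (part in .set_partitions(n)) {
    ok <- all(vapply(part, function(blk) {
      .block_feasible_r(reads$units[blk], window, config)
    }, logical(1L)))
    if (!ok) next
    total <- 0
    chains <- vector("list", length(part))
    chain_of <- integer(n)
    strand <- character(n)
    for (k in seq_along(part)) {
      blk <- part[[k]]
      chain_of[blk] <- k
      m <- length(blk)
      bestblk <- NULL
      for (code in 0:(2^m - 1)) {
        sv <- c("fwd", "rev")[bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L) + 1L]
        r <- .chain_dp_r(reads$units[blk], sv, window, config)
        if (is.null(bestblk) || r$score > bestblk$score) {
          bestblk <- r
          bestblk$strands <- sv
        }
      }
      lens <- vapply(reads$units[blk], function(u) u$n_bases, integer(1L))
      pi0 <- m * (0.5 * log(bestblk$end - bestblk$start + 1) + 2 * log(sum(lens)))
      total <- total + bestblk$score + pi0
      strand[blk] <- bestblk$strands
      chains[[k]] <- bestblk[c("start", "end", "g", "score")]
    }
    if (total > best$logLik) {
      best <- list(
        logLik = total, chain_of = chain_of,
        strand = strand, chains = chains
      )
    }
  }
  best
}
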