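# Shared fixture builders.  All fixtures are constructed in code.

# A fake fitted object with fully specified chains, members, and strands;
# bypasses the optimizer so that post-processing can be tested in
# isolation against hand-computable values.
fake_fit <- function(units, chain_members, strands, g_chains, window,
                     config = methaplo_config("wgbs-single")) {
  reads <- methaplo_reads(units, chrom = window$chrom)
  # methaplo_reads() sorts by start; map original indices to sorted order
  ids <- vapply(reads$units, function(u) u$id, character(1L))
  orig_ids <- vapply(units, function(u) u$id, character(1L))
  remap <- match(orig_ids, ids)
  chain_of <- integer(length(units))
  chains <- vector("list", length(chain_members))
  for (k in seq_along(chain_members)) {
    mem <- remap[chain_members[[k]]]
    chain_of[mem] <- k
    lo <- min(vapply(reads$units[mem], function(u) u$lo, integer(1L)))
    hi <- max(vapply(reads$units[mem], function(u) u$hi, integer(1L)))
    g <- g_chains[[k]]
    stopifnot(length(g) == hi - lo + 1L)
    chains[[k]] <- list(
      id = k, start = lo, end = hi, members = mem, g = g,
      dp = NA_real_, pi0 = NA_real_, n_reads = length(mem),
      total_bases = sum(vapply(reads$units[mem], function(u) u$n_bases, integer(1L)))
    )
  }
  sorted_strands <- strands[order(remap)]
  structure(
    list(
      chains = chains, chain_of = chain_of, strand = sorted_strands,
      logLik = NA_real_, trajectory = numeric(0), passes = 0L,
      converged = TRUE, config = config, window = window, reads = reads,
      kept = NULL
    ),
    class = "methaplo_fit"
  )
}

# Reference windows with known context structure.
win_repeat_acgt <- function(n = 30L) reference_window(strrep("ACGT", n))

# Valid epigenotype chains under the pairing rules, for exhaustive
# enumeration oracles: greedy parse (M must open a CpG pair; in NOMe
# mode W may open a GpC pair).
chain_is_strand_compatible <- function(g, nome = FALSE) {
  j <- 1L
  n <- length(g)
  while (j <= n) {
    if (g[j] %in% c("A", "C", "G", "T")) {
      j <- j + 1L
    } else if (g[j] == "M") {
      if (j + 1L > n || g[j + 1L] != "W") return(FALSE)
      j <- j + 2L
    } else if (g[j] == "W") {
      if (!nome || j + 1L > n || g[j + 1L] != "M") return(FALSE)
      j <- j + 2L
    } else {
      return(FALSE)
    }
  }
  TRUE
}

# A fake fit with one chain per requested genotype at position 11 of a
# 20 bp window (reference T, known alternate C); each chain has n_fwd
# forward reads showing the converted forward base and n_rev reverse
# reads showing the reverse base.
genotype_fit <- function(chain_bases, n_fwd = 4L, n_rev = 4L) {
  win <- reference_window(paste0(strrep("A", 10), "T", strrep("A", 9)))
  win <- add_known_variants(win, data.frame(pos = 11L, ref = "T", alt = "C"))
  cfg <- methaplo_config("wgbs-single")
  units <- list()
  strands <- character(0)
  members <- list()
  gch <- list()
  p0 <- conversion_params(1, 0)
  nuc <- c("A", "C", "G", "T")
  for (k in seq_along(chain_bases)) {
    g <- chain_bases[k]
    fwd_base <- nuc[which.max(conversion_prob(nuc, g, "fwd", p0))]
    rev_base <- nuc[which.max(conversion_prob(nuc, g, "rev", p0))]
    mem <- integer(0)
    for (i in seq_len(n_fwd)) {
      units[[length(units) + 1L]] <- read_unit(
        sprintf("c%d_f%d", k, i), 1L,
        paste0(strrep("A", 10), fwd_base, strrep("A", 9)), 0.001
      )
      strands <- c(strands, "fwd")
      mem <- c(mem, length(units))
    }
    for (i in seq_len(n_rev)) {
      units[[length(units) + 1L]] <- read_unit(
        sprintf("c%d_r%d", k, i), 1L,
        paste0(strrep("A", 10), rev_base, strrep("A", 9)), 0.001
      )
      strands <- c(strands, "rev")
      mem <- c(mem, length(units))
    }
    members[[k]] <- mem
    gch[[k]] <- c(rep("A", 10), g, rep("A", 9))
  }
  fake_fit(units, members, strands, gch, win, cfg)
}

# Score a fixed epigenotype chain for a set of units/strands: summed log
# emissions plus the genotype prior.  Independent of the DP.
score_chain_naive <- function(g, lo, units, strands, window, config) {
  tot <- 0
  allowed <- if (config$use_db) window$allowed else NULL
  q <- config$q
  for (k in seq_along(units)) {
    u <- units[[k]]
    for (i in seq_len(u$n_bases)) {
      d <- c("A", "C", "G", "T", "N")[u$base[i] + 1L]
      gi <- g[u$pos[i] - lo + 1L]
      tot <- tot + log(emission_prob(d, gi, strands[k], u$eps[i], config$params))
    }
  }
  for (j in seq_along(g)) {
    pos <- lo + j - 1L
    ok <- prior_indicator(window, pos, epi_projection(g[j]), use_db = config$use_db)
    tot <- tot + if (ok == 1L) log(q) else log(1 - q)
  }
  tot
}
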