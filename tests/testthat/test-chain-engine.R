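# Chain inference: overlap/feasibility rules, the constrained epigenotype
# DP, the structure and genotype priors, the posterior, and the optimizer
# against independent oracles.

test_that("overlap statistics count footprint base pairs and dinucleotide sites", {
  win <- reference_window(paste0(
    strrep("T", 10), "ACGT", strrep("A", 86), strrep("T", 100)
  ))
  u <- read_unit("r", 51L, strrep("A", 100))
  expect_equal(unname(overlap_stats(1L, 200L, u, win)["bp"]), 100)
  expect_equal(unname(overlap_stats(1L, 40L, u, win)["bp"]), 0)
  # overlap covering the lone isolated CpG once
  u2 <- read_unit("r2", 5L, strrep("A", 20))
  os <- overlap_stats(1L, 40L, u2, win)
  expect_equal(unname(os["bp"]), 20)
  expect_equal(unname(os["n_cpg"]), 1)
  expect_equal(unname(os["n_iso_cpg"]), 1)
  expect_equal(unname(os["n_iso_gpc"]), 0)
  # a CpG whose C sits outside the overlap is not counted
  os3 <- overlap_stats(13L, 40L, u2, win)
  expect_equal(unname(os3["n_cpg"]), 0)
  # overlapping mates count each shared column once
  up <- read_unit("p", c(5L, 15L), c(strrep("A", 20), strrep("A", 20)))
  expect_equal(unname(overlap_stats(1L, 100L, up, win)["bp"]), 30)
})

test_that("feasibility thresholds are inclusive at-least rules", {
  # window with a CpG every 4 bp
  win <- win_repeat_acgt(50)
  cfg <- methaplo_config("wgbs-paired") # K0 = 50, K1 = 2
  u49 <- read_unit("a", 1L, strrep("A", 49))
  u50 <- read_unit("b", 1L, strrep("A", 50))
  expect_false(is_feasible_addition(1L, 200L, u49, win, cfg)) # 49 bp < K0
  expect_true(is_feasible_addition(1L, 200L, u50, win, cfg)) # boundary holds
  # enough base pairs but too few CpGs in the overlap
  win2 <- reference_window(paste0(strrep("A", 90), "CG", strrep("A", 108)))
  expect_false(is_feasible_addition(1L, 200L, read_unit("c", 1L, strrep("A", 60)), win2, cfg))
  # NOMe needs isolated GpCs
  cfgn <- methaplo_config("nome") # K0 = 40, K3 = 2
  expect_false(is_feasible_addition(1L, 200L, read_unit("d", 1L, strrep("A", 60)), win2, cfgn))
  winn <- reference_window(strrep("TGCAATTAGA", 20))
  expect_true(is_feasible_addition(1L, 200L, read_unit("e", 1L, strrep("A", 60)), winn, cfgn))
})

test_that("the epigenotype DP equals exhaustive enumeration on tiny windows", {
  epi6 <- c("A", "C", "G", "T", "M", "W")
  for (case in list(
    list(seq = "AACGT", nome = FALSE, seed = 1),
    list(seq = "TGCAT", nome = TRUE, seed = 2),
    list(seq = "CGCGA", nome = FALSE, seed = 3),
    list(seq = "GCGCA", nome = TRUE, seed = 4)
  )) {
    set.seed(case$seed)
    win <- reference_window(case$seq)
    L <- nchar(case$seq)
    cfg <- methaplo_config(if (case$nome) "nome" else "wgbs-single")
    for (rep in 1:3) {
      units <- lapply(1:2, function(k) {
        read_unit(paste0("r", k), 1L,
          paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
          0.05
        )
      })
      strands <- sample(c("fwd", "rev"), 2L, replace = TRUE)
      reads <- methaplo_reads(units, "chr")
      got <- optimal_epigenotype_chain(reads, strands, win, cfg)
      # exhaustive maximum over all strand-compatible chains
      grid <- expand.grid(rep(list(epi6), L), stringsAsFactors = FALSE)
      best <- -Inf
      for (i in seq_len(nrow(grid))) {
        g <- unlist(grid[i, ], use.names = FALSE)
        if (!chain_is_strand_compatible(g, nome = case$nome)) next
        sc <- score_chain_naive(g, 1L, units, strands, win, cfg)
        if (sc > best) best <- sc
      }
      expect_equal(got$score, best, tolerance = 1e-9)
      expect_true(chain_is_strand_compatible(got$g, nome = case$nome))
      expect_equal(
        score_chain_naive(got$g, got$start, units, strands, win, cfg),
        got$score,
        tolerance = 1e-9
      )
    }
  }
})

test_that("error-free read pairs decode CpG methylation as in the conversion table", {
  win <- reference_window("AACGTT")
  cfg <- methaplo_config("wgbs-single", conversion_rate = 0.95, beta = 0.05)
  # unmethylated fragment: fwd read shows T at the CpG C, rev read shows A at the G
  units <- list(
    read_unit("f", 1L, "AATGTT", 1e-4),
    read_unit("r", 1L, "AACATT", 1e-4)
  )
  got <- optimal_epigenotype_chain(methaplo_reads(units), c("fwd", "rev"), win, cfg)
  expect_equal(got$g, c("A", "A", "C", "G", "T", "T"))
  # methylated fragment: C/C observed
  units <- list(
    read_unit("f", 1L, "AACGTT", 1e-4),
    read_unit("r", 1L, "AACGTT", 1e-4)
  )
  got <- optimal_epigenotype_chain(methaplo_reads(units), c("fwd", "rev"), win, cfg)
  expect_equal(got$g, c("A", "A", "M", "W", "T", "T"))
})

test_that("methylation is only called as a paired dinucleotide", {
  # 10 fwd reads all showing C at an isolated CpG -> meC-meG pair
  win <- reference_window("AACGTT")
  cfg <- methaplo_config("wgbs-single")
  units <- lapply(1:10, function(k) read_unit(paste0("r", k), 1L, "AACGTT", 0.01))
  got <- optimal_epigenotype_chain(methaplo_reads(units), rep("fwd", 10), win, cfg)
  expect_equal(got$g[3:4], c("M", "W"))
  # in NOMe mode a methylated GpC is the meG-meC pair
  winn <- reference_window("TTGCAA")
  cfgn <- methaplo_config("nome")
  units <- lapply(1:10, function(k) read_unit(paste0("r", k), 1L, "TTGCAA", 0.01))
  gotn <- optimal_epigenotype_chain(methaplo_reads(units), rep("fwd", 10), winn, cfgn)
  expect_equal(gotn$g[3:4], c("W", "M"))
})

test_that("structure prior follows the read-weighted chain form", {
  # 2 reads of length 100 in one chain of length 150
  expect_equal(
    log_prior_B(150, list(c(100, 100))),
    2 * (0.5 * log(150) + 2 * log(200))
  )
  # equal-length reads: general form differs from the n^2 sqrt(L) form by
  # a structure-independent constant
  simplified <- function(ns, Ls) sum(ns * (2 * log(ns) + 0.5 * log(Ls)))
  s1 <- log_prior_B(c(150, 80), list(rep(50, 3), rep(50, 2)))
  s2 <- log_prior_B(c(120, 110), list(rep(50, 4), rep(50, 1)))
  expect_equal(
    s1 - s2,
    simplified(c(3, 2), c(150, 80)) - simplified(c(4, 1), c(120, 110)),
    tolerance = 1e-12
  )
  # all-singleton structures have finite weight
  expect_true(is.finite(log_prior_B(c(50, 50), list(50, 50))))
  expect_error(log_prior_B(100, list(numeric(0))))
})

test_that("genotype prior weights reference agreement by q", {
  set.seed(5)
  win <- make_reference(length = 100, cpg_density = 0, seed = 5)
  ref_g <- strsplit(win$seq, "")[[1L]]
  chains <- list(list(start = 1L, end = 100L, g = ref_g))
  expect_equal(log_prior_G(chains, win, q = 0.9999), 100 * log(0.9999))
  # q = 0.5 gives every assignment the same weight
  rand_g <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  expect_equal(
    log_prior_G(list(list(start = 1L, end = 100L, g = rand_g)), win, q = 0.5),
    100 * log(0.5)
  )
  # one private mutation costs log(q / (1 - q))
  mut <- ref_g
  mut[40] <- setdiff(c("A", "C", "G", "T"), ref_g[40])[1L]
  expect_equal(
    log_prior_G(chains, win, q = 0.9999) -
      log_prior_G(list(list(start = 1L, end = 100L, g = mut)), win, q = 0.9999),
    log(0.9999 / (1 - 0.9999))
  )
})

test_that("the posterior is the sum of its parts and matches the optimizer", {
  for (s in 1:10) {
    inst <- sim_random_instance(seed = 200 + s, n_reads = 3 + s %% 3)
    f <- methaplo(inst$reads, inst$window, inst$config)
    chs <- lapply(f$chains, function(c) list(start = c$start, end = c$end, g = c$g))
    naive <- log_posterior(
      inst$reads, inst$window, inst$config,
      f$chain_of, f$strand, chs
    )
    expect_equal(naive, f$logLik, tolerance = 1e-6)
    # additivity: prior pieces plus likelihood reproduce the total
    Ls <- vapply(chs, function(c) c$end - c$start + 1, numeric(1L))
    rl <- lapply(seq_along(chs), function(k) {
      vapply(inst$reads$units[f$chain_of == k], function(u) u$n_bases, integer(1L))
    })
    lik <- naive - log_prior_B(Ls, rl) -
      log_prior_G(chs, inst$window, inst$config$q, inst$config$use_db)
    expect_true(is.finite(lik))
    expect_true(lik <= 0 + 1e-9) # a product of probabilities
  }
})

test_that("identical concordant reads merge; discordant epi-alleles stay apart", {
  cfg <- methaplo_config("wgbs-single") # K0 = 40, K1 = 1
  win <- win_repeat_acgt(30) # CpG every 4 bp
  meth <- strrep("ACGT", 15) # fwd read, fully methylated pattern
  unmeth <- strrep("ATGT", 15) # fwd read, converted pattern
  f <- methaplo(methaplo_reads(list(
    read_unit("a", 1L, meth, 0.01), read_unit("b", 1L, meth, 0.01)
  )), win, cfg)
  expect_equal(length(f$chains), 1L)
  f2 <- methaplo(methaplo_reads(list(
    read_unit("a", 1L, meth, 0.01), read_unit("b", 1L, unmeth, 0.01)
  )), win, cfg)
  expect_equal(length(f2$chains), 2L)
})

test_that("reads without the required CpG overlap never merge", {
  cfg <- methaplo_config("wgbs-single")
  win <- reference_window(strrep("AT", 60)) # no CpG anywhere
  f <- methaplo(methaplo_reads(list(
    read_unit("a", 1L, strrep("AT", 30), 0.01),
    read_unit("b", 1L, strrep("AT", 30), 0.01)
  )), win, cfg)
  expect_equal(length(f$chains), 2L)
})

test_that("single reads reproduce the exhaustive search exactly", {
  inst <- sim_random_instance(seed = 77, n_reads = 1L)
  f <- methaplo(inst$reads, inst$window, inst$config)
  o <- brute_force_fit(inst$reads, inst$window, inst$config)
  expect_equal(f$logLik, o$logLik, tolerance = 1e-9)
  expect_equal(f$chains[[1L]]$g, o$chains[[1L]]$g)
})

test_that("partitions with coverage gaps are excluded from the search", {
  cfg <- methaplo_config("wgbs-single")
  win <- win_repeat_acgt(50)
  reads <- methaplo_reads(list(
    read_unit("a", 1L, strrep("ACGT", 10), 0.01),
    read_unit("b", 101L, strrep("ACGT", 10), 0.01) # disjoint: gap 41..100
  ))
  o <- brute_force_fit(reads, win, cfg)
  expect_equal(length(o$chains), 2L) # the 1-chain partition is infeasible
  f <- methaplo(reads, win, cfg)
  expect_equal(f$logLik, o$logLik, tolerance = 1e-9)
})

test_that("empty input yields an empty fit", {
  win <- win_repeat_acgt(10)
  f <- methaplo(methaplo_reads(list()), win, methaplo_config("wgbs-single"))
  expect_equal(length(f$chains), 0L)
  expect_true(f$converged)
})
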