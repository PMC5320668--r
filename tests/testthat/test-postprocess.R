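# Post-inference: depth fraction, the noise filter, fit-ratios, combined
# genotypes, methylation levels, and NOMe accessibility.

# fake fits reused across blocks ---------------------------------------------

# two disjoint single-read chains and helpers
simple_window <- function() reference_window(strrep("ATTA", 100)) # no CpG/GpC

test_that("depth fraction is self-inclusive and splits by read mass", {
  win <- simple_window()
  cfg <- methaplo_config("wgbs-single")
  # a lone chain in its region
  u1 <- read_unit("a", 1L, strrep("A", 50), 0.01)
  u2 <- read_unit("b", 201L, strrep("A", 50), 0.01)
  f <- fake_fit(
    list(u1, u2), list(1L, 2L), c("fwd", "fwd"),
    list(rep("A", 50), rep("A", 50)), win, cfg
  )
  expect_equal(depth_fraction(f), c(1, 1))
  # 300 read-bp overlapped by one chain with 600 read-bp -> 1/3
  units <- c(
    lapply(1:3, function(k) read_unit(paste0("x", k), 1L, strrep("A", 100), 0.01)),
    lapply(1:6, function(k) read_unit(paste0("y", k), 51L, strrep("A", 100), 0.01))
  )
  f2 <- fake_fit(
    units, list(1:3, 4:9), rep("fwd", 9),
    list(rep("A", 100), rep("A", 100)), win, cfg
  )
  expect_equal(depth_fraction(f2), c(300 / 900, 600 / 900))
  # two identical chains split evenly
  f3 <- fake_fit(
    units[c(1, 4)], list(1L, 2L), c("fwd", "fwd"),
    list(rep("A", 100), rep("A", 100)), win, cfg
  )
  expect_equal(depth_fraction(f3), c(0.5, 0.5))
})

test_that("the keep rule is exact at its boundary and monotone", {
  # paired-WGBS defaults a = 10000, b = 28500
  expect_true(chain_keep_rule(10000, 0, 10000, 28500))
  expect_false(chain_keep_rule(9999, 0, 10000, 28500))
  expect_false(chain_keep_rule(500, 0.1, 10000, 28500)) # 500+2850 < 10000
  # with b >= a a full-depth chain is kept regardless of length
  expect_true(all(chain_keep_rule(c(1, 10, 100), 1, 10000, 28500)))
  # monotonicity in both arguments
  set.seed(21)
  L <- runif(200, 0, 20000)
  df <- runif(200)
  kept <- chain_keep_rule(L, df, 10000, 28500)
  expect_true(all(chain_keep_rule(L + 100, df, 10000, 28500) >= kept))
  expect_true(all(chain_keep_rule(L, pmin(df + 0.05, 1), 10000, 28500) >= kept))
})

test_that("filter_chains marks chains by length and depth fraction", {
  win <- simple_window()
  cfg <- methaplo_config("wgbs-single") # a = 5000, b = 20000
  units <- c(
    lapply(1:9, function(k) read_unit(paste0("x", k), 1L, strrep("A", 100), 0.01)),
    list(read_unit("y", 51L, strrep("A", 100), 0.01))
  )
  f <- fake_fit(
    units, list(1:9, 10L), rep("fwd", 10),
    list(rep("A", 100), rep("A", 100)), win, cfg
  )
  f <- filter_chains(f)
  # df = 0.9 and 0.1: 100 + 20000*0.9 >= 5000 kept; 100 + 2000 < 5000 removed
  expect_equal(f$kept, c(TRUE, FALSE))
})

test_that("position log-likelihoods match a naive recomputation", {
  set.seed(22)
  inst <- sim_random_instance(seed = 300, n_reads = 5L)
  f <- methaplo(inst$reads, inst$window, inst$config)
  for (k in seq_along(f$chains)) {
    ch <- f$chains[[k]]
    for (pos in unique(round(seq(ch$start, ch$end, length.out = 4)))) {
      got <- position_loglik(f, k, pos)
      for (x in c("A", "C", "G", "T", "M", "W")) {
        naive <- 0
        for (m in ch$members) {
          u <- f$reads$units[[m]]
          at <- which(u$pos == pos)
          for (i in at) {
            d <- c("A", "C", "G", "T", "N")[u$base[i] + 1L]
            naive <- naive +
              log(emission_prob(d, x, f$strand[m], u$eps[i], f$config$params))
          }
        }
        expect_equal(unname(got[x]), naive, tolerance = 1e-9)
      }
    }
  }
  expect_error(position_loglik(f, 1L, f$chains[[1L]]$end + 10L))
})

test_that("fit-ratios use the paired epigenotype sets and reward strong support", {
  f <- genotype_fit("C")
  fr <- fit_ratios(f, 1L, 11L)
  expect_equal(fr$g, "C")
  expect_equal(fr$ref, "T")
  expect_equal(fr$alt, "C")
  expect_lt(fr$F, -15) # well-supported epigenotype
  # F compares {g, projection} against the best of the rest (tabulated check)
  ell <- position_loglik(f, 1L, 11L)
  expect_equal(fr$F, 2 * (max(ell[c("A", "G", "T", "M", "W")]) - ell[["C"]]))
  # F_R pairs the reference T with itself only; F_A pairs C with meC
  expect_equal(fr$F_R, 2 * (max(ell[c("A", "C", "G", "M", "W")]) - ell[["T"]]))
  expect_equal(fr$F_A, 2 * (max(ell[c("A", "G", "T")]) - max(ell[c("C", "M")])))
  # adding an all-N read (supporting every state equally) leaves F unchanged
  f2 <- f
  nn <- read_unit("nn", 1L, strrep("N", 20), 0.01)
  f2$reads$units <- c(f2$reads$units, list(nn))
  f2$chains[[1L]]$members <- c(f2$chains[[1L]]$members, length(f2$reads$units))
  f2$strand <- c(f2$strand, "fwd")
  expect_equal(fit_ratios(f2, 1L, 11L)$F, fr$F)
})

test_that("the combined genotype aggregates passing chains into a call", {
  # two passing chains with C and one with T -> heterozygous CT
  f <- genotype_fit(c("C", "C", "T"))
  cg <- combined_genotype(f, 11L)
  expect_equal(cg$genotype, "CT")
  expect_equal(cg$n_chains, 3L)
  expect_false(cg$ambiguous)
  # all chains agreeing on A -> homozygous AA
  f2 <- genotype_fit(c("A", "A"))
  expect_equal(combined_genotype(f2, 11L)$genotype, "AA")
  # chains with too little evidence are excluded; none passing -> no-call
  f3 <- genotype_fit("C", n_fwd = 1L, n_rev = 0L)
  f3$window$allowed[11L, ] <- c(FALSE, FALSE, FALSE, TRUE) # drop the alt
  cg3 <- combined_genotype(f3, 11L)
  expect_true(is.na(cg3$genotype))
  expect_equal(cg3$n_chains, 0L)
})

test_that("methylation level is the read fraction in methylated chains", {
  win <- reference_window(paste0(strrep("A", 8), "CG", strrep("A", 10)))
  cfg <- methaplo_config("wgbs-single")
  units <- lapply(1:10, function(k) {
    read_unit(paste0("r", k), 1L, paste0(
      strrep("A", 8),
      if (k <= 6) "CG" else "TG", strrep("A", 10)
    ), 0.01)
  })
  gm <- c(rep("A", 8), "M", "W", rep("A", 10))
  gu <- c(rep("A", 8), "C", "G", rep("A", 10))
  f <- fake_fit(units, list(1:6, 7:10), rep("fwd", 10), list(gm, gu), win, cfg)
  ml <- methylation_level(f, 9L)
  expect_equal(ml$level, 0.6)
  expect_equal(ml$coverage, 10L)
  # a fully methylated lone chain
  f1 <- fake_fit(units[1:6], list(1:6), rep("fwd", 6), list(gm), win, cfg)
  expect_equal(methylation_level(f1, 9L)$level, 1)
  # relabeling chains does not change the level
  f_swap <- fake_fit(units, list(7:10, 1:6), rep("fwd", 10), list(gu, gm), win, cfg)
  expect_equal(methylation_level(f_swap, 9L)$level, 0.6)
  # non-CpG positions are rejected in WGBS mode; zero coverage is a no-call
  expect_error(methylation_level(f, 3L))
  f_far <- fake_fit(units[1], list(1L), "fwd",
    list(gm[1:20]), win, cfg)
  f_far$chains[[1L]]$members <- integer(0) # chain with no informative reads
  expect_true(is.na(methylation_level(f_far, 9L)$level))
})

test_that("methylation call table covers every reference CpG", {
  sim <- sim_asm_scenario(5)
  f <- filter_chains(methaplo(sim$reads, sim$window, methaplo_config("wgbs-paired")))
  mc <- methylation_calls(f)
  expect_equal(mc$pos, attr(sim, "cpg_c"))
  covered <- !is.na(mc$level)
  expect_true(all(mc$level[covered] >= 0 & mc$level[covered] <= 1))
  # ASM: interior island CpGs should show intermediate consensus levels
  interior <- mc$coverage > 10
  expect_true(all(mc$level[interior] > 0.15 & mc$level[interior] < 0.85))
})

test_that("accessibility profiles recover protected intervals per chain", {
  win <- reference_window(strrep("TGCAATTAGA", 12)) # isolated GpC every 10 bp
  cfg <- methaplo_config("nome")
  gpc_g <- which(bitwAnd(win$context, 64L) > 0L)
  # one chain, all GpCs accessible
  g_all <- rep("A", 120)
  seqs <- strsplit(win$seq, "")[[1L]]
  g_all <- ifelse(seqs %in% c("A", "C", "G", "T"), seqs, "A")
  g_acc <- g_all
  g_acc[gpc_g] <- "W"
  g_acc[gpc_g + 1L] <- "M"
  u <- read_unit("r", 1L, win$seq, 0.01)
  f <- fake_fit(list(u), list(1L), "fwd", list(g_acc), win, cfg)
  acc <- accessibility(f)
  expect_true(all(acc$sites$chain_consensus == 1))
  expect_equal(nrow(acc$intervals), 0L)
  # protect the middle four GpCs
  g_block <- g_acc
  blocked <- gpc_g[5:8]
  g_block[blocked] <- "G"
  g_block[blocked + 1L] <- "C"
  f2 <- fake_fit(list(u), list(1L), "fwd", list(g_block), win, cfg)
  acc2 <- accessibility(f2)
  expect_equal(nrow(acc2$intervals), 1L)
  expect_equal(acc2$intervals$n_gpc, 4L)
  expect_equal(acc2$intervals$start, floor((gpc_g[4] + gpc_g[5]) / 2))
  expect_equal(acc2$intervals$end, ceiling((gpc_g[8] + gpc_g[9]) / 2))
  # chain and read consensus agree when depth is uniform
  expect_equal(acc2$sites$chain_consensus, acc2$sites$read_consensus)
})
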