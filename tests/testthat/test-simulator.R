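# The synthetic read generator: reference construction, conversion logic,
# error channel calibration, determinism, and rate recovery.

test_that("reference generator honors explicit sequences and density 0", {
  win <- make_reference(seq = "ACGTACGT")
  expect_equal(win$seq, "ACGTACGT")
  win0 <- make_reference(length = 2000, cpg_density = 0, seed = 4)
  expect_false(grepl("CG", win0$seq))
  expect_equal(nchar(win0$seq), 2000L)
})

test_that("realized CpG counts track the requested density", {
  n <- sapply(1:40, function(s) {
    win <- make_reference(length = 1000, cpg_density = 0.03, seed = 400 + s)
    sum(bitwAnd(win$context, 1L) > 0L)
  })
  # planting follows a renewal process with expectation ~ density * length;
  # check the mean against simulation noise
  expect_gt(mean(n), 30 * 0.75)
  expect_lt(mean(n), 30 * 1.25)
})

test_that("simulation is bit-identical under a fixed seed", {
  win <- make_reference(length = 500, cpg_density = 0.05, seed = 9)
  al <- list(epiallele(1, meth = TRUE))
  s1 <- simulate_reads(win, al, depth = 5, read_len = 60, layout = "single", seed = 42)
  s2 <- simulate_reads(win, al, depth = 5, read_len = 60, layout = "single", seed = 42)
  expect_identical(
    lapply(s1$reads$units, function(u) u$base),
    lapply(s2$reads$units, function(u) u$base)
  )
  expect_identical(s1$truth, s2$truth)
})

test_that("perfect conversion produces the expected strand-specific patterns", {
  win <- make_reference(length = 600, cpg_density = 0.08, seed = 10)
  cpg_c <- which(bitwAnd(win$context, 1L) > 0L)
  cpg_g <- cpg_c + 1L
  for (meth in c(FALSE, TRUE)) {
    sim <- simulate_reads(win, list(epiallele(1, meth = meth)),
      depth = 10, read_len = 80, layout = "single",
      conversion_rate = 1, beta = 0, phred = 90, seed = 11
    )
    for (k in seq_along(sim$reads$units)) {
      u <- sim$reads$units[[k]]
      idx <- u$pos - win$start + 1L
      at_c <- idx %in% cpg_c
      at_g <- idx %in% cpg_g
      if (sim$truth$strand[k] == "fwd") {
        # unmethylated C -> T, methylated C stays C; G positions untouched
        expect_true(all(u$base[at_c] == (if (meth) 1L else 3L)))
        expect_true(all(u$base[at_g] == 2L))
      } else {
        # reverse-strand reads: C positions read back as C, G positions
        # reflect the reverse-strand C (A when converted, G when protected)
        expect_true(all(u$base[at_c] == 1L))
        expect_true(all(u$base[at_g] == (if (meth) 2L else 0L)))
      }
    }
  }
})

test_that("sequencing mismatch rate matches the Phred setting", {
  win <- make_reference(length = 2000, cpg_density = 0, seed = 12)
  sim <- simulate_reads(win, list(epiallele(1)),
    depth = 50, read_len = 100, layout = "single",
    conversion_rate = 1, beta = 0, phred = 20, seed = 13
  )
  ref <- win$base
  n_err <- 0L
  n_tot <- 0L
  # restrict to A/T reference positions: bisulfite conversion rewrites
  # every unmethylated C (and the rev-read view of G), CpG context or not
  for (u in sim$reads$units) {
    idx <- u$pos - win$start + 1L
    at <- ref[idx] %in% c(0L, 3L)
    n_err <- n_err + sum(u$base[at] != ref[idx][at])
    n_tot <- n_tot + sum(at)
  }
  p <- n_err / n_tot
  sigma <- sqrt(0.01 * 0.99 / n_tot)
  expect_lt(abs(p - 0.01), 3 * sigma + 1e-12)
})

test_that("paired layout emits two same-strand mates spanning the insert", {
  win <- make_reference(length = 500, cpg_density = 0.05, seed = 14)
  sim <- simulate_reads(win, list(epiallele(1)),
    depth = 4, read_len = 50, layout = "paired", insert = 120, seed = 15
  )
  for (u in sim$reads$units) {
    expect_equal(nrow(u$segs), 2L)
    expect_equal(u$hi - u$lo + 1L, 120L)
  }
})

test_that("method-of-moments recovery of the conversion rates", {
  win <- make_reference(length = 4000, cpg_density = 0.2, seed = 16)
  n_cpg <- sum(bitwAnd(win$context, 1L) > 0L)
  meth <- rep(c(TRUE, FALSE), length.out = n_cpg)
  sim <- simulate_reads(win, list(epiallele(1, meth = meth)),
    depth = 60, read_len = 100, layout = "single",
    conversion_rate = 0.95, beta = 0.05, phred = 90, seed = 17
  )
  est <- empirical_conversion_rates(sim)
  expect_gt(est$n_unmeth, 1e4)
  expect_gt(est$n_meth, 1e4)
  s_a <- sqrt(0.05 * 0.95 / est$n_unmeth)
  s_b <- sqrt(0.05 * 0.95 / est$n_meth)
  expect_lt(abs(est$alpha_fail - 0.05), 3 * s_a)
  expect_lt(abs(est$beta - 0.05), 3 * s_b)
  # degenerate corners
  sim0 <- simulate_reads(win, list(epiallele(1, meth = meth)),
    depth = 2, read_len = 100, layout = "single",
    conversion_rate = 1, beta = 0, phred = 90, seed = 18
  )
  est0 <- empirical_conversion_rates(sim0)
  expect_equal(est0$alpha_fail, 0)
  expect_equal(est0$beta, 0)
})

test_that("SNV overrides and NOMe accessibility shape the true epigenotype", {
  win <- reference_window(paste0("AAAA", strrep("TGCAATTAGA", 4), "ACGTAA"))
  al <- epiallele(1, meth = TRUE, accessible = c(TRUE, FALSE, TRUE, FALSE),
    snv = c("2" = "T"))
  epi <- methaplo:::.allele_epigenotype(win, al, nome = TRUE)
  expect_equal(epi[2], 3L) # SNV applied
  gpc_g <- which(bitwAnd(win$context, 64L) > 0L)
  expect_equal(epi[gpc_g[1]], 5L) # accessible: meG
  expect_equal(epi[gpc_g[2]], 2L) # protected: plain G
  cpg_c <- which(bitwAnd(win$context, 1L) > 0L)
  expect_equal(epi[cpg_c[1]], 4L) # methylated CpG: meC
})
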