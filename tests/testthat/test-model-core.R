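# The six-state observation model: bisulfite conversion table, sequencing
# emission, Phred mapping, and the error-free observable map.

test_that("conversion probabilities match the model's defining entries", {
  p <- conversion_params(conversion_rate = 0.95, beta = 0.05)
  # failed conversion leaves an unmethylated C as C on its own strand
  expect_equal(conversion_prob("C", "C", "fwd", p), 0.05)
  expect_equal(conversion_prob("T", "C", "fwd", p), 0.95)
  # plain A is read faithfully
  expect_equal(conversion_prob("A", "A", "fwd", p), 1)
  expect_equal(conversion_prob("C", "A", "fwd", p), 0)
  # methylated C is protected except for inappropriate conversion
  expect_equal(conversion_prob("T", "M", "fwd", p), 0.05)
  expect_equal(conversion_prob("C", "M", "fwd", p), 0.95)
  # the complementary strand sees the partner base deterministically
  expect_equal(conversion_prob("C", "C", "rev", p), 1)
  expect_equal(conversion_prob("G", "G", "fwd", p), 1)
  # reverse-strand reads see the conversion of the reverse-strand C at G sites
  expect_equal(conversion_prob("A", "G", "rev", p), 0.95)
  expect_equal(conversion_prob("G", "G", "rev", p), 0.05)
  expect_equal(conversion_prob("A", "W", "rev", p), 0.05)
  expect_error(conversion_prob("N", "C", "fwd", p))
  expect_error(conversion_prob("C", "X", "fwd", p))
})

test_that("conversion and emission are probability distributions over the grid", {
  for (cr in c(0.8, 0.95, 1)) {
    for (b in c(0, 0.05, 0.2)) {
      p <- conversion_params(cr, b)
      for (g in c("A", "C", "G", "T", "M", "W")) {
        for (r in c("fwd", "rev")) {
          expect_equal(sum(conversion_prob(c("A", "C", "G", "T"), g, r, p)), 1,
            tolerance = 1e-12
          )
          for (e in c(0, 1e-4, 0.01, 0.3, 0.75)) {
            expect_equal(
              sum(emission_prob(c("A", "C", "G", "T"), g, r, e, p)), 1,
              tolerance = 1e-12
            )
          }
        }
      }
    }
  }
})

test_that("strand symmetry: fwd entries equal complemented rev entries", {
  p <- conversion_params(0.9, 0.08)
  comp_b <- c(A = "T", C = "G", G = "C", T = "A")
  comp_g <- c(A = "T", C = "G", G = "C", T = "A", M = "W", W = "M")
  for (z in names(comp_b)) {
    for (g in names(comp_g)) {
      expect_equal(
        conversion_prob(z, g, "fwd", p),
        conversion_prob(comp_b[[z]], comp_g[[g]], "rev", p)
      )
    }
  }
})

test_that("emission reduces to conversion at zero error and is 1 for N", {
  p <- conversion_params()
  for (g in c("A", "C", "M", "W")) {
    for (d in c("A", "C", "G", "T")) {
      expect_equal(
        emission_prob(d, g, "fwd", 0, p),
        conversion_prob(d, g, "fwd", p)
      )
    }
  }
  expect_equal(emission_prob("N", "M", "fwd", 0.3, p), 1)
  # hand evaluation: (1 - 4/3*0.03) * 0.95 + 0.01
  expect_equal(emission_prob("C", "M", "fwd", 0.03, p), 0.922)
})

test_that("Phred conversion follows the definition with clamping", {
  expect_equal(phred_to_epsilon(10), 0.1)
  expect_equal(phred_to_epsilon(30), 0.001)
  expect_equal(phred_to_epsilon(0), 0.75) # clamped from 1.0
  expect_equal(phred_to_epsilon(90), 1e-6) # lower clamp
  expect_error(phred_to_epsilon(-1))
})

test_that("exactly six error-free observable pairs exist and decode uniquely", {
  obs <- enumerate_error_free_observables()
  expect_equal(nrow(obs), 6L)
  pairs <- paste(obs$fwd, obs$rev)
  expect_equal(length(unique(pairs)), 6L)
  # the fragment-level map of the conversion figure
  expected <- data.frame(
    epigenotype = c("A", "C", "G", "T", "M", "W"),
    fwd = c("A", "T", "G", "T", "C", "G"),
    rev = c("A", "C", "A", "T", "C", "G"),
    stringsAsFactors = FALSE
  )
  expect_equal(obs[order(obs$epigenotype), ], expected[order(expected$epigenotype), ],
    ignore_attr = TRUE
  )
})

test_that("observed pairs invert to the generating fragment state", {
  # G/A pair: the forward strand carries G, the reverse-strand C unmethylated
  d <- decode_observable_pair("G", "A")
  expect_equal(unique(d$epigenotype), "G")
  expect_equal(d$read1_strand, "fwd")
  # A/A pair comes from an A-T fragment (strand of each read is ambiguous)
  d <- decode_observable_pair("A", "A")
  expect_equal(unique(d$epigenotype), "A")
  expect_equal(nrow(d), 2L)
  # with only one strand observed, at least one base is ambiguous:
  # a lone T is consistent with epigenotypes C and T
  p0 <- conversion_params(1, 0)
  consistent <- Filter(
    function(g) {
      any(c(
        conversion_prob("T", g, "fwd", p0),
        conversion_prob("T", g, "rev", p0)
      ) > 0)
    },
    c("A", "C", "G", "T", "M", "W")
  )
  expect_true(all(c("C", "T") %in% consistent))
})

test_that("epigenotype projection collapses methylation onto nucleotides", {
  expect_equal(epi_projection(c("A", "C", "G", "T", "M", "W")),
    c("A", "C", "G", "T", "C", "G"))
  expect_equal(epi_projection("meC"), "C")
  expect_equal(epi_projection("meG"), "G")
})
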