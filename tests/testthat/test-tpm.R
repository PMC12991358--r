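test_that("the tau=1 empirical TPM equals the truth-table TPM exactly", {
  m <- reference_gate_model(steps_per_run = 8)
  expect_equal(unname(m$tpm), oracle_gate_tpm())
  expect_true(all(m$tpm %in% c(0, 1)))
})

test_that("binarization maps subthreshold potentials to state 0", {
  # from (1,0,0) the AND neuron sits at 50 mV (subthreshold) on step 1
  tr <- simulate_iaf(gate_network(), c(1, 0, 0), 4)
  expect_equal(tr$v[1, "AND"], 50, ignore_attr = TRUE)
  expect_equal(binarize(tr)[1, ], c(0L, 0L, 1L), ignore_attr = TRUE)
  # an all-silent trace binarizes to all zeros
  tr0 <- simulate_iaf(gate_network(), c(0, 0, 0), 4)
  expect_true(all(binarize(tr0) == 0L))
})

test_that("every empirical TPM row is a probability distribution", {
  for (tau in c(1, 3, 6)) for (w in c(25, 62.5, 100)) {
    m <- empirical_tpm(gate_network(w = w, tau = tau), steps_per_run = 60)
    expect_equal(rowSums(m$tpm), rep(1, 8), ignore_attr = TRUE)
    expect_true(all(m$tpm >= 0 & m$tpm <= 1))
  }
})

test_that("leaky dynamics yield fractional transition probabilities", {
  m <- empirical_tpm(gate_network(w = 62.5, tau = 4), steps_per_run = 200)
  expect_true(any(m$tpm > 0 & m$tpm < 1))
})

test_that("pooling is idempotent for memoryless (tau = 1) networks", {
  for (w in c(25, 50, 87.5)) {
    short <- empirical_tpm(gate_network(w = w, tau = 1), steps_per_run = 8)
    long <- empirical_tpm(gate_network(w = w, tau = 1), steps_per_run = 16)
    expect_equal(short$tpm, long$tpm)
  }
})

test_that("connectivity matrices mirror nonzero weights", {
  cm <- connectivity_matrix(gate_network())
  expect_equal(unname(cm), 1L - diag(3L))
  expect_true(all(connectivity_matrix(gate_network(w = 0)) == 0L))
  net4 <- add_source_node(gate_network(), target = 1, weight = 50)
  cm4 <- connectivity_matrix(net4)
  expect_equal(dim(cm4), c(4, 4))
  expect_equal(unname(cm4[, 4]), rep(0L, 4))        # nothing feeds the source
  expect_equal(unname(cm4[4, ]), c(1L, 0L, 0L, 0L)) # source feeds OR only
})

test_that("transition models survive JSON and delimited round-trips", {
  m <- empirical_tpm(gate_network(w = 62.5, tau = 3), steps_per_run = 40)
  f <- tempfile(fileext = ".json")
  write_transition_model(m, f)
  m2 <- read_transition_model(f)
  expect_equal(m$tpm, m2$tpm)
  expect_equal(unname(m$cm), unname(m2$cm))
  ft <- tempfile(fileext = ".tsv")
  write_tpm_table(m, ft)
  hdr <- readLines(ft, n = 1)
  expect_match(hdr, "ordering=little-endian")
  got <- as.matrix(utils::read.delim(ft, skip = 1, row.names = 1))
  expect_equal(unname(got), unname(m$tpm), tolerance = 1e-12)
})

test_that("malformed TPMs are rejected with a diagnostic", {
  bad <- matrix(1 / 8, 8, 8)
  bad[3, ] <- bad[3, ] * 1.5
  expect_error(transition_model(bad, matrix(1L, 3, 3)), "sum to 1")
  expect_error(transition_model(matrix(1 / 4, 4, 4), matrix(1L, 3, 3)),
               "2\\^n")
})
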