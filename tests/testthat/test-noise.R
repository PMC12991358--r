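test_that("Poisson trains have the requested rate and are reproducible", {
  tr <- poisson_train(3, 1000, seed = 1)
  p <- 1 / 3
  expect_lt(abs(mean(tr) - p), 3 * sqrt(p * (1 - p) / 1000))
  expect_true(all(tr %in% c(0L, 1L)))
  expect_identical(poisson_train(5, 200, seed = 7),
                   poisson_train(5, 200, seed = 7))
  expect_equal(poisson_train(Inf, 100, seed = 1), rep(0L, 100))
})

test_that("relative change computes percentages with the x sentinel", {
  base <- tibble::tibble(state = c("00", "01", "10", "11"),
                         phi = c(0.5, 0, 0.3, NA),
                         status = c("ok", "ok", "ok", "unreachable"))
  noisy <- tibble::tibble(state = c("00", "01", "10", "11"),
                          phi = c(1.0, 0.3, 0.3, 0.2),
                          status = "ok")
  rc <- relative_change(base, noisy)
  expect_equal(rc$rel_change, c(100, NA, 0, NA))
  expect_equal(rc$rel_label, c("100.0", "x", "0.0", NA))
  expect_error(relative_change(base[1:2, ], noisy), "not aligned")
})

test_that("the infinite-interval limit reproduces the deterministic table", {
  net <- gate_network(w = 62.5, tau = 2)
  base <- phi_internal_noise(net, Inf, steps_per_run = 300, seed = 5)
  det <- iafphi:::phi_per_state(empirical_tpm(net, steps_per_run = 300))
  expect_identical(base, det)
})

test_that("noisy Phi tables are bit-identical for a fixed seed", {
  net <- gate_network(w = 62.5, tau = 2)
  a <- phi_internal_noise(net, 3, steps_per_run = 300, seed = 9)
  b <- phi_internal_noise(net, 3, steps_per_run = 300, seed = 9)
  expect_identical(a, b)
  # noise makes the TPM genuinely stochastic in the working range
  m <- empirical_tpm(net, steps_per_run = 300,
                     noise = poisson_input(3), seed = 9)
  expect_true(any(m$tpm > 0 & m$tpm < 1))
})

test_that("the feedforward 4-element system is reducible for every state", {
  tab <- phi_external_noise(gate_network(), mean_interval = 3,
                            steps_per_run = 400, seed = 21)
  expect_equal(nrow(tab), 16)
  ok <- tab[tab$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$phi == 0))
})

test_that("mean Phi vs interval summarises the sweep and hits the noise-free mean", {
  res <- mean_phi_vs_interval(c(3, Inf), taus = 2, weights = 62.5,
                              steps_per_run = 200, seed = 4)
  expect_equal(nrow(res), 2)
  expect_true(all(res$sem >= 0 | is.na(res$sem)))
  det <- iafphi:::phi_per_state(
    empirical_tpm(gate_network(w = 62.5, tau = 2), steps_per_run = 200))
  expect_equal(res$mean_phi[2], mean(det$phi[det$status == "ok"]))
})
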