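# The Phi engine, validated bottom-up: exact EMD, repertoires against
# brute-force enumeration, small phi, and big Phi structural properties.

test_that("the exact EMD solver matches closed-form cases", {
  D <- iafphi:::hamming_cost(2)
  # identical distributions move nothing
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(iafphi:::emd_exact(p, p, D), 0)
  # point masses pay the ground distance
  e1 <- c(1, 0, 0, 0); e4 <- c(0, 0, 0, 1)
  expect_equal(iafphi:::emd_exact(e1, e4, D), 2)  # Hamming((0,0),(1,1))
  expect_equal(iafphi:::emd_exact(e1, c(0, 1, 0, 0), D), 1)
  # symmetry
  q <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(iafphi:::emd_exact(p, q, D), iafphi:::emd_exact(q, p, D))
})

test_that("EMD between product distributions is the sum of marginal gaps", {
  # For independent (product) distributions over binary nodes with the
  # Hamming ground metric, the EMD has the closed form sum_i |p_i - q_i|.
  prod_dist <- function(pr) {
    d <- 1
    for (p in pr) d <- c(d * (1 - p), d * p)
    d
  }
  set.seed(42)
  for (k in 2:4) {
    D <- iafphi:::hamming_cost(k)
    for (rep in 1:5) {
      a <- runif(k); b <- runif(k)
      expect_equal(iafphi:::emd_exact(prod_dist(a), prod_dist(b), D),
                   sum(abs(a - b)), tolerance = 1e-9)
    }
  }
})

test_that("unreachable gate states are flagged and reachable ones are not", {
  m <- reference_gate_model()
  for (s in reference_unreachable) expect_false(check_reachable(m, s))
  for (s in names(reference_phi)) expect_true(check_reachable(m, s))
  uniform <- transition_model(matrix(1 / 8, 8, 8), matrix(1L, 3, 3))
  for (k in 1:8) expect_true(check_reachable(uniform, all_states(3)[k, ]))
})

test_that("gate-system repertoires match brute-force enumeration", {
  m <- reference_gate_model()
  # cause: mechanism {OR = 1}, purview {AND, XOR}
  cr <- cause_repertoire(m, c(1, 0, 0), mechanism = 1, purview = c(2, 3))
  expect_equal(cr$distribution, oracle_gate_cause(1, 1, c(2, 3)))
  expect_equal(cr$distribution, c(0, 1, 1, 1) / 3)
  # effect: mechanism {AND = 0}, purview {OR}
  er <- effect_repertoire(m, c(1, 0, 0), mechanism = 2, purview = 1)
  p_on <- oracle_gate_effect(2, 0, 1)
  expect_equal(er$distribution, c(1 - p_on, p_on))
  expect_equal(er$distribution, c(0.5, 0.5))
  # empty mechanism: unconstrained (uniform) past
  expect_equal(
    cause_repertoire(m, c(1, 0, 0), integer(), c(1, 2, 3))$distribution,
    rep(1 / 8, 8))
  # deterministic whole-system mechanism pins the successor state
  er_all <- effect_repertoire(m, c(1, 0, 0), mechanism = 1:3, purview = 1:3)
  expect_equal(er_all$distribution[state_index(oracle_gate_next(c(1, 0, 0)))], 1)
  expect_equal(sum(er_all$distribution), 1)
})

test_that("repertoires stay normalized across mechanisms and purviews", {
  m <- empirical_tpm(gate_network(w = 62.5, tau = 3), steps_per_run = 100)
  for (mech in list(1L, 2L, c(1L, 3L), 1:3)) {
    for (pv in list(1L, c(2L, 3L), 1:3)) {
      expect_equal(sum(cause_repertoire(m, c(1, 1, 1), mech, pv)$distribution), 1)
      expect_equal(sum(effect_repertoire(m, c(1, 1, 1), mech, pv)$distribution), 1)
    }
  }
})

test_that("disconnected systems carry no irreducible mechanisms", {
  m <- random_model(3, seed = 5, cm = matrix(0L, 3, 3))
  # every repertoire equals the unconstrained one
  expect_equal(cause_repertoire(m, c(1, 0, 1), 1, c(2, 3))$distribution,
               rep(1 / 4, 4))
  for (mech in list(1L, c(1L, 2L), 1:3)) {
    expect_equal(small_phi(m, c(1, 0, 1), mech, "cause")$phi, 0)
    expect_equal(small_phi(m, c(1, 0, 1), mech, "effect")$phi, 0)
  }
  expect_equal(big_phi(m, c(1, 0, 1))$phi, 0)
})

test_that("gate mechanisms are irreducible where theory demands", {
  m <- reference_gate_model()
  sp <- small_phi(m, c(1, 0, 0), 1, "cause")
  expect_gt(sp$phi, 0)
  expect_true(length(sp$purview) >= 1)
})

test_that("big Phi is nonnegative, reproducible and zero for reducible systems", {
  m <- reference_gate_model()
  r1 <- big_phi(m, "100"); r2 <- big_phi(m, "100")
  expect_identical(r1$phi, r2$phi)
  expect_gte(r1$phi, 0)
  expect_gt(r1$n_concepts, 0)
  expect_true(all(r1$concepts$phi > 0))
  # the minimizing cut is a genuine bipartition
  expect_setequal(c(r1$cut$from, r1$cut$to), 1:3)
  # block structure (independent 2-node and 1-node subsystems) gives Phi 0
  set.seed(9)
  t2 <- matrix(rgamma(16, 1), 4, 4); t2 <- t2 / rowSums(t2)
  t1 <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE)
  tpm <- matrix(0, 8, 8)
  bits <- all_states(3)
  for (s in 1:8) for (t in 1:8) {
    s2 <- 1 + bits[s, 1] + 2 * bits[s, 2]; t2i <- 1 + bits[t, 1] + 2 * bits[t, 2]
    tpm[s, t] <- t2[s2, t2i] * t1[1 + bits[s, 3], 1 + bits[t, 3]]
  }
  cm <- matrix(0L, 3, 3); cm[1:2, 1:2] <- 1L; cm[3, 3] <- 1L
  mb <- transition_model(tpm, cm)
  expect_equal(big_phi(mb, c(0, 1, 0))$phi, 0)
})

test_that("Phi is invariant under node relabelling", {
  for (seed in c(11, 12)) {
    m <- random_model(3, seed)
    st <- c(1, 0, 1)
    base <- big_phi(m, st)$phi
    for (perm in list(c(2, 3, 1), c(3, 2, 1))) {
      pm <- permute_model(m, perm, st)
      expect_equal(big_phi(pm$model, pm$state)$phi, base, tolerance = 1e-6)
    }
  }
})

test_that("unreachable states carry no Phi value and tidy methods work", {
  m <- reference_gate_model()
  r <- big_phi(m, "010")
  expect_equal(r$status, "unreachable")
  expect_true(is.na(r$phi))
  expect_equal(nrow(tidy(r)), 0)
  g <- glance(big_phi(m, "100"))
  expect_s3_class(g, "tbl_df")
  expect_equal(g$status, "ok")
  f <- tempfile(fileext = ".json")
  write_big_phi(big_phi(m, "100"), f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$phi, big_phi(m, "100")$phi)
})
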