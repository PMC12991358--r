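# Independent oracles: pure truth-table gate logic (no membrane potentials)
# and brute-force repertoire enumeration for the fully connected OR-AND-XOR
# system. These never call the simulator or the Phi engine.

# One synchronous update of the gate system: A = OR(B, C), B = AND(A, C),
# C = XOR(A, B), all reading the previous state.
oracle_gate_next <- function(s) {
  c(
    as.integer(s[2] | s[3]),
    as.integer(s[1] & s[3]),
    as.integer(xor(s[1], s[2]))
  )
}

# Deterministic 8x8 truth-table TPM in the package state ordering.
oracle_gate_tpm <- function() {
  states <- all_states(3)
  tpm <- matrix(0, 8, 8)
  for (k in 1:8) {
    nxt <- oracle_gate_next(states[k, ])
    tpm[k, state_index(nxt)] <- 1
  }
  tpm
}

# Brute-force single-mechanism cause repertoire for the gate system:
# enumerate all 8 equally likely prior states, keep those for which the
# mechanism node's update matches its observed state, and histogram the
# prior purview states.
oracle_gate_cause <- function(node, observed, purview) {
  states <- all_states(3)
  w <- numeric(2^length(purview))
  for (k in 1:8) {
    if (oracle_gate_next(states[k, ])[node] == observed) {
      sub <- states[k, purview]
      idx <- 1 + sum(sub * 2^(seq_along(purview) - 1))
      w[idx] <- w[idx] + 1
    }
  }
  w / sum(w)
}

# Brute-force single-node effect repertoire: probability that `node` fires
# next, averaging uniformly over all prior states consistent with the
# mechanism assignment.
oracle_gate_effect <- function(mechanism, values, node) {
  states <- all_states(3)
  keep <- apply(states, 1, function(s) all(s[mechanism] == values))
  mean(apply(states[keep, , drop = FALSE], 1,
             function(s) oracle_gate_next(s)[node]))
}

# Random row-stochastic state-by-state TPM over n nodes.
random_model <- function(n, seed, cm = matrix(1L, n, n)) {
  set.seed(seed)
  tpm <- matrix(rgamma(4^n, 1), 2^n, 2^n)
  transition_model(tpm / rowSums(tpm), cm)
}

# Permute the nodes of a model: old node i moves to position perm[i].
permute_model <- function(model, perm, state) {
  n <- model$n
  bits <- all_states(n)
  idx <- apply(bits, 1, function(x) {
    y <- integer(n); y[perm] <- x
    1 + sum(y * 2^(seq_len(n) - 1))
  })
  tpm2 <- matrix(0, 2^n, 2^n)
  tpm2[idx, idx] <- model$tpm
  cm2 <- matrix(0L, n, n)
  cm2[perm, perm] <- model$cm
  st2 <- integer(n); st2[perm] <- state
  list(model = transition_model(tpm2, cm2), state = st2)
}

reference_gate_model <- function(steps_per_run = 8) {
  empirical_tpm(gate_network(w = 50, tau = 1), steps_per_run = steps_per_run)
}

# Published reference Phi values for the fully connected OR-AND-XOR system
# (reachable states), state label -> Phi.
reference_phi <- c(
  "000" = 0.666668, "001" = 0.25, "100" = 1.916665,
  "101" = 1.816667, "110" = 0.25, "111" = 0.666668
)
reference_unreachable <- c("010", "011")
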