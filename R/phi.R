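# Integrated information (IIT 3.0) engine.
#
# The engine consumes a state-by-state TPM plus a connectivity matrix and a
# current binary state. Internally it derives the per-node conditional spike
# probabilities p_i(s) = P(node i ON next | current state s) by
# marginalisation (the state-by-node view used by the reference IIT 3.0
# semantics), marginalises each node's view over its non-inputs according to
# the connectivity matrix, and computes:
#   - cause/effect repertoires of a mechanism over a purview,
#   - small phi via the minimum-information partition (earth-mover's
#     distance, Hamming ground metric over purview states),
#   - concepts and the cause-effect structure (constellation),
#   - big Phi as the minimum over unidirectional system cuts of the extended
#     EMD between the intact and cut constellations.
# phi/Phi values and distances are rounded at 1e-6 before comparisons, the
# printed precision of the reference implementation.

PHI_PRECISION <- 6L

.cache <- new.env(parent = emptyenv())

hamming_cost <- function(k) {
  key <- paste0("ham", k)
  if (is.null(.cache[[key]])) {
    b <- all_states(k)
    m <- matrix(0, 2^k, 2^k)
    for (i in seq_len(2^k)) for (j in seq_len(2^k))
      m[i, j] <- sum(b[i, ] != b[j, ])
    .cache[[key]] <- m
  }
  .cache[[key]]
}

# All subsets of 1..n in powerset order (size ascending, lexicographic
# within size), as a list of integer vectors.
powerset_sets <- function(n, nonempty = TRUE) {
  key <- paste0("pow", n, nonempty)
  if (is.null(.cache[[key]])) {
    out <- list()
    for (size in seq_len(n)) {
      cmb <- utils::combn(n, size)
      out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    }
    if (!nonempty) out <- c(list(integer()), out)
    .cache[[key]] <- out
  }
  .cache[[key]]
}

set_mask <- function(nodes) if (length(nodes)) sum(2^(nodes - 1)) else 0

# Index (1-based) of each full state's restriction to the sorted node subset.
restriction_index <- function(bits, nodes) {
  if (!length(nodes)) return(rep(1L, nrow(bits)))
  as.integer(bits[, nodes, drop = FALSE] %*% 2^(seq_along(nodes) - 1)) + 1L
}

# ---- Subsystem -------------------------------------------------------------

# A subsystem bundles the factorized node views under an optional
# unidirectional cut, the current state, and a repertoire cache.
new_subsystem <- function(model, state, cut = NULL) {
  n <- model$n
  bits <- all_states(n)
  sbn <- model$tpm %*% bits           # P(node i on | current state), raw
  cm <- model$cm
  if (!is.null(cut)) cm[cut$from, cut$to] <- 0L
  node_p <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sbn[, i]
    for (j in seq_len(n)) {
      if (cm[j, i] == 0) {
        # marginalise (noise) non-input j uniformly
        flip <- ifelse(bits[, j] == 0L, seq_len(2^n) + 2^(j - 1),
                       seq_len(2^n) - 2^(j - 1))
        p <- (p + p[flip]) / 2
      }
    }
    node_p[[i]] <- p
  }
  env <- new.env(parent = emptyenv())
  list(n = n, state = state, bits = bits, cm = cm, node_p = node_p,
       cut = cut, cache = env)
}

# Effect repertoire of mechanism (in its current state) over purview.
# Product over purview nodes of the conditional ON-probability with the
# mechanism fixed and all other nodes noised.
sub_effect_rep <- function(ss, mechanism, purview) {
  if (!length(purview)) return(1)
  sel <- rep(TRUE, 2^ss$n)
  for (i in mechanism) sel <- sel & (ss$bits[, i] == ss$state[i])
  dist <- 1
  for (j in purview) {
    p_on <- mean(ss$node_p[[j]][sel])
    dist <- c(dist * (1 - p_on), dist * p_on)  # node j becomes next bit
  }
  dist
}

# Cause repertoire of mechanism over purview: product over mechanism nodes
# of the likelihood of the node's current state given each past purview
# state (non-purview past nodes uniform), normalized.
sub_cause_rep <- function(ss, mechanism, purview) {
  if (!length(purview)) return(1)
  k <- length(purview)
  if (!length(mechanism)) return(rep(1 / 2^k, 2^k))
  grp <- restriction_index(ss$bits, purview)
  lik <- rep(1, 2^k)
  for (i in mechanism) {
    q <- if (ss$state[i] == 1) ss$node_p[[i]] else 1 - ss$node_p[[i]]
    li <- as.vector(rowsum(q, grp)) / 2^(ss$n - k)
    lik <- lik * li
  }
  s <- sum(lik)
  if (s == 0) rep(0, 2^k) else lik / s
}

sub_repertoire <- function(ss, direction, mechanism, purview) {
  key <- paste0(substr(direction, 1, 1), set_mask(mechanism), "|",
                set_mask(purview))
  r <- ss$cache[[key]]
  if (is.null(r)) {
    r <- if (direction == "cause") sub_cause_rep(ss, mechanism, purview)
         else sub_effect_rep(ss, mechanism, purview)
    ss$cache[[key]] <- r
  }
  r
}

# Joint distribution over sorted union purview from two part repertoires.
combine_parts <- function(purview, p1, r1, p2, r2) {
  k <- length(purview)
  bitsP <- all_states(k)
  out <- rep(1, 2^k)
  if (length(p1)) {
    idx1 <- restriction_index(bitsP, match(p1, purview))
    out <- out * r1[idx1]
  }
  if (length(p2)) {
    idx2 <- restriction_index(bitsP, match(p2, purview))
    out <- out * r2[idx2]
  }
  out
}

# EMD between distributions over the states of a k-node purview.
rep_distance <- function(direction, d1, d2, k) {
  if (direction == "cause") {
    emd_exact(d1, d2, hamming_cost(k))
  } else {
    # For product (effect) repertoires the Hamming EMD reduces to the sum of
    # per-node marginal differences.
    b <- all_states(k)
    tot <- 0
    for (j in seq_len(k)) {
      off <- b[, j] == 0L
      tot <- tot + abs(sum(d1[off]) - sum(d2[off]))
    }
    tot
  }
}

# Minimum-information partition of (mechanism, purview) in one direction.
find_mip <- function(ss, direction, mechanism, purview) {
  whole <- sub_repertoire(ss, direction, mechanism, purview)
  k <- length(purview)
  if (sum(whole) == 0) {
    return(list(phi = 0, partition = NULL, repertoire = whole))
  }
  nm <- length(mechanism)
  best <- Inf; best_part <- NULL
  # Unordered bipartitions of the mechanism: the first mechanism node is
  # always assigned to part 2.
  m_rest <- mechanism[-1]
  m_subsets <- powerset_sets_of(m_rest)
  p_subsets <- powerset_sets_of(purview, nonempty = FALSE)
  for (M1 in m_subsets) {
    M2 <- setdiff(mechanism, M1)
    for (P1 in p_subsets) {
      P2 <- setdiff(purview, P1)
      if ((length(M1) + length(P1)) == 0) next
      if ((length(M2) + length(P2)) == 0) next
      r1 <- if (length(P1)) sub_repertoire(ss, direction, M1, P1) else NULL
      r2 <- if (length(P2)) sub_repertoire(ss, direction, M2, P2) else NULL
      part <- combine_parts(purview, P1, r1, P2, r2)
      if (max(abs(whole - part)) < 1e-12) {
        best <- 0
        best_part <- list(m1 = M1, p1 = P1, m2 = M2, p2 = P2)
        break
      }
      d <- round(rep_distance(direction, whole, part, k), PHI_PRECISION)
      if (d < best) {
        best <- d
        best_part <- list(m1 = M1, p1 = P1, m2 = M2, p2 = P2)
        if (best == 0) break
      }
    }
    if (best == 0) break
  }
  list(phi = if (is.finite(best)) best else 0, partition = best_part,
       repertoire = whole)
}

# All subsets of an arbitrary node vector (size ascending, lexicographic).
powerset_sets_of <- function(nodes, nonempty = FALSE) {
  k <- length(nodes)
  if (k == 0) return(list(integer()))
  lapply(powerset_sets(k, nonempty), function(ix) nodes[ix])
}

# Is the cm block from `from` to `to` trivially reducible (some row or
# column all zero)? Then every partition quotient is exact and phi = 0.
block_reducible <- function(cm, from, to) {
  if (!length(from) || !length(to)) return(TRUE)
  blk <- cm[from, to, drop = FALSE]
  any(rowSums(blk) == 0) || any(colSums(blk) == 0)
}

# Maximally irreducible cause or effect: max over purviews of the MIP phi.
# Ties prefer the larger purview, then the earlier purview in powerset
# order.
find_mice <- function(ss, direction, mechanism) {
  purviews <- powerset_sets(ss$n)
  keep <- vapply(purviews, function(P) {
    if (direction == "effect") !block_reducible(ss$cm, mechanism, P)
    else !block_reducible(ss$cm, P, mechanism)
  }, logical(1))
  purviews <- purviews[keep]
  best <- list(phi = 0, purview = integer(), partition = NULL,
               repertoire = NULL)
  for (P in purviews) {
    mip <- find_mip(ss, direction, mechanism, P)
    if (mip$phi > best$phi ||
        (mip$phi == best$phi && mip$phi > 0 &&
         length(P) > length(best$purview))) {
      best <- list(phi = mip$phi, purview = P, partition = mip$partition,
                   repertoire = mip$repertoire)
    }
  }
  best
}

# Concept of a mechanism: phi = min(phi_cause, phi_effect); retained only
# when positive.
sub_concept <- function(ss, mechanism) {
  cause <- find_mice(ss, "cause", mechanism)
  if (cause$phi == 0) return(NULL)
  effect <- find_mice(ss, "effect", mechanism)
  phi <- min(cause$phi, effect$phi)
  if (phi <= 0) return(NULL)
  list(mechanism = mechanism, phi = phi, cause = cause, effect = effect,
       subsystem = ss)
}

# Cause-effect structure: concepts of all mechanisms (or a given list).
sub_ces <- function(ss, mechanisms = NULL) {
  if (is.null(mechanisms)) mechanisms <- powerset_sets(ss$n)
  out <- list()
  for (M in mechanisms) {
    cpt <- sub_concept(ss, M)
    if (!is.null(cpt)) out[[length(out) + 1]] <- cpt
  }
  out
}

null_concept <- function(ss) {
  full <- seq_len(ss$n)
  list(mechanism = integer(), phi = 0,
       cause = list(phi = 0, purview = full,
                    repertoire = sub_repertoire(ss, "cause", integer(), full)),
       effect = list(phi = 0, purview = full,
                     repertoire = sub_repertoire(ss, "effect", integer(), full)),
       subsystem = ss)
}

# Expand a repertoire over `purview` to the sorted union purview `U` by
# multiplying in the unconstrained repertoire of the missing nodes
# (computed in the concept's own, possibly cut, subsystem).
expand_repertoire <- function(concept, direction, U) {
  side <- concept[[direction]]
  P <- side$purview
  extra <- setdiff(U, P)
  r_extra <- if (length(extra)) {
    sub_repertoire(concept$subsystem, direction, integer(), extra)
  } else NULL
  out <- combine_parts(U, P, side$repertoire, extra, r_extra)
  s <- sum(out)
  if (s > 0) out / s else out
}

# Distance between two concepts: cause EMD plus effect EMD, each over the
# union of the two purviews.
concept_distance <- function(c1, c2) {
  cu <- sort(union(c1$cause$purview, c2$cause$purview))
  eu <- sort(union(c1$effect$purview, c2$effect$purview))
  rep_distance("cause",
               expand_repertoire(c1, "cause", cu),
               expand_repertoire(c2, "cause", cu), length(cu)) +
  rep_distance("effect",
               expand_repertoire(c1, "effect", eu),
               expand_repertoire(c2, "effect", eu), length(eu))
}

concept_emd_eq <- function(c1, c2) {
  identical(c1$mechanism, c2$mechanism) &&
    c1$phi == c2$phi &&
    identical(c1$cause$purview, c2$cause$purview) &&
    identical(c1$effect$purview, c2$effect$purview) &&
    max(abs(c1$cause$repertoire - c2$cause$repertoire)) < 1e-9 &&
    max(abs(c1$effect$repertoire - c2$effect$repertoire)) < 1e-9
}

sum_phi <- function(ces) if (!length(ces)) 0 else sum(vapply(ces, `[[`, 0, "phi"))

# Extended EMD between two constellations. Concepts carry mass phi; a
# concept may move to a concept of the other constellation (cost = concept
# distance) or be created/destroyed against the null concept.
ces_distance <- function(C1, C2) {
  uniq1 <- Filter(function(c1) !any(vapply(C2, concept_emd_eq, TRUE, c1)), C1)
  uniq2 <- Filter(function(c2) !any(vapply(C1, concept_emd_eq, TRUE, c2)), C2)
  if (!length(uniq1) || !length(uniq2)) {
    # Only destroyed (or only created) concepts: move each straight to the
    # null concept of its own subsystem.
    big <- if (sum_phi(C2) > sum_phi(C1)) uniq2 else uniq1
    d <- sum(vapply(big, function(c)
      c$phi * concept_distance(c, null_concept(c$subsystem)), 0))
    return(round(d, PHI_PRECISION))
  }
  N <- length(uniq1); M <- length(uniq2)
  distances <- matrix(0, N, M)
  for (i in seq_len(N)) for (j in seq_len(M))
    distances[i, j] <- concept_distance(uniq1[[i]], uniq2[[j]])
  to_null <- vapply(c(uniq1, uniq2), function(c)
    concept_distance(c, null_concept(c$subsystem)), 0)
  side <- N + M + 1
  D <- matrix(max(distances) + 1, side, side)
  D[seq_len(N), N + seq_len(M)] <- distances
  D[N + seq_len(M), seq_len(N)] <- t(distances)
  D[side, -side] <- to_null
  D[-side, side] <- to_null
  D[side, side] <- 0
  d1 <- c(vapply(uniq1, `[[`, 0, "phi"), rep(0, M), 0)
  d2 <- c(rep(0, N), vapply(uniq2, `[[`, 0, "phi"), 0)
  residual <- sum(d1) - sum(d2)
  if (residual > 0) d2[side] <- residual
  if (residual < 0) d1[side] <- -residual
  round(emd_exact(d1, d2, D), PHI_PRECISION)
}

# Mechanisms straddling a cut (nodes on both sides), whose concepts a cut
# may create even if absent from the intact constellation.
cut_mechanisms <- function(n, from, to) {
  Filter(function(M) length(intersect(M, from)) > 0 &&
                     length(intersect(M, to)) > 0,
         powerset_sets(n))
}

# ---- User-facing operations ------------------------------------------------

#' Is a state reachable under the transition model?
#'
#' A current state is reachable when some previous state assigns it positive
#' probability under the per-node factorisation of the TPM (the reference
#' IIT 3.0 reachability test). Big Phi is undefined for unreachable
#' ("impossible") states.
#'
#' @param model A [transition_model()].
#' @param state Binary state (vector or string such as `"010"`).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' m <- empirical_tpm(gate_network(), steps_per_run = 8)
#' check_reachable(m, "010")  # FALSE: AND on requires OR on next step
check_reachable <- function(model, state) {
  stopifnot(inherits(model, "transition_model"))
  state <- parse_state(state)
  stopifnot(length(state) == model$n)
  bits <- all_states(model$n)
  sbn <- model$tpm %*% bits
  ok <- rep(TRUE, nrow(sbn))
  for (i in seq_len(model$n)) {
    ok <- ok & if (state[i] == 1) sbn[, i] > 0 else sbn[, i] < 1
  }
  any(ok)
}

#' Cause and effect repertoires
#'
#' The cause repertoire is the probability distribution over past purview
#' states obtained by Bayesian inversion of the TPM with uniform priors,
#' conditioning on the mechanism nodes being in their current state and
#' noising all other nodes. The effect repertoire is the forward analogue:
#' the distribution over future purview states (a product over purview
#' nodes) given the mechanism state, with non-mechanism inputs noised.
#'
#' @inheritParams check_reachable
#' @param mechanism Integer node indices of the mechanism (may be empty for
#'   the unconstrained repertoire).
#' @param purview Integer node indices of the purview.
#' @return A list with `purview`, `distribution` (over purview states in
#'   [all_states()] order) and `empty` (`TRUE` when conditioning annihilates
#'   the distribution).
#' @export
cause_repertoire <- function(model, state, mechanism, purview) {
  ss <- engine_subsystem(model, state)
  d <- sub_repertoire(ss, "cause", as.integer(mechanism),
                      sort(as.integer(purview)))
  list(purview = sort(as.integer(purview)), distribution = d,
       empty = sum(d) == 0)
}

#' @rdname cause_repertoire
#' @export
effect_repertoire <- function(model, state, mechanism, purview) {
  ss <- engine_subsystem(model, state)
  d <- sub_repertoire(ss, "effect", as.integer(mechanism),
                      sort(as.integer(purview)))
  list(purview = sort(as.integer(purview)), distribution = d,
       empty = sum(d) == 0)
}

engine_subsystem <- function(model, state) {
  stopifnot(inherits(model, "transition_model"))
  state <- parse_state(state)
  stopifnot(length(state) == model$n)
  new_subsystem(model, state)
}

#' Small phi of a mechanism
#'
#' Irreducibility of a mechanism in one direction: the maximum over purviews
#' of the minimum over mechanism/purview bipartitions of the earth-mover's
#' distance between the whole repertoire and the product of the parts.
#'
#' @inheritParams cause_repertoire
#' @param direction `"cause"` or `"effect"`.
#' @return A list with `phi`, the maximally irreducible `purview`, the
#'   minimum-information `partition` and the `repertoire` over that purview.
#' @export
small_phi <- function(model, state, mechanism,
                      direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  ss <- engine_subsystem(model, state)
  find_mice(ss, direction, sort(as.integer(mechanism)))
}

#' Big Phi of a system in a state
#'
#' Builds the full cause-effect structure of the system, then for every
#' unidirectional bipartition of the nodes severs the connections from one
#' part to the other (replacing them with noise), rebuilds the structure,
#' and takes Phi as the minimum over cuts of the extended earth-mover's
#' distance between the intact and cut constellations. States that the
#' dynamics cannot reach are flagged `"unreachable"` and carry no Phi value.
#'
#' @inheritParams check_reachable
#' @return A `big_phi_result` with fields `phi`, `status` (`"ok"` or
#'   `"unreachable"`), `cut` (`from`/`to` node sets of the minimising cut),
#'   `n_concepts` and a `concepts` tibble. `tidy()` returns the concepts,
#'   `glance()` a one-row summary.
#' @export
#' @examples
#' m <- empirical_tpm(gate_network(), steps_per_run = 8)
#' big_phi(m, "100")$phi  # 1.916665
big_phi <- function(model, state) {
  stopifnot(inherits(model, "transition_model"))
  state <- parse_state(state)
  stopifnot(length(state) == model$n)
  if (!check_reachable(model, state)) {
    return(new_big_phi_result(NA_real_, "unreachable", NULL, list(), model,
                              state))
  }
  whole <- new_subsystem(model, state)
  C <- sub_ces(whole)
  if (!length(C)) {
    return(new_big_phi_result(0, "ok", NULL, C, model, state))
  }
  n <- model$n
  parts <- powerset_sets(n)
  parts <- parts[vapply(parts, length, 1L) < n]
  best_phi <- Inf; best_cut <- NULL
  for (A in parts) {
    B <- setdiff(seq_len(n), A)
    if (sum(whole$cm[A, B]) == 0) {
      # Severing non-existent connections leaves the system untouched; the
      # constellation distance is exactly zero.
      best_phi <- 0; best_cut <- list(from = A, to = B)
      break
    }
    cut_ss <- new_subsystem(model, state, cut = list(from = A, to = B))
    mechs <- unique(c(lapply(C, `[[`, "mechanism"),
                      cut_mechanisms(n, A, B)))
    C_cut <- sub_ces(cut_ss, mechs)
    d <- ces_distance(C, C_cut)
    if (d < best_phi) {
      best_phi <- d
      best_cut <- list(from = A, to = B)
      if (best_phi == 0) break
    }
  }
  new_big_phi_result(round(best_phi, PHI_PRECISION), "ok", best_cut, C,
                     model, state)
}

new_big_phi_result <- function(phi, status, cut, ces, model, state) {
  labs <- model$labels
  concepts <- if (length(ces)) {
    tibble::tibble(
      mechanism = vapply(ces, function(c)
        paste(labs[c$mechanism], collapse = ","), ""),
      phi = vapply(ces, `[[`, 0, "phi"),
      phi_cause = vapply(ces, function(c) c$cause$phi, 0),
      phi_effect = vapply(ces, function(c) c$effect$phi, 0),
      cause_purview = vapply(ces, function(c)
        paste(labs[c$cause$purview], collapse = ","), ""),
      effect_purview = vapply(ces, function(c)
        paste(labs[c$effect$purview], collapse = ","), "")
    )
  } else {
    tibble::tibble(mechanism = character(), phi = numeric(),
                   phi_cause = numeric(), phi_effect = numeric(),
                   cause_purview = character(), effect_purview = character())
  }
  structure(
    list(phi = phi, status = status, cut = cut, concepts = concepts,
         n_concepts = nrow(concepts), state = state, labels = labs),
    class = "big_phi_result"
  )
}

#' @export
print.big_phi_result <- function(x, ...) {
  if (x$status == "unreachable") {
    cat(sprintf("<big_phi_result> state %s: unreachable (Phi undefined)\n",
                state_label(x$state)))
  } else {
    cat(sprintf("<big_phi_result> state %s: Phi = %g (%d concepts)\n",
                state_label(x$state), x$phi, x$n_concepts))
    if (!is.null(x$cut))
      cat(sprintf("  minimising cut: {%s} -/-> {%s}\n",
                  paste(x$labels[x$cut$from], collapse = ","),
                  paste(x$labels[x$cut$to], collapse = ",")))
  }
  invisible(x)
}

#' @export
tidy.big_phi_result <- function(x, ...) x$concepts

#' @export
glance.big_phi_result <- function(x, ...) {
  tibble::tibble(
    state = state_label(x$state), phi = x$phi, status = x$status,
    n_concepts = x$n_concepts,
    cut = if (is.null(x$cut)) NA_character_ else
      paste0(paste(x$labels[x$cut$from], collapse = ","), " -/-> ",
             paste(x$labels[x$cut$to], collapse = ","))
  )
}

#' Write a big-Phi result as JSON
#'
#' @param result A `big_phi_result`.
#' @param path File path.
#' @export
write_big_phi <- function(result, path) {
  stopifnot(inherits(result, "big_phi_result"))
  obj <- list(
    state = state_label(result$state), phi = result$phi,
    status = result$status,
    cut = if (!is.null(result$cut))
      list(from = result$labels[result$cut$from],
           to = result$labels[result$cut$to]),
    concepts = as.data.frame(result$concepts)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
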