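# The stochastic scission engine.
#
# State is the length histogram of the ensemble. One event: pick a length
# class with probability proportional to m(n) * k(n), pick a bond uniformly
# along the selected chain, replace the chain by its two fragments. Monomer
# mass is conserved exactly and each event adds one chain, so the final
# number-average MW is Mn0 / (achieved scissions per chain + 1) by
# bookkeeping alone, for any rate model and any seed.

round_half_up <- function(x) floor(x + 0.5)

stop_exhausted <- function(events_done, m) {
  stop(structure(
    class = c("scission_exhausted_error", "error", "condition"),
    list(message = sprintf(
      "ensemble exhausted after %d events (achieved SiC = %g): no cleavable chain left",
      events_done, events_done / m),
      call = NULL, events_done = events_done, achieved_sic = events_done / m)))
}

# eligible-rate lookup: k(n) for n = 1..nmax with ineligible lengths zeroed
eligible_rate_vector <- function(nmax, model, eligible_min_length = 2L) {
  kvec <- chain_rate_constant(seq_len(nmax), model)
  if (eligible_min_length > 1) kvec[seq_len(eligible_min_length - 1L)] <- 0
  kvec
}

# Inner event loop on the histogram state. `checkpoint_after` is a
# nondecreasing vector of cumulative event counts at which to snapshot the
# histogram. Uses the current RNG state; callers seed.
mc_event_loop <- function(counts, kvec, n_events, checkpoint_after = integer(0),
                          record_events = FALSE, m_initial = sum(counts)) {
  nmax <- length(counts)
  snaps <- vector("list", length(checkpoint_after))
  ev_mat <- if (record_events) {
    matrix(0L, nrow = n_events, ncol = 3,
           dimnames = list(NULL, c("parent_length", "cut_position", "step")))
  }
  ci <- 1L
  while (ci <= length(checkpoint_after) && checkpoint_after[ci] == 0L) {
    snaps[[ci]] <- counts
    ci <- ci + 1L
  }
  if (n_events > 0) {
    for (ev in seq_len(n_events)) {
      w <- counts * kvec
      if (sum(w) <= 0) stop_exhausted(ev - 1L, m_initial)
      n <- sample.int(nmax, 1L, prob = w)
      j <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
      counts[n] <- counts[n] - 1
      counts[j] <- counts[j] + 1
      counts[n - j] <- counts[n - j] + 1
      if (record_events) ev_mat[ev, ] <- c(n, j, ev)
      while (ci <= length(checkpoint_after) && checkpoint_after[ci] == ev) {
        snaps[[ci]] <- counts
        ci <- ci + 1L
      }
    }
  }
  list(counts = counts, snapshots = snaps, events = ev_mat)
}

#' Perform a single scission step on an ensemble
#'
#' Selects one chain with probability proportional to its length-specific
#' rate constant, cleaves it at a bond chosen uniformly among its `n - 1`
#' inter-monomer bonds, and returns the updated ensemble together with the
#' event record. Uses the current RNG state; call `set.seed()` beforehand
#' for reproducibility.
#'
#' @param ensemble A `chain_ensemble` with at least one cleavable chain.
#' @param model A [rate_model()].
#' @param eligible_min_length Minimum cleavable length (default 2).
#' @return A list with elements `ensemble` (updated) and `event` (a list
#'   with `parent_length`, `cut_position` and `child_lengths`).
#' @examples
#' set.seed(1)
#' simulate_scission_step(chain_ensemble(10, 1))$event
#' @export
simulate_scission_step <- function(ensemble, model = rate_model(),
                                   eligible_min_length = 2L) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  w <- selection_weights(ensemble, model, eligible_min_length)  # errors if exhausted
  n <- sample.int(length(w), 1L, prob = w)
  j <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
  counts <- ensemble$counts
  counts[n] <- counts[n] - 1
  counts[j] <- counts[j] + 1
  counts[n - j] <- counts[n - j] + 1
  list(
    ensemble = new_chain_ensemble(counts, ensemble$mw_monomer),
    event = list(parent_length = n, cut_position = j,
                 child_lengths = c(j, n - j))
  )
}

# Individual-chain engine with genealogy. Distributionally identical to the
# histogram engine (same selection law); used for small ensembles where the
# reaction network itself is of interest.
mc_genealogy_run <- function(counts, mw_monomer, model, n_events,
                             eligible_min_length = 2L) {
  lengths <- rep(seq_along(counts), times = counts)
  m <- length(lengths)
  cap <- m + 2L * n_events
  len <- integer(cap); len[seq_len(m)] <- lengths
  gen <- integer(cap)
  parent <- rep(NA_integer_, cap)
  reacted <- logical(cap)
  alive <- logical(cap); alive[seq_len(m)] <- TRUE
  n_tot <- m
  ev <- data.frame(step_index = integer(n_events), parent_id = integer(n_events),
                   parent_length = integer(n_events), cut_position = integer(n_events),
                   child1_id = integer(n_events), child2_id = integer(n_events),
                   child1_length = integer(n_events), child2_length = integer(n_events))
  for (s in seq_len(n_events)) {
    idx <- which(alive[seq_len(n_tot)] & len[seq_len(n_tot)] >= eligible_min_length)
    if (length(idx) == 0L) stop_exhausted(s - 1L, m)
    w <- chain_rate_constant(len[idx], model)
    i <- idx[sample.int(length(idx), 1L, prob = w)]
    n <- len[i]
    j <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
    reacted[i] <- TRUE
    alive[i] <- FALSE
    c1 <- n_tot + 1L; c2 <- n_tot + 2L; n_tot <- c2
    len[c1] <- j; len[c2] <- n - j
    gen[c1] <- gen[i] + 1L; gen[c2] <- gen[i] + 1L
    parent[c1] <- i; parent[c2] <- i
    alive[c1] <- TRUE; alive[c2] <- TRUE
    ev[s, ] <- list(s, i, n, j, c1, c2, j, n - j)
  }
  genealogy <- data.frame(
    id = seq_len(n_tot),
    length = len[seq_len(n_tot)],
    generation = gen[seq_len(n_tot)],
    parent_id = parent[seq_len(n_tot)],
    reacted = reacted[seq_len(n_tot)]
  )
  final_counts <- tabulate(len[which(alive)], nbins = max(len[seq_len(n_tot)]))
  list(counts = final_counts, events = ev, genealogy = genealogy)
}

#' Run a stochastic multi-step scission simulation
#'
#' Builds the initial ensemble from `spec`, then executes exactly
#' `round(sic_target * m)` scission events (round half up), each selecting a
#' chain by the length-dependent rate law and cleaving it at a uniformly
#' chosen bond. The run is deterministic given `(spec, model, sic_target,
#' seed)`.
#'
#' With `track_genealogy = TRUE` (and `m` at most `genealogy_threshold`)
#' every chain is tracked individually with its parent and generation —
#' generation counts the number of consecutive scissions needed to form the
#' chain, initial chains being generation 0 — enabling [classify_chains()]
#' and [export_network()]. Without genealogy the engine works on the length
#' histogram, which is distributionally identical and scales to thousands of
#' chains and tens of thousands of events.
#'
#' @param spec An [ensemble_spec()].
#' @param model A [rate_model()].
#' @param sic_target Requested average scissions per initial chain (> 0, and
#'   `round(sic_target * m) >= 1`).
#' @param seed Integer seed.
#' @param track_genealogy Track individual chain identities?
#' @param genealogy_threshold Maximum `m` for which genealogy tracking is
#'   honored (memory guard, default 1000).
#' @return An object of class `scission_sim` with elements `initial` and
#'   `final` (chain ensembles), `events` (one row per scission),
#'   `genealogy` (data frame or `NULL`), `achieved_sic`, `sic_target`,
#'   `seed`, `spec`, `model`. If the ensemble runs out of cleavable chains
#'   before the event budget, an error of class `scission_exhausted_error`
#'   carrying the achieved extent is raised.
#' @examples
#' sim <- run_simulation(ensemble_spec(20, 145, 9.09), sic_target = 1,
#'                       seed = 7, track_genealogy = TRUE)
#' sim
#' @export
run_simulation <- function(spec, model = rate_model(), sic_target, seed = 1L,
                           track_genealogy = FALSE, genealogy_threshold = 1000L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  stopifnot(inherits(model, "rate_model"))
  check_positive(sic_target, "sic_target")
  n_events <- as.integer(round_half_up(sic_target * spec$m))
  if (n_events < 1L) {
    stop_domain("sic_target %g on m = %d chains rounds to zero events",
                sic_target, spec$m)
  }
  set.seed(seed)
  initial <- build_initial_ensemble(spec, seed = seed)
  use_genealogy <- track_genealogy && spec$m <= genealogy_threshold
  if (track_genealogy && !use_genealogy) {
    warning(sprintf(
      "genealogy tracking skipped: m = %d exceeds threshold %d",
      spec$m, genealogy_threshold))
  }
  if (use_genealogy) {
    res <- mc_genealogy_run(initial$counts, spec$mw_monomer, model, n_events)
    events <- res$events
    genealogy <- res$genealogy
  } else {
    kvec <- eligible_rate_vector(length(initial$counts), model)
    res <- mc_event_loop(initial$counts, kvec, n_events, record_events = TRUE,
                         m_initial = spec$m)
    events <- as.data.frame(res$events)
    events$child1_length <- events$cut_position
    events$child2_length <- events$parent_length - events$cut_position
    events <- events[, c("step", "parent_length", "cut_position",
                         "child1_length", "child2_length")]
    names(events)[1] <- "step_index"
    genealogy <- NULL
  }
  structure(list(
    initial = initial,
    final = new_chain_ensemble(res$counts, spec$mw_monomer),
    events = events,
    genealogy = genealogy,
    achieved_sic = n_events / spec$m,
    sic_target = sic_target,
    n_events = n_events,
    seed = seed,
    spec = spec,
    model = model
  ), class = "scission_sim")
}

#' @export
print.scission_sim <- function(x, ...) {
  cat(sprintf(
    "Scission simulation: m = %d chains, %d events (SiC = %g, requested %g), seed %d\n",
    x$spec$m, x$n_events, x$achieved_sic, x$sic_target, x$seed))
  cat(sprintf("  Mn: %.4g -> %.4g Da; final chains: %g%s\n",
              number_average_mw(x$initial), number_average_mw(x$final),
              sum(x$final$counts),
              if (is.null(x$genealogy)) "" else "; genealogy tracked"))
  invisible(x)
}

#' Classify chains of a tracked simulation as intermediate or final
#'
#' A chain that reacted (was cleaved) during the run is an *intermediate*;
#' a chain that never reacted is part of the *final* pool, split into
#' initial survivors (`"Initial-Final"`, generation 0) and daughter products
#' (`"Daughter-Final"`). The bookkeeping identities — one intermediate per
#' event, final-pool size `m + events` — are verified and an error of class
#' `scission_integrity_error` is raised if the genealogy violates them.
#'
#' @param sim A `scission_sim` run with `track_genealogy = TRUE`, or its
#'   `genealogy` data frame.
#' @return The genealogy data frame with an added `label` factor.
#' @examples
#' sim <- run_simulation(ensemble_spec(20, 145, 9.09), sic_target = 1,
#'                       seed = 7, track_genealogy = TRUE)
#' table(classify_chains(sim)$label)
#' @export
classify_chains <- function(sim) {
  g <- if (inherits(sim, "scission_sim")) sim$genealogy else sim
  if (is.null(g)) stop_domain("simulation was run without genealogy tracking")
  lab <- ifelse(g$reacted, "Intermediate",
                ifelse(g$generation == 0L, "Initial-Final", "Daughter-Final"))
  m <- sum(g$generation == 0L)
  n_events <- sum(g$reacted)
  ok <- nrow(g) == m + 2L * n_events &&
    sum(!g$reacted) == m + n_events &&
    all(g$length >= 1L) &&
    all(is.na(g$parent_id[g$generation == 0L])) &&
    all(!is.na(g$parent_id[g$generation > 0L]))
  if (!ok) {
    stop(structure(
      class = c("scission_integrity_error", "error", "condition"),
      list(message = "inconsistent genealogy: bookkeeping identities violated",
           call = NULL)))
  }
  g$label <- factor(lab, levels = c("Initial-Final", "Intermediate",
                                    "Daughter-Final"))
  g
}

#' Export the scission reaction network as an edge list
#'
#' One directed edge per parent-to-child relation: each scission contributes
#' two edges, so a run with `E` events yields `2 E` edges over `m + 2 E`
#' nodes.
#'
#' @param sim A `scission_sim` run with genealogy tracking (or its genealogy
#'   data frame).
#' @return A data frame with columns `parent_id`, `child_id`,
#'   `child_length`, `child_generation`, `final_flag`.
#' @export
export_network <- function(sim) {
  g <- if (inherits(sim, "scission_sim")) sim$genealogy else sim
  if (is.null(g)) stop_domain("simulation was run without genealogy tracking")
  kids <- g[!is.na(g$parent_id), , drop = FALSE]
  data.frame(
    parent_id = kids$parent_id,
    child_id = kids$id,
    child_length = kids$length,
    child_generation = kids$generation,
    final_flag = !kids$reacted
  )
}
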