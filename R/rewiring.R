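#' Synapse formation rule
#'
#' Declares which element types can bind into a synapse of a given type, for
#' which populations, and with what weight.
#'
#' @param syn_type synapse model label (e.g. `"ex"`, `"in"`).
#' @param pre_element axonal element type consumed on the source neuron.
#' @param post_element dendritic element type consumed on the target neuron.
#' @param pre_populations,post_populations character vectors of population names.
#' @param weight PSC amplitude of formed synapses, pA.
#' @return object of class `synapse_rule`.
#' @export
synapse_rule <- function(syn_type, pre_element, post_element,
                         pre_populations, post_populations, weight) {
  structure(list(syn_type = syn_type, pre_element = pre_element,
                 post_element = post_element,
                 pre_populations = pre_populations,
                 post_populations = post_populations,
                 weight = weight),
            class = "synapse_rule")
}

pool_key <- function(neuron, element_type) paste0(neuron, "\r", element_type)

#' Register structural plasticity on a network state
#'
#' Attaches synaptic-element pools (one per neuron and element type, starting
#' at `z = 0` unless seeded), growth curves, synapse-formation rules and the
#' structural update configuration to a state.
#'
#' @param state a `sim_state`.
#' @param elements data.frame with columns `population`, `element_type`,
#'   `eta`, `eps`, `nu` — one growth curve per (population, element type).
#' @param rules list of [synapse_rule()].
#' @param update_interval structural update interval, ms.
#' @param allow_autapses,allow_multapses policy flags.
#' @param param_bounds optional named list of `c(lower, upper)` bounds for
#'   steerable parameters (`nu`, `eta`, `update_interval`).
#' @return the state with plasticity configured.
#' @export
register_plasticity <- function(state, elements, rules,
                                update_interval = 100,
                                allow_autapses = FALSE,
                                allow_multapses = TRUE,
                                param_bounds = NULL) {
  stopifnot(inherits(state, "sim_state"), update_interval > 0)
  pools <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    if (!(e$eps > e$eta)) stop("invalid growth curve for ", e$population, "/",
                               e$element_type, ": eps must exceed eta")
    ids <- population_ids(state, e$population)
    data.frame(neuron = ids, element_type = e$element_type,
               z = 0, bound = 0L, eta = e$eta, eps = e$eps, nu = e$nu,
               stringsAsFactors = FALSE)
  }))
  for (r in rules) {
    for (p in r$pre_populations) {
      if (!any(pools$element_type == r$pre_element &
               pools$neuron %in% population_ids(state, p)))
        stop("rule ", r$syn_type, ": pre element ", r$pre_element,
             " not registered on population ", p)
    }
    for (p in r$post_populations) {
      if (!any(pools$element_type == r$post_element &
               pools$neuron %in% population_ids(state, p)))
        stop("rule ", r$syn_type, ": post element ", r$post_element,
             " not registered on population ", p)
    }
  }
  state$pools <- pools
  state$rules <- rules
  state$conn <- canonical_conn(state$conn)
  state$struct$update_interval <- update_interval
  state$struct$allow_autapses <- allow_autapses
  state$struct$allow_multapses <- allow_multapses
  state$struct$param_bounds <- param_bounds
  state
}

# sample() without the length-1 surprise
resample <- function(x, size = length(x)) {
  if (length(x) == 1L) {
    if (size >= 1L) rep(x, min(size, 1L)) else x[0]
  } else {
    sample(x, size)
  }
}

#' Form synapses from free elements
#'
#' Pairs individual free axonal (pre) and dendritic (post) elements uniformly
#' at random: exactly `min(sum(free_pre), sum(free_post))` pairings are drawn
#' (element slots sampled without replacement on each side, then matched).
#' Pairs that would violate the autapse or multapse policy are dropped and
#' their elements remain free.
#'
#' @param free_pre,free_post named integer vectors: free element counts per
#'   neuron id (names are the ids).
#' @param rule a [synapse_rule()] supplying type and weight.
#' @param allow_autapses,allow_multapses policy flags.
#' @param existing optional connection table consulted for the multapse policy.
#' @return a [connection_table()] of new rows.
#' @export
form_synapses <- function(free_pre, free_post, rule,
                          allow_autapses = FALSE, allow_multapses = TRUE,
                          existing = NULL) {
  stopifnot(all(free_pre >= 0), all(free_post >= 0))
  n_new <- min(sum(free_pre), sum(free_post))
  if (n_new == 0) return(connection_table())
  pre_slots <- rep(as.integer(names(free_pre)), free_pre)
  post_slots <- rep(as.integer(names(free_post)), free_post)
  src <- resample(pre_slots)[seq_len(n_new)]
  tgt <- resample(post_slots)[seq_len(n_new)]
  keep <- rep(TRUE, n_new)
  if (!allow_autapses) keep <- keep & (src != tgt)
  if (!allow_multapses) {
    key <- paste0(src, "\r", tgt)
    keep <- keep & !duplicated(key)
    if (!is.null(existing) && nrow(existing)) {
      ex <- existing[existing$syn_type == rule$syn_type, ]
      keep <- keep & !(key %in% paste0(ex$source, "\r", ex$target))
    }
  }
  k <- sum(keep)
  if (!k) return(connection_table())
  connection_table(source = src[keep], target = tgt[keep],
                   syn_type = rep(rule$syn_type, k),
                   weight = rep(rule$weight, k), plastic = rep(TRUE, k))
}

# rules that consume a given element type, split by side
rules_using <- function(rules, element_type, side) {
  Filter(function(r) {
    if (side == "pre") r$pre_element == element_type
    else r$post_element == element_type
  }, rules)
}

#' Delete synapses to resolve element deficits
#'
#' For every pool whose integer element count `floor(z)` has dropped below its
#' `bound` count, removes `bound - floor(z)` synapses that use this pool,
#' chosen uniformly at random; the counterpart element on the partner neuron
#' becomes free again (its `bound` is decremented, its `z` untouched). Pools
#' are processed in canonical (neuron, element type) order, recomputing each
#' deficit after earlier deletions.
#'
#' @param state a `sim_state` with plasticity registered.
#' @return list with `state` (pools and table updated) and `removed`
#'   (the removed connection rows).
#' @export
delete_synapses <- function(state) {
  pools <- state$pools
  conn <- state$conn
  removed_idx <- integer()
  ord <- order(pools$neuron, pools$element_type)
  keyv <- pool_key(pools$neuron, pools$element_type)
  alive <- rep(TRUE, nrow(conn))
  for (i in ord) {
    deficit <- pools$bound[i] - floor(pools$z[i])
    if (deficit <= 0) next
    # candidate rows: plastic rows using this pool on either side
    cand <- integer()
    for (r in rules_using(state$rules, pools$element_type[i], "pre")) {
      cand <- c(cand, which(alive & conn$plastic &
                            conn$syn_type == r$syn_type &
                            conn$source == pools$neuron[i]))
    }
    for (r in rules_using(state$rules, pools$element_type[i], "post")) {
      cand <- c(cand, which(alive & conn$plastic &
                            conn$syn_type == r$syn_type &
                            conn$target == pools$neuron[i]))
    }
    cand <- unique(cand)
    if (deficit > length(cand)) {
      stop("internal inconsistency: pool (neuron ", pools$neuron[i], ", ",
           pools$element_type[i], ") has deficit ", deficit,
           " but only ", length(cand), " synapses")
    }
    drop <- resample(cand, deficit)
    alive[drop] <- FALSE
    removed_idx <- c(removed_idx, drop)
    # decrement bounds on both endpoints of each removed row
    for (j in drop) {
      r <- rule_for(state$rules, conn$syn_type[j])
      kpre <- match(pool_key(conn$source[j], r$pre_element), keyv)
      kpost <- match(pool_key(conn$target[j], r$post_element), keyv)
      pools$bound[kpre] <- pools$bound[kpre] - 1L
      pools$bound[kpost] <- pools$bound[kpost] - 1L
    }
  }
  state$pools <- pools
  removed <- conn[removed_idx, , drop = FALSE]
  state$conn <- as_connection_table(conn[alive, , drop = FALSE])
  rownames(state$conn) <- NULL
  list(state = state, removed = removed)
}

rule_for <- function(rules, syn_type) {
  for (r in rules) if (r$syn_type == syn_type) return(r)
  stop("no rule for synapse type ", syn_type)
}

free_counts <- function(pools, ids, element_type) {
  sel <- pools$neuron %in% ids & pools$element_type == element_type
  f <- pmax(0L, as.integer(floor(pools$z[sel])) - pools$bound[sel])
  stats::setNames(f, pools$neuron[sel])
}

#' Perform one structural update
#'
#' Integrates every element pool with the neuron's current filtered rate
#' (piecewise-constant over the elapsed interval), then deletes synapses for
#' pools in deficit, then forms new synapses from the free elements
#' (delete-then-form, so freed counterpart elements can immediately re-pair).
#'
#' @param state a `sim_state` with plasticity registered.
#' @param elapsed time since the previous structural update, ms; defaults to
#'   the configured update interval.
#' @return the updated state; per-update created/deleted counts are appended
#'   to `state$rewiring_log`.
#' @export
structural_update <- function(state, elapsed = NULL) {
  stopifnot(inherits(state, "sim_state"))
  if (is.null(elapsed)) elapsed <- state$struct$update_interval
  pools <- state$pools
  if (nrow(pools)) {
    lam <- state$lambda[pools$neuron]
    pools$z <- pmax(0, pools$z +
                      growth_rate_num(lam, pools$eta, pools$eps, pools$nu) *
                      elapsed)
    state$pools <- pools
  }
  del <- delete_synapses(state)
  state <- del$state
  n_deleted <- nrow(del$removed)
  n_created <- 0L
  for (r in state$rules) {
    pre_ids <- unlist(lapply(r$pre_populations,
                             function(p) population_ids(state, p)))
    post_ids <- unlist(lapply(r$post_populations,
                              function(p) population_ids(state, p)))
    fp <- free_counts(state$pools, pre_ids, r$pre_element)
    fq <- free_counts(state$pools, post_ids, r$post_element)
    new_rows <- form_synapses(fp, fq, r,
                              allow_autapses = state$struct$allow_autapses,
                              allow_multapses = state$struct$allow_multapses,
                              existing = state$conn)
    if (nrow(new_rows)) {
      keyv <- pool_key(state$pools$neuron, state$pools$element_type)
      inc_pre <- table(new_rows$source)
      inc_post <- table(new_rows$target)
      ip <- match(pool_key(as.integer(names(inc_pre)), r$pre_element), keyv)
      iq <- match(pool_key(as.integer(names(inc_post)), r$post_element), keyv)
      state$pools$bound[ip] <- state$pools$bound[ip] + as.integer(inc_pre)
      state$pools$bound[iq] <- state$pools$bound[iq] + as.integer(inc_post)
      state$conn <- as_connection_table(rbind(state$conn, new_rows))
      rownames(state$conn) <- NULL
      n_created <- n_created + nrow(new_rows)
    }
  }
  # canonical row order keeps deletion sampling independent of formation
  # history, so a reloaded snapshot continues identically to the live run
  state$conn <- canonical_conn(state$conn)
  state$iteration <- state$iteration + 1L
  state$rewiring_log <- rbind(state$rewiring_log,
                              data.frame(iteration = state$iteration,
                                         created = n_created,
                                         deleted = n_deleted))
  state
}

#' Check element/synapse bookkeeping invariants
#'
#' For every synapse type: the number of plastic rows equals the summed bound
#' counts of its pre-side pools and of its post-side pools; no free count is
#' negative.
#'
#' @param state a `sim_state`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_state <- function(state) {
  pools <- state$pools
  if (nrow(pools) && any(floor(pools$z) - pools$bound < 0)) {
    stop("negative free element count (floor(z) < bound)")
  }
  for (r in state$rules) {
    rows <- sum(state$conn$plastic & state$conn$syn_type == r$syn_type)
    pre_ids <- unlist(lapply(r$pre_populations,
                             function(p) population_ids(state, p)))
    post_ids <- unlist(lapply(r$post_populations,
                              function(p) population_ids(state, p)))
    pre_bound <- sum(pools$bound[pools$neuron %in% pre_ids &
                                 pools$element_type == r$pre_element])
    post_bound <- sum(pools$bound[pools$neuron %in% post_ids &
                                  pools$element_type == r$post_element])
    if (rows != pre_bound || rows != post_bound) {
      stop("conservation violated for synapse type ", r$syn_type, ": rows=",
           rows, " pre_bound=", pre_bound, " post_bound=", post_bound)
    }
  }
  if (any(pools$bound < 0)) stop("negative bound count")
  invisible(TRUE)
}
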