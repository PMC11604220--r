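state_key <- function(state) {
  paste(c(if (is.null(state$uas_occupied)) -1L else as.integer(state$uas_occupied),
          match(state$promoter_state, c("EMPTY", "PRE", "POST")) - 1L,
          as.integer(state$transcript_occupancy),
          as.integer(state$terminator_occupied)), collapse = "")
}

#' Exact stationary occupancy of the transcription-cycle Markov chain
#'
#' Enumerates the state space reachable from the empty gene (breadth-first,
#' using [list_transitions()] and [apply_event()]), builds the generator
#' matrix, and solves the stationary linear system exactly.  Compartment
#' occupancy is the summed stationary probability of the states in which
#' that compartment is occupied.  This is the verification oracle for the
#' stochastic engine: population means must converge to these values as the
#' number of simulated genes grows.
#'
#' @param rates a [rate_set()].
#' @param arch a [gene_architecture()]; the full state space has
#'   `3 * 2^(bins + 1 + has_uas)` states and must fit under `max_states`.
#' @param max_states refuse architectures whose state space exceeds this cap.
#' @return An object of class `ctmc_occupancy`: a named numeric vector of
#'   per-compartment occupancies with attributes `probs` (stationary
#'   distribution over reachable states) and `states` (state table:
#'   `uas`, `promoter` 0/1/2 for empty/pre/post-TFIIH, `bin_*`, `terminator`).
#' @examples
#' r <- rate_set(gene_class = "TFO", k3 = 0.002, k_rev3 = 0.002)
#' arch <- gene_architecture(n_transcript_bins = 1)
#' ctmc_stationary_occupancy(r, arch)["promoter"]  # k3 / (k3 + k_rev3) = 0.5
#' @export
ctmc_stationary_occupancy <- function(rates, arch, max_states = 1e5) {
  check_consistent(rates$gene_class, arch, rates)
  n_full <- 3 * 2^(arch$n_transcript_bins + 1 + arch$has_uas)
  if (n_full > max_states)
    stop("state space has ", n_full, " states, exceeding the cap of ",
         max_states, "; raise max_states to at least ", n_full)

  init <- transcription_state(arch, rates$gene_class)
  index <- new.env(parent = emptyenv())
  states <- list(init)
  assign(state_key(init), 1L, envir = index)
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  head <- 1L
  while (head <= length(states)) {
    s <- states[[head]]
    tr <- list_transitions(s, rates, arch)
    keep <- tr$propensity > 0
    for (i in which(keep)) {
      s2 <- apply_event(s, tr$event[i], rates$gene_class)
      k2 <- state_key(s2)
      j <- index[[k2]]
      if (is.null(j)) {
        states[[length(states) + 1L]] <- s2
        j <- length(states)
        assign(k2, j, envir = index)
      }
      from <- c(from, head); to <- c(to, j); rate <- c(rate, tr$propensity[i])
    }
    head <- head + 1L
  }
  n <- length(states)

  # single-closed-class check: terminal strongly connected components
  if (length(from)) {
    comp <- strong_components(n, from, to)
    leaves <- unique(comp$membership[from][comp$membership[from] !=
                                             comp$membership[to]])
    closed <- setdiff(unique(comp$membership), leaves)
    if (length(closed) > 1)
      stop("reducible chain: ", length(closed),
           " closed communicating classes; stationary distribution not unique")
  } else if (n > 1) {
    stop("reducible chain: no transitions")
  }

  pi_hat <- if (n == 1) 1 else {
    diag_rate <- tapply(rate, from, sum)
    Q <- Matrix::sparseMatrix(
      i = c(from, as.integer(names(diag_rate))),
      j = c(to, as.integer(names(diag_rate))),
      x = c(rate, -as.numeric(diag_rate)), dims = c(n, n))
    A <- Matrix::t(Q)
    A[n, ] <- 1
    b <- c(rep(0, n - 1), 1)
    as.numeric(Matrix::solve(A, b))
  }
  if (any(pi_hat < -1e-8) || abs(sum(pi_hat) - 1) > 1e-10)
    stop("stationary solve failed (negative mass or normalization error)")
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)

  st <- do.call(rbind, lapply(states, function(s)
    c(uas = if (is.null(s$uas_occupied)) NA_integer_
            else as.integer(s$uas_occupied),
      promoter = match(s$promoter_state, c("EMPTY", "PRE", "POST")) - 1L,
      setNames(as.integer(s$transcript_occupancy),
               paste0("bin_", seq_along(s$transcript_occupancy))),
      terminator = as.integer(s$terminator_occupied))))
  occ <- numeric(0)
  if (arch$has_uas) occ <- c(UAS = sum(pi_hat[st[, "uas"] == 1]))
  occ <- c(occ,
           promoter = sum(pi_hat[st[, "promoter"] != 0]),
           setNames(vapply(seq_len(arch$n_transcript_bins), function(i)
             sum(pi_hat[st[, paste0("bin_", i)] == 1]), numeric(1)),
             paste0("bin_", seq_len(arch$n_transcript_bins))),
           terminator = sum(pi_hat[st[, "terminator"] == 1]))
  structure(occ, probs = pi_hat, states = st, class = "ctmc_occupancy")
}

#' @export
print.ctmc_occupancy <- function(x, ...) {
  cat("<ctmc_occupancy> exact stationary occupancy (",
      length(attr(x, "probs")), "reachable states )\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Stationary initiation and termination fluxes
#'
#' At stationarity the initiation flux `k5 * P(post-TFIIH promoter, bin 1
#' empty)` equals the termination flux `k7 * P(terminator occupied)`.
#'
#' @param oracle result of [ctmc_stationary_occupancy()].
#' @param rates the [rate_set()] used to build it.
#' @return Named vector with `initiation` and `termination` fluxes (/s).
#' @export
stationary_fluxes <- function(oracle, rates) {
  st <- attr(oracle, "states")
  p <- attr(oracle, "probs")
  c(initiation = rates$k5 * sum(p[st[, "promoter"] == 2 & st[, "bin_1"] == 0]),
    termination = rates$k7 * sum(p[st[, "terminator"] == 1]))
}

# Iterative Tarjan strongly-connected components on an edge list.
strong_components <- function(n, from, to) {
  adj <- split(to, factor(from, levels = seq_len(n)))
  index <- rep(NA_integer_, n); low <- integer(n)
  onstack <- logical(n); stack <- integer(0)
  comp <- integer(n); ncomp <- 0L; counter <- 0L
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    # explicit DFS stack: (node, next child pointer)
    dfs <- list(c(root, 0L))
    while (length(dfs)) {
      fr <- dfs[[length(dfs)]]
      v <- fr[1]; ci <- fr[2]
      if (ci == 0L) {
        counter <- counter + 1L
        index[v] <- low[v] <- counter
        stack <- c(stack, v); onstack[v] <- TRUE
      }
      children <- adj[[v]]
      advanced <- FALSE
      while (ci < length(children)) {
        ci <- ci + 1L
        w <- children[ci]
        if (is.na(index[w])) {
          dfs[[length(dfs)]] <- c(v, ci)
          dfs[[length(dfs) + 1L]] <- c(w, 0L)
          advanced <- TRUE
          break
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      }
      if (advanced) next
      # finished v
      if (low[v] == index[v]) {
        ncomp <- ncomp + 1L
        repeat {
          w <- stack[length(stack)]
          stack <- stack[-length(stack)]
          onstack[w] <- FALSE
          comp[w] <- ncomp
          if (w == v) break
        }
      }
      dfs[[length(dfs)]] <- NULL
      if (length(dfs)) {
        u <- dfs[[length(dfs)]][1]
        low[u] <- min(low[u], low[v])
      }
    }
  }
  list(membership = comp, n = ncomp)
}
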