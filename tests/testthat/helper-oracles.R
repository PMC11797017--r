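# exhaustive parsimony oracle: minimum changes over every assignment of
# states to internal nodes (trees small enough to enumerate)
exhaustive_parsimony <- function(tree, tip_states, alphabet) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  states <- tip_states[tree$tip.label]
  grid <- expand.grid(rep(list(alphabet), nn), stringsAsFactors = FALSE)
  best <- Inf; best_roots <- character()
  for (i in seq_len(nrow(grid))) {
    assign <- c(states, stats::setNames(unlist(grid[i, ]),
                                        as.character(nt + seq_len(nn))))
    changes <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    if (changes < best) {
      best <- changes
      best_roots <- unname(assign[nt + 1])
    } else if (changes == best) {
      best_roots <- union(best_roots, unname(assign[nt + 1]))
    }
  }
  list(score = best, root_states = sort(best_roots))
}

# brute-force likelihood oracle: sum over all internal-state assignments
exhaustive_ml_posterior <- function(tree, tip_states, rate, alphabet) {
  k <- length(alphabet)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  states <- tip_states[tree$tip.label]
  ptrans <- function(from, to, t) {
    stay <- 1 / k + (1 - 1 / k) * exp(-k * rate * t / (k - 1))
    if (from == to) stay else (1 - stay) / (k - 1)
  }
  grid <- expand.grid(rep(list(alphabet), nn), stringsAsFactors = FALSE)
  lik <- stats::setNames(rep(0, k), alphabet)
  for (i in seq_len(nrow(grid))) {
    assign <- c(states, stats::setNames(unlist(grid[i, ]),
                                        as.character(nt + seq_len(nn))))
    l <- 1 / k  # uniform root prior
    for (e in seq_len(nrow(tree$edge)))
      l <- l * ptrans(assign[tree$edge[e, 1]], assign[tree$edge[e, 2]],
                      tree$edge.length[e])
    root_state <- assign[nt + 1]
    lik[root_state] <- lik[root_state] + l
  }
  lik / sum(lik)
}
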