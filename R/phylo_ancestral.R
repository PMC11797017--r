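#' Fitch parsimony ancestral reconstruction of a single character
#'
#' Bottom-up Fitch pass on a rooted tree: each internal node's state set
#' is the intersection of its children's sets when non-empty, otherwise
#' their union, adding one change per union. Missing tip states (NA)
#' contribute the full observed alphabet. Polytomies are resolved
#' arbitrarily into a binary tree with zero-length branches before the
#' pass (deterministic under fixed input order).
#'
#' @param tree A rooted `phylo` tree.
#' @param tip_states Named character vector over `tree$tip.label`; NA =
#'   missing.
#' @param alphabet Optional state alphabet; defaults to the observed
#'   states.
#' @return list: `root_states` (character vector of most-parsimonious root
#'   states), `score` (minimal number of changes).
#' @export
fitch_ancestral <- function(tree, tip_states, alphabet = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) stop("unlabeled tip(s): ", paste(miss, collapse = ", "))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  states <- tip_states[tree$tip.label]
  if (is.null(alphabet)) alphabet <- sort(unique(states[!is.na(states)]))
  nt <- length(tree$tip.label)
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt))
    sets[[i]] <- if (is.na(states[i])) alphabet else states[i]
  score <- 0L
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (node in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == node, 2]
    cur <- sets[[kids[1]]]
    for (k in kids[-1]) {
      inter <- intersect(cur, sets[[k]])
      if (length(inter)) cur <- inter
      else { cur <- union(cur, sets[[k]]); score <- score + 1L }
    }
    sets[[node]] <- cur
  }
  root <- nt + 1L
  list(root_states = sets[[root]], score = score)
}

#' Maximum-likelihood ancestral root posterior for a single character
#'
#' Felsenstein pruning on a rooted tree under the symmetric k-state Markov
#' model: along a branch of length t the probability of staying in a state
#' is 1/k + (1 - 1/k) exp(-k mu t / (k - 1)) and of moving to any given
#' other state (1 - stay)/(k - 1). The root prior is uniform; missing tip
#' states carry partial likelihood 1 for every state. Returns the
#' normalized marginal posterior over root states.
#'
#' @param tree Rooted `phylo` tree with branch lengths >= 0.
#' @param tip_states Named character vector; NA = missing.
#' @param rate Substitution rate mu (>= 0).
#' @param alphabet Optional alphabet; defaults to observed states.
#' @return Named numeric vector over the alphabet summing to 1.
#' @export
ml_ancestral <- function(tree, tip_states, rate, alphabet = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  states <- tip_states[tree$tip.label]
  if (is.null(alphabet)) alphabet <- sort(unique(states[!is.na(states)]))
  k <- length(alphabet)
  if (k < 2) {  # degenerate: single observed state
    return(stats::setNames(rep(1, 1), alphabet))
  }
  nt <- length(tree$tip.label)
  L <- matrix(1, nt + tree$Nnode, k, dimnames = list(NULL, alphabet))
  for (i in seq_len(nt)) {
    if (!is.na(states[i])) {
      L[i, ] <- 0
      L[i, states[i]] <- 1
    }
  }
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- tree$edge.length[match(paste(edge[, 1], edge[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  pmat <- function(t) {
    stay <- 1 / k + (1 - 1 / k) * exp(-k * rate * t / (k - 1))
    move <- (1 - stay) / (k - 1)
    m <- matrix(move, k, k)
    diag(m) <- stay
    m
  }
  done <- rep(FALSE, nt + tree$Nnode)
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1]; child <- edge[i, 2]
    P <- pmat(elen[i])
    contrib <- as.vector(P %*% L[child, ])
    if (!done[par]) { L[par, ] <- contrib; done[par] <- TRUE }
    else L[par, ] <- L[par, ] * contrib
  }
  root <- nt + 1L
  post <- L[root, ] / k               # uniform prior
  post / sum(post)
}

#' Tally the character states over the tree's tips
#' @param tip_states Named character vector (NA = missing, excluded).
#' @return Named integer vector of counts per state.
#' @export
tip_state_tally <- function(tip_states) {
  tab <- table(tip_states[!is.na(tip_states)])
  stats::setNames(as.integer(tab), names(tab))
}
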