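#' Transition probabilities of the symmetric two-state Markov model
#'
#' Single-rate symmetric continuous-time Markov chain on
#' {absent, present}: the probability of remaining in a state over time
#' `t` is `0.5 + 0.5 * exp(-2 * rate * t)`.
#'
#' @param rate transitions per Myr (> 0 for a proper model; 0 allowed and
#'   gives the identity).
#' @param t elapsed time, Myr (>= 0).
#' @return 2 x 2 stochastic matrix; rows/cols ordered (absent, present).
#' @export
transition_prob <- function(rate, t) {
  check_number(rate, "rate"); check_number(t, "t")
  if (t < 0) stop_invalid("`t` must be >= 0")
  if (rate < 0) stop_invalid("`rate` must be >= 0")
  stay <- 0.5 + 0.5 * exp(-2 * rate * t)
  matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

## tip state -> partial likelihood row (absent, present); '?' is ambiguous
tip_partial <- function(state) {
  switch(as.character(state),
         "0" = c(1, 0),
         "1" = c(0, 1),
         "?" = c(1, 1),
         stop_invalid("invalid tip state '%s' (expected '0', '1' or '?')", state))
}

## Postorder pruning. Returns list(loglik, L = conditional likelihoods
## per node (unscaled shape, log-scaled internally), logscale per node).
prune_tree <- function(tree, tip_states, rate, root_prior = c(0.5, 0.5),
                       min_branch = 1e-8) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  if (is.null(names(tip_states))) {
    if (length(tip_states) != ntip) stop_invalid("tip state / tip count mismatch")
    names(tip_states) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    stop_invalid("tips without states: %s", paste(missing, collapse = ", "))
  }
  L <- matrix(1, nnode, 2)
  logscale <- numeric(nnode)
  for (i in seq_len(ntip)) L[i, ] <- tip_partial(tip_states[[tree$tip.label[i]]])
  po <- ape::reorder.phylo(tree, "postorder")
  bl <- pmax(po$edge.length, min_branch)
  P <- vector("list", nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) P[[e]] <- transition_prob(rate, bl[e])
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    contrib <- P[[e]] %*% L[ch, ]
    L[par, ] <- L[par, ] * contrib
    logscale[par] <- logscale[par] + logscale[ch]
    sc <- max(L[par, ])
    if (sc > 0 && (sc < 1e-100 || sc > 1e100)) {
      L[par, ] <- L[par, ] / sc
      logscale[par] <- logscale[par] + log(sc)
    }
  }
  root <- ntip + 1L
  lik <- sum(root_prior * L[root, ])
  list(loglik = log(lik) + logscale[root], L = L, logscale = logscale,
       P = P, postorder = po, min_branch = min_branch)
}

#' Log-likelihood of one binary character on a dated tree
#'
#' Felsenstein pruning over the symmetric two-state model; `"?"` tips
#' contribute the ambiguous partial likelihood (1, 1), so a character with
#' all tips uncertain has log-likelihood 0.
#'
#' @param tree dated `phylo`.
#' @param tip_states character vector over `{"1", "0", "?"}`, named by tip
#'   label (or in `tip.label` order).
#' @param rate symmetric transition rate, per Myr.
#' @param root_prior root state prior, default stationary (0.5, 0.5).
#' @return log-likelihood (numeric scalar).
#' @export
character_loglik <- function(tree, tip_states, rate, root_prior = c(0.5, 0.5)) {
  prune_tree(tree, tip_states, rate, root_prior)$loglik
}

#' Maximum-likelihood transition rate for one character
#'
#' Bounded one-dimensional optimization of [character_loglik()] over
#' `rate` in `[lower, upper]` (on the log scale, tolerance 1e-8).
#' Invariant characters whose certain tips all share one state bypass the
#' optimizer and return rate 0 (the state is fixed clade-wide).
#'
#' @inheritParams character_loglik
#' @param lower,upper rate bounds (per Myr).
#' @return list: `rate`, `loglik`, `invariant` (logical).
#' @export
estimate_rate <- function(tree, tip_states, lower = 1e-8, upper = 1e3,
                          root_prior = c(0.5, 0.5)) {
  st <- unlist(tip_states, use.names = FALSE)
  certain <- st[st != "?"]
  if (length(unique(certain)) <= 1) {
    return(list(rate = 0, loglik = NA_real_, invariant = TRUE,
                state = if (length(certain)) unname(certain[1]) else "?"))
  }
  f <- function(lr) character_loglik(tree, tip_states, exp(lr), root_prior)
  opt <- stats::optimize(f, interval = c(log(lower), log(upper)),
                         maximum = TRUE, tol = 1e-8)
  list(rate = exp(opt$maximum), loglik = opt$objective, invariant = FALSE)
}

#' Marginal ancestral state probabilities for one character
#'
#' Standard two-pass computation: a postorder pruning pass collects
#' within-subtree conditional likelihoods, then a preorder pass propagates
#' the likelihood of everything outside each node's subtree; the marginal
#' probability of each state at a node is the normalized product of the
#' two. Internal states are discretized against the threshold `theta`:
#' present when `P(present) >= theta`, absent when
#' `P(present) <= 1 - theta`, otherwise uncertain.
#'
#' @inheritParams character_loglik
#' @param theta discretization threshold in (0.5, 1], default 0.8.
#' @return list: `prob` (numeric vector, `P(present)` per internal node,
#'   named by node label), `state` (character vector over
#'   `{"1", "0", "?"}`), `loglik`.
#' @export
marginal_states <- function(tree, tip_states, rate, theta = 0.8,
                            root_prior = c(0.5, 0.5)) {
  check_number(theta, "theta")
  if (theta <= 0.5 || theta > 1) stop_invalid("`theta` must be in (0.5, 1]")
  pr <- prune_tree(tree, tip_states, rate, root_prior)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- pr$postorder
  ## D[n, s]: likelihood of all data outside subtree(n), given state s at
  ## n, including the root prior. Symmetric P, so direction is immaterial.
  D <- matrix(NA_real_, nnode, 2)
  D[root, ] <- root_prior
  edges <- rev(seq_len(nrow(po$edge)))   # parents before children
  ## per-edge child contribution to the parent: P %*% L[child]
  child_contrib <- matrix(NA_real_, nrow(po$edge), 2)
  for (e in seq_len(nrow(po$edge))) {
    child_contrib[e, ] <- pr$P[[e]] %*% pr$L[po$edge[e, 2], ]
  }
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (e in edges) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sibs <- setdiff(kids[[as.character(par)]], e)
    out_par <- D[par, ]
    for (s in sibs) out_par <- out_par * child_contrib[s, ]
    D[ch, ] <- as.vector(t(pr$P[[e]]) %*% out_par)
    mx <- max(D[ch, ])
    if (mx > 0 && (mx < 1e-100 || mx > 1e100)) D[ch, ] <- D[ch, ] / mx
  }
  internal <- (ntip + 1L):nnode
  prob <- numeric(length(internal))
  for (k in seq_along(internal)) {
    n <- internal[k]
    w <- pr$L[n, ] * D[n, ]
    prob[k] <- w[2] / sum(w)
  }
  labs <- node_labels(tree)[internal]
  names(prob) <- labs
  state <- ifelse(prob >= theta, "1", ifelse(prob <= 1 - theta, "0", "?"))
  names(state) <- labs
  list(prob = prob, state = state, loglik = pr$loglik)
}

#' Reconstruct the full ancestral niche matrix for one variable
#'
#' Fits a rate and computes marginal ancestral states independently for
#' every bin of a BR matrix. Bins whose certain tip states are invariant
#' bypass optimization: all ancestors take the shared state (or stay
#' uncertain if no tip is certain).
#'
#' @param br a `br_matrix` (rows = tree tips).
#' @param tree dated `phylo`.
#' @param theta discretization threshold (default 0.8).
#' @param lower,upper rate bounds for [estimate_rate()].
#' @return list of class `ancestral_niche`: `state` (character matrix,
#'   internal nodes x bins), `prob` (numeric matrix of `P(present)`),
#'   `rates` (per-bin fitted rate), `variable`, `scheme`.
#' @export
reconstruct_matrix <- function(br, tree, theta = 0.8, lower = 1e-8, upper = 1e3) {
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(br))
  extra <- setdiff(rownames(br), tips)
  if (length(missing) || length(extra)) {
    stop_invalid("BR matrix / tree mismatch; missing: {%s}; extra: {%s}",
                 paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  nbin <- ncol(br)
  internal <- ape::Ntip(tree) + seq_len(tree$Nnode)
  labs <- node_labels(tree)[internal]
  state <- matrix("?", length(internal), nbin,
                  dimnames = list(labs, colnames(br)))
  prob <- matrix(NA_real_, length(internal), nbin,
                 dimnames = list(labs, colnames(br)))
  rates <- rep(NA_real_, nbin)
  for (b in seq_len(nbin)) {
    tip_states <- stats::setNames(br[tips, b], tips)
    fit <- estimate_rate(tree, tip_states, lower = lower, upper = upper)
    if (fit$invariant) {
      rates[b] <- 0
      if (fit$state != "?") {
        state[, b] <- fit$state
        prob[, b] <- if (fit$state == "1") 1 else 0
      } else {
        prob[, b] <- 0.5
      }
    } else {
      rates[b] <- fit$rate
      ms <- marginal_states(tree, tip_states, fit$rate, theta = theta)
      state[, b] <- ms$state[labs]
      prob[, b] <- ms$prob[labs]
    }
  }
  structure(list(state = state, prob = prob, rates = rates,
                 variable = attr(br, "variable"), scheme = attr(br, "scheme")),
            class = "ancestral_niche")
}

#' Write ancestral niche states and probabilities as TSV
#'
#' @param anc an `ancestral_niche`.
#' @param state_path,prob_path output paths (either may be `NULL`).
#' @export
write_ancestral_niche <- function(anc, state_path = NULL, prob_path = NULL) {
  if (!is.null(state_path)) {
    utils::write.table(anc$state, state_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(prob_path)) {
    utils::write.table(anc$prob, prob_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(NULL)
}
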