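# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: likelihoods by exhaustive enumeration over all node-state
# assignments, coding/classification by literal rule application, thinning
# by exhaustive subset search.

# enumeration over all node states; tips constrained by their (possibly
# ambiguous) observed state
oracle_enumerate <- function(tree, tip_states, rate, root_prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  if (is.null(names(tip_states))) names(tip_states) <- tree$tip.label
  allowed <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[i]]]
    allowed[[i]] <- switch(s, "0" = 0L, "1" = 1L, "?" = c(0L, 1L))
  }
  for (i in (ntip + 1L):nnode) allowed[[i]] <- c(0L, 1L)
  stay <- function(t) 0.5 + 0.5 * exp(-2 * rate * t)
  combos <- expand.grid(allowed, KEEP.OUT.ATTRS = FALSE)
  root <- ntip + 1L
  total <- 0
  marg <- numeric(nnode)
  for (k in seq_len(nrow(combos))) {
    st <- as.integer(combos[k, ])
    lik <- root_prior[st[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      p <- stay(tree$edge.length[e])
      same <- st[tree$edge[e, 1]] == st[tree$edge[e, 2]]
      lik <- lik * if (same) p else 1 - p
    }
    total <- total + lik
    marg <- marg + lik * st
  }
  list(loglik = log(total), marginal_present = marg / total)
}

# literal application of the three BR coding rules on bin index ranges:
# occ_bins = bins overlapping the closed occupied interval; m coverage via
# the open accessible interval; no M => uncertain outside the present run
oracle_code_br <- function(o_lo, o_hi, m_lo, m_hi, edges) {
  n <- length(edges) - 1L
  out <- character(n)
  for (b in seq_len(n)) {
    left <- edges[b]; right <- edges[b + 1L]
    last <- b == n
    occ_overlap <- if (last) left <= o_hi && right >= o_lo else left <= o_hi && right > o_lo
    if (occ_overlap) {
      out[b] <- "1"
    } else if (is.null(m_lo)) {
      out[b] <- "?"
    } else {
      in_m <- left < m_hi && right > m_lo
      out[b] <- if (in_m) "0" else "?"
    }
  }
  out
}

# literal restatement of the bin-change rules
oracle_classify_bins <- function(A, D) {
  out <- character(length(A))
  for (i in seq_along(A)) {
    a <- A[i]; d <- D[i]
    out[i] <- if (a == "?" || d == "?") "indeterminate"
    else if (a == d) "stasis"
    else if (a == "1" && d == "0") "retraction"
    else "expansion"
  }
  out
}

# maximum number of points with all pairwise great-circle distances >= thr
oracle_max_retained <- function(lon, lat, thr_km) {
  n <- length(lon)
  d <- geosphere::distm(cbind(lon, lat), fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371.0088)
  })
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      pr <- utils::combn(idx, 2)
      ok <- all(d[t(pr)] >= thr_km)
    }
    if (ok) best <- length(idx)
  }
  best
}

random_dated_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  barniche::validate_dated_tree(tree)
}

random_tip_states <- function(tree, p_q = 0.2) {
  st <- sample(c("0", "1", "?"), ape::Ntip(tree), replace = TRUE,
               prob = c((1 - p_q) / 2, (1 - p_q) / 2, p_q))
  names(st) <- tree$tip.label
  st
}

# every distinct rooted binary tree shape with 2..6 tips (the
# Wedderburn-Etherington enumeration: 1, 1, 2, 3, 6 shapes)
all_tree_shapes <- function() {
  shapes <- c(
    "(t1,t2);",
    "((t1,t2),t3);",
    "(((t1,t2),t3),t4);",
    "((t1,t2),(t3,t4));",
    "((((t1,t2),t3),t4),t5);",
    "(((t1,t2),(t3,t4)),t5);",
    "(((t1,t2),t3),(t4,t5));",
    "(((((t1,t2),t3),t4),t5),t6);",
    "((((t1,t2),(t3,t4)),t5),t6);",
    "((((t1,t2),t3),(t4,t5)),t6);",
    "((((t1,t2),t3),t4),(t5,t6));",
    "(((t1,t2),(t3,t4)),(t5,t6));",
    "(((t1,t2),t3),((t4,t5),t6));"
  )
  lapply(shapes, function(s) ape::read.tree(text = s))
}

with_random_lengths <- function(tree, seed) {
  set.seed(seed)
  tree$edge.length <- runif(nrow(tree$edge), 0.2, 3)
  tree$node.label <- paste0("n", ape::Ntip(tree) + seq_len(tree$Nnode))
  tree
}
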