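## Mk-model likelihood and maximum-likelihood ancestral state estimation
## for a binary character, via Felsenstein's pruning algorithm and the
## re-rooting (inside/outside) pass for marginal node probabilities.

## 2x2 transition probability matrix.  ER uses a single rate q with
## P(change over t) = (1 - exp(-2qt))/2; ARD uses rates (q01, q10).
.mkP <- function(t, rates, model) {
  if (model == "ER") {
    q <- rates[1]
    pc <- (1 - exp(-2 * q * t)) / 2
    matrix(c(1 - pc, pc, pc, 1 - pc), 2, 2, byrow = TRUE)
  } else {
    r <- sum(rates)
    if (r == 0) return(diag(2))
    e <- exp(-r * t)
    matrix(c((rates[2] + rates[1] * e) / r, rates[1] * (1 - e) / r,
             rates[2] * (1 - e) / r, (rates[1] + rates[2] * e) / r),
           2, 2, byrow = TRUE)
  }
}

.mkRootPrior <- function(rates, model, rootPrior, states) {
  if (rootPrior == "observed") {
    f <- mean(states == 1)
    return(c(1 - f, f))
  }
  if (model == "ER") c(0.5, 0.5)
  else {
    r <- sum(rates)
    if (r == 0) c(0.5, 0.5) else c(rates[2], rates[1]) / r
  }
}

.checkStates <- function(x, tipStates) {
  tips <- tipLabels(x)
  key <- normalizeName(names(tipStates))
  idx <- match(normalizeName(tips), key)
  if (anyNA(idx)) {
    miss <- tips[is.na(idx)]
    psValidationError(sprintf("missing tip state(s) for: %s",
                              paste(miss, collapse = ", ")),
                      tips = miss)
  }
  st <- as.integer(tipStates[idx])
  if (any(!st %in% 0:1))
    psDomainError("tip states must be binary (0/1)")
  names(st) <- tips
  st
}

## Post-order conditional likelihoods; returns list(L, S, po, root) where
## S[[k]] is the per-edge "message" P(t_k) %*% L[child_k, ].
.mkDown <- function(phy, st, rates, model) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  L <- matrix(1, nn, 2)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), st + 1L)] <- 1
  S <- vector("list", nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    u <- po$edge[k, 1]; v <- po$edge[k, 2]
    P <- .mkP(po$edge.length[k], rates, model)
    S[[k]] <- as.vector(P %*% L[v, ])
    L[u, ] <- L[u, ] * S[[k]]
  }
  list(L = L, S = S, po = po, root = ntip + 1L)
}

#' Mk-model log-likelihood of binary tip states
#'
#' Felsenstein pruning over the tree, with the root state weighted by the
#' model's equilibrium frequencies (or the observed tip frequencies).
#' Under the equal-rates (ER) model the probability of a state change over a
#' branch of length `t` is `(1 - exp(-2*q*t)) / 2`.
#'
#' @param x a [CalibratedPhylogeny-class].
#' @param tipStates named vector of 0/1 states covering every tip.
#' @param rates rate(s) per Myr: one value for `"ER"`, `c(q01, q10)` for
#'   `"ARD"`.
#' @param model `"ER"` or `"ARD"`.
#' @param rootPrior `"equilibrium"` (default) or `"observed"`.
#' @return log-likelihood.
#' @export
mkLoglik <- function(x, tipStates, rates, model = c("ER", "ARD"),
                     rootPrior = c("equilibrium", "observed")) {
  model <- match.arg(model)
  rootPrior <- match.arg(rootPrior)
  if (any(rates < 0)) psDomainError("rates must be >= 0")
  if (model == "ER" && length(rates) != 1)
    psDomainError("ER model takes a single rate")
  if (model == "ARD" && length(rates) != 2)
    psDomainError("ARD model takes c(q01, q10)")
  st <- .checkStates(x, tipStates)
  dn <- .mkDown(x@tree, st, rates, model)
  pi <- .mkRootPrior(rates, model, rootPrior, st)
  log(sum(pi * dn$L[dn$root, ]))
}

#' Maximum-likelihood ancestral state estimation (binary Mk)
#'
#' Finds the transition rate(s) maximizing [mkLoglik()] by bounded 1-D (ER)
#' or 2-D (ARD) optimization, then computes marginal state probabilities at
#' every internal node by the re-rooting method: each node's marginal
#' combines the conditional likelihood of its subtree with the likelihood of
#' the remainder of the tree given the node's state.
#'
#' @inheritParams mkLoglik
#' @param model `"ER"` (default) or `"ARD"`.
#' @return an [AncestralEstimate-class].
#' @examples
#' phy <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' est <- estimateASR(phy, c(A = 0, B = 0, C = 1, D = 1))
#' est@marginals  # root marginal is (0.5, 0.5) by symmetry
#' @export
estimateASR <- function(x, tipStates, model = c("ER", "ARD"),
                        rootPrior = c("equilibrium", "observed")) {
  model <- match.arg(model)
  rootPrior <- match.arg(rootPrior)
  st <- .checkStates(x, tipStates)
  phy <- x@tree
  ub <- max(10, 1000 / mean(phy$edge.length))
  f <- function(r) mkLoglik(x, st, r, model = model, rootPrior = rootPrior)
  if (model == "ER") {
    ## the profile likelihood can have a local mode and a high-rate plateau;
    ## scan a log-spaced grid, then refine around the best point
    grid <- exp(seq(log(1e-7 * ub), log(ub), length.out = 60))
    lls <- vapply(grid, f, numeric(1))
    k <- which.max(lls)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    opt <- stats::optimize(function(lq) f(exp(lq)),
                           interval = log(c(lo, hi)), maximum = TRUE,
                           tol = 1e-12)
    rates <- exp(opt$maximum)
    ll <- opt$objective
    ## the data may favour the zero-rate boundary
    ll0 <- f(1e-12)
    if (ll0 > ll) { rates <- 1e-12; ll <- ll0 }
  } else {
    opt <- stats::optim(c(0.1, 0.1) / mean(phy$edge.length),
                        function(p) -f(p), method = "L-BFGS-B",
                        lower = 1e-9, upper = ub)
    if (opt$convergence != 0)
      psStop(sprintf("rate optimization did not converge (code %d)", opt$convergence),
             "psConvergenceError", best = opt$par, logLik = -opt$value)
    rates <- opt$par
    ll <- -opt$value
  }
  names(rates) <- if (model == "ER") "q" else c("q01", "q10")
  marg <- .mkMarginals(x, st, rates, model, rootPrior)
  new("AncestralEstimate", rates = rates, logLik = ll, marginals = marg,
      model = model)
}

## Marginal probabilities at internal nodes.  G[v, ] is the likelihood of
## all data outside v's subtree given the state at v, seeded with the root
## prior; marginal(v) is proportional to L[v, ] * G[v, ].
.mkMarginals <- function(x, st, rates, model, rootPrior) {
  phy <- x@tree
  ntip <- length(phy$tip.label)
  dn <- .mkDown(phy, st, rates, model)
  po <- dn$po
  pi <- .mkRootPrior(rates, model, rootPrior, st)
  nn <- ntip + phy$Nnode
  G <- matrix(NA_real_, nn, 2)
  G[dn$root, ] <- pi

  childEdges <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (k in rev(seq_len(nrow(po$edge)))) {       # pre-order
    u <- po$edge[k, 1]; v <- po$edge[k, 2]
    if (v <= ntip) next
    excl <- c(1, 1)
    for (j in childEdges[[as.character(u)]])
      if (j != k) excl <- excl * dn$S[[j]]
    H <- G[u, ] * excl
    P <- .mkP(po$edge.length[k], rates, model)
    G[v, ] <- as.vector(t(P) %*% H)
  }

  nodes <- (ntip + 1L):nn
  m <- dn$L[nodes, , drop = FALSE] * G[nodes, , drop = FALSE]
  m <- m / rowSums(m)
  colnames(m) <- c("state0", "state1")
  rownames(m) <- if (!is.null(phy$node.label) &&
                     all(nzchar(phy$node.label)))
    phy$node.label else paste0("node_", nodes)
  m
}
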