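## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: likelihoods by exhaustive enumeration, shared
## depths by walking root-to-tip paths, GLS in closed form.

## 2x2 transition matrix, written out independently of the package.
oracleP <- function(t, rates, model) {
  if (model == "ER") {
    q <- rates[1]
    pc <- (1 - exp(-2 * q * t)) / 2
    matrix(c(1 - pc, pc, pc, 1 - pc), 2, 2, byrow = TRUE)
  } else {
    a <- rates[1]; b <- rates[2]; r <- a + b
    if (r == 0) return(diag(2))
    e <- exp(-r * t)
    matrix(c((b + a * e) / r, a * (1 - e) / r,
             b * (1 - e) / r, (a + b * e) / r), 2, 2, byrow = TRUE)
  }
}

oracleRootPrior <- function(rates, model, rootPrior, states) {
  if (rootPrior == "observed") {
    f <- mean(states == 1)
    c(1 - f, f)
  } else if (model == "ER") c(0.5, 0.5)
  else if (sum(rates) == 0) c(0.5, 0.5)
  else c(rates[2], rates[1]) / sum(rates)
}

## Likelihood of binary tip states by brute-force summation over every
## assignment of states to internal nodes.
bruteMkLik <- function(phy, states, rates, model = "ER",
                       rootPrior = "equilibrium") {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  st <- states[phy$tip.label]
  pi <- oracleRootPrior(rates, model, rootPrior, st)
  root <- ntip + 1L
  total <- 0
  for (code in 0:(2^nint - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(nint)]
    full <- c(st, assign)           # indexed by node number
    p <- pi[full[root] + 1]
    for (k in seq_len(nrow(phy$edge))) {
      u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
      P <- oracleP(phy$edge.length[k], rates, model)
      p <- p * P[full[u] + 1, full[v] + 1]
    }
    total <- total + p
  }
  total
}

## Marginal state probabilities at internal nodes by the same enumeration,
## accumulating probability mass per (node, state) and normalizing.
bruteMkMarginals <- function(phy, states, rates, model = "ER",
                             rootPrior = "equilibrium") {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  st <- states[phy$tip.label]
  pi <- oracleRootPrior(rates, model, rootPrior, st)
  root <- ntip + 1L
  mass <- matrix(0, nint, 2)
  for (code in 0:(2^nint - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(nint)]
    full <- c(st, assign)
    p <- pi[full[root] + 1]
    for (k in seq_len(nrow(phy$edge))) {
      u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
      P <- oracleP(phy$edge.length[k], rates, model)
      p <- p * P[full[u] + 1, full[v] + 1]
    }
    for (j in seq_len(nint)) mass[j, assign[j] + 1] <- mass[j, assign[j] + 1] + p
  }
  mass / rowSums(mass)
}

## Shared root-to-MRCA depth between two tips, by intersecting the
## root-to-tip edge paths.
bruteSharedDepth <- function(phy, tipA, tipB) {
  pathEdges <- function(tip) {
    node <- which(phy$tip.label == tip)
    out <- integer(0)
    repeat {
      k <- which(phy$edge[, 2] == node)
      if (!length(k)) break
      out <- c(out, k)
      node <- phy$edge[k, 1]
    }
    out
  }
  shared <- intersect(pathEdges(tipA), pathEdges(tipB))
  sum(phy$edge.length[shared])
}

## Closed-form generalized least squares.
glsEstimate <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

## Fixed Table-1-style worked inputs: a species with seven prey groups,
## three of them carrying quantitative proportions.
workedDietReports <- function() {
  list(
    qual = qualitativeDietReport(
      "Amaurobius similis",
      c(Coleoptera = "common", Dermaptera = "common", Diptera = "major",
        Hymenoptera = "uncommon", Araneae = "rare", Hemiptera = "common",
        Isopoda = "rare")),
    quant = quantitativeDietReport(
      "Amaurobius similis",
      c(Coleoptera = 0.21, Diptera = 0.75, Araneae = 0.01))
  )
}

## Small assay-level dataset simulated under the animal model, used by the
## GLS-oracle checks.
glsTestData <- function(nSpecies = 20, seed = 101, truth = NULL) {
  if (is.null(truth)) {
    truth <- defaultGroundTruth()
    truth$betaMass <- 0.2
  }
  phy <- simulateTree(nSpecies, seed = seed)
  traits <- simulateTraits(phy, truth, seed = seed + 1)
  diets <- simulateDiets(tipLabels(phy), seed = seed + 2)
  assays <- simulateLD50(phy, diets, traits, truth, seed = seed + 3)
  d <- assays
  d$log10_mass <- log10(traits$body_mass_g[match(d$species, traits$species)])
  list(phy = phy, data = d, truth = truth)
}

## Record-level covariance V = s2a * A[sp, sp] + s2s * ZZ' + s2e * I and the
## corresponding design matrix for a D + log10_mass model.
glsOracleFit <- function(dat) {
  d <- dat$data
  X <- cbind(1, d$d_ld50_diet_hmya, d$log10_mass)
  A <- phyloCorrelationMatrix(dat$phy, unique(d$species))
  idx <- match(d$species, rownames(A))
  Zs <- outer(d$species, unique(d$species), "==") * 1
  tr <- dat$truth
  V <- tr$sigma2Animal * A[idx, idx] + tr$sigma2Species * tcrossprod(Zs) +
    tr$sigma2Resid * diag(nrow(d))
  list(X = X, y = d$log10_ld50, V = V, beta = glsEstimate(X, d$log10_ld50, V))
}

## Strong (near-point-mass) inverse-gamma priors centred on given variances.
strongPriors <- function(truth, shape = 1e6) {
  list(animal = c(shape = shape, scale = (shape - 1) * truth$sigma2Animal),
       species = c(shape = shape, scale = (shape - 1) * truth$sigma2Species),
       residual = c(shape = shape, scale = (shape - 1) * truth$sigma2Resid))
}

## Monte-Carlo standard error of a posterior mean.
mcse <- function(x) stats::sd(x) / sqrt(effectiveSize(x))
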