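#' Phylogenetic correlation matrix
#'
#' Expected trait correlation between species under Brownian evolution on
#' the tree: entry (i, j) is the length of the shared root-to-MRCA path
#' divided by the total tree depth, so the diagonal is 1 for an ultrametric
#' tree.  The result is the "A" matrix of the animal model.
#'
#' @param x an ultrametric [CalibratedPhylogeny-class].
#' @param species species names to include (default: all tips); matched
#'   case-insensitively with spaces and underscores interchangeable.
#' @return symmetric positive-semidefinite matrix with unit diagonal,
#'   dimnames = species.
#' @examples
#' phy <- readNewick("((A:100,B:100):200,C:300);")
#' phyloCorrelationMatrix(phy)["A", "B"]  # 200/300
#' @export
phyloCorrelationMatrix <- function(x, species = tipLabels(x)) {
  if (!isUltrametric(x))
    psDomainError("tree is not ultrametric; shared-depth correlations are undefined")
  phy <- x@tree
  key <- normalizeName(phy$tip.label)
  idx <- match(normalizeName(species), key)
  if (anyNA(idx))
    psLookupError(sprintf("species not on tree: %s",
                          paste(species[is.na(idx)], collapse = ", ")),
                  taxon = species[which(is.na(idx))[1]])
  V <- ape::vcv.phylo(phy)
  A <- V[idx, idx, drop = FALSE] / treeDepth(x)
  dimnames(A) <- list(species, species)
  A
}

#' Default inverse-gamma variance priors
#'
#' The weakest conventional conjugate choice standing in for "flat"
#' variance priors: inverse-gamma with shape and scale both `eps`.
#'
#' @param eps shape and scale (default 0.001).
#' @return named list with `animal`, `species`, `residual` components.
#' @export
defaultPriors <- function(eps = 0.001) {
  pr <- c(shape = eps, scale = eps)
  list(animal = pr, species = pr, residual = pr)
}

#' Construct a mixed-model specification
#'
#' Defaults follow standard practice for this class of analysis: 2 400 000
#' iterations with a burn-in of 40 000 and thinning of 100 over 3 chains
#' (23 600 retained draws per chain, comfortably above 1000 per parameter),
#' injection-route reference level `IP`, silk-use reference `FALSE`
#' (non-silk hunter), and [defaultPriors()].  Tests and exploratory fits
#' should pass scaled-down chain settings.
#'
#' @param response response column name (e.g. `"log10_ld50"`).
#' @param fixed character vector of fixed-effect terms; interactions as
#'   `"a:b"`.
#' @param random random terms, subset of `c("animal", "species")`.
#' @param referenceLevels named list of reference levels for categorical
#'   terms.
#' @param priors see [defaultPriors()].
#' @param iterations,burnin,thin,nChains,seed chain settings.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(response, fixed = character(0),
                      random = c("animal", "species"),
                      referenceLevels = list(route = "IP", silk_use = "FALSE"),
                      priors = defaultPriors(),
                      iterations = 2400000L, burnin = 40000L, thin = 100L,
                      nChains = 3L, seed = 42L) {
  new("ModelSpec", response = response, fixed = fixed, random = random,
      referenceLevels = referenceLevels, priors = priors,
      iterations = as.integer(iterations), burnin = as.integer(burnin),
      thin = as.integer(thin), nChains = as.integer(nChains),
      seed = as.integer(seed))
}

#' Fit a Bayesian phylogenetic mixed model by Gibbs sampling
#'
#' Fits the Gaussian animal model
#' `y = X beta + Z a + Z s + e`, where `a` is the phylogenetic random effect
#' with covariance `sigma2_a * A` (`A` from [phyloCorrelationMatrix()]),
#' `s` the iid species repeat-measure effect and `e` the residual.  The
#' improper flat prior on `beta` and conjugate inverse-gamma priors on the
#' variances make all full conditionals available in closed form, so the
#' sampler is a plain Gibbs scheme (implemented in compiled code).  Chain
#' `k` is seeded with `seed + k - 1`; with fixed settings the entire draw
#' stream is bit-reproducible.
#'
#' @param data data.frame holding the response, every fixed-effect column,
#'   and a `species` column when random terms are present.
#' @param spec a [ModelSpec-class].
#' @param tree a [CalibratedPhylogeny-class]; required when `"animal"` is
#'   among the random terms.
#' @return a [PMMFit-class].
#' @seealso [summarizePMM()], [gelmanRubin()]
#' @export
fitPMM <- function(data, spec, tree = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  resp <- spec@response
  if (!resp %in% names(data))
    psValidationError(sprintf("response column '%s' not in data", resp),
                      column = resp)
  vars <- unique(unlist(strsplit(spec@fixed, ":", fixed = TRUE)))
  missing <- setdiff(vars, names(data))
  if (length(missing))
    psValidationError(sprintf("fixed-effect column(s) missing: %s",
                              paste(missing, collapse = ", ")),
                      column = missing[1])
  ## apply reference levels to categorical terms
  for (v in vars) {
    if (is.character(data[[v]]) || is.factor(data[[v]]) || is.logical(data[[v]])) {
      f <- factor(as.character(data[[v]]))
      ref <- spec@referenceLevels[[v]]
      if (!is.null(ref) && as.character(ref) %in% levels(f))
        f <- stats::relevel(f, ref = as.character(ref))
      data[[v]] <- f
    }
  }
  form <- if (length(spec@fixed)) stats::reformulate(spec@fixed) else ~1
  X <- stats::model.matrix(form, data = data)
  y <- data[[resp]]
  if (any(!is.finite(y)) || any(!is.finite(X)))
    psValidationError("non-finite values in response or design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    psDomainError(sprintf("fixed-effect design is rank deficient; collinear column(s): %s",
                          paste(drop, collapse = ", ")),
                  columns = drop)
  }

  useAnimal <- "animal" %in% spec@random
  useSpecies <- "species" %in% spec@random
  if ((useAnimal || useSpecies) && !"species" %in% names(data))
    psValidationError("random terms need a 'species' column", column = "species")

  if (useAnimal || useSpecies) {
    spFac <- factor(as.character(data$species))
    spIdx <- as.integer(spFac) - 1L
    speciesLevels <- levels(spFac)
  } else {
    spIdx <- integer(nrow(data))
    speciesLevels <- character(0)
  }
  q <- max(1L, length(speciesLevels))

  if (useAnimal) {
    if (is.null(tree))
      psDomainError("the animal term requires a calibrated tree")
    A <- phyloCorrelationMatrix(tree, speciesLevels)
    Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
      psDomainError("phylogenetic correlation matrix is not positive definite"))
  } else {
    Ainv <- diag(q)
  }

  pr <- spec@priors
  draws <- vector("list", spec@nChains)
  for (ch in seq_len(spec@nChains)) {
    set.seed(spec@seed + ch - 1L)
    m <- .pmm_gibbs_cpp(y, X, spIdx, Ainv,
                        useAnimal, useSpecies, q,
                        pr$animal[["shape"]], pr$animal[["scale"]],
                        pr$species[["shape"]], pr$species[["scale"]],
                        pr$residual[["shape"]], pr$residual[["scale"]],
                        spec@iterations, spec@burnin, spec@thin)
    colnames(m) <- c(colnames(X), "var_animal", "var_species", "var_resid")
    draws[[ch]] <- m
  }
  new("PMMFit", draws = draws, spec = spec, species = speciesLevels,
      nObs = nrow(data))
}

#' Gelman-Rubin convergence diagnostic (R-hat)
#'
#' Potential scale reduction factor for one parameter over several chains:
#' with m chains of length n, within-chain variance `W` (mean of the
#' per-chain variances) and between-chain variance `B = n * var(chain
#' means)`, the pooled variance estimate is `(n-1)/n * W + B/n` and R-hat is
#' the square root of its ratio to `W`.  Values near 1 indicate convergence;
#' > 1.1 is the conventional alarm threshold.
#'
#' @param chains list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @return R-hat.
#' @export
gelmanRubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) psDomainError("R-hat needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) psDomainError("chains must have equal length")
  if (n < 10) psDomainError("chains must have length >= 10")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of one MCMC stream
#'
#' Initial-positive-sequence estimate: `n / (1 + 2 * sum(rho_k))` with the
#' autocorrelations accumulated until they first drop to zero or below.
#'
#' @param x numeric draw vector.
#' @return effective sample size.
#' @export
effectiveSize <- function(x) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 10 * ceiling(log10(n)) * 10),
                   plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  ess <- n / (1 + 2 * sum(ac))
  max(1, min(n, ess))
}

#' Summarize a phylogenetic mixed-model fit
#'
#' Posterior means, equal-tailed 95% credibility intervals, the
#' interval-excludes-zero significance flag, per-parameter R-hat (when at
#' least two chains were run) and effective sample sizes for the fixed
#' effects; posterior means of the variance components; and the phylogenetic
#' heritability h2, computed per draw as `var_animal / denominator` and then
#' summarized.  By default the denominator is the sum of all three variance
#' components (animal + species + residual); `h2Denominator =
#' "animal_resid"` restricts it to animal + residual.
#'
#' @param fit a [PMMFit-class].
#' @param h2Denominator `"all"` or `"animal_resid"`.
#' @param prob interval mass (default 0.95).
#' @return a [PosteriorSummary-class].
#' @export
summarizePMM <- function(fit, h2Denominator = c("all", "animal_resid"),
                         prob = 0.95) {
  h2Denominator <- match.arg(h2Denominator)
  all <- posteriorDraws(fit)
  if (nrow(all) < 2) psDomainError("need at least 2 draws to summarize")
  alpha <- (1 - prob) / 2
  varCols <- c("var_animal", "var_species", "var_resid")
  fxCols <- setdiff(colnames(all), varCols)

  qs <- apply(all[, fxCols, drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha))
  rhat <- vapply(fxCols, function(p) {
    if (length(fit@draws) >= 2)
      gelmanRubin(lapply(fit@draws, function(m) m[, p]))
    else NA_real_
  }, numeric(1))
  ess <- vapply(fxCols, function(p)
    sum(vapply(fit@draws, function(m) effectiveSize(m[, p]), numeric(1))),
    numeric(1))
  fx <- data.frame(mean = colMeans(all[, fxCols, drop = FALSE]),
                   lower = qs[1, ], upper = qs[2, ],
                   significant = qs[1, ] > 0 | qs[2, ] < 0,
                   rhat = rhat, ess = ess, row.names = fxCols)

  vr <- data.frame(mean = colMeans(all[, varCols, drop = FALSE]),
                   row.names = varCols)

  denom <- if (h2Denominator == "all")
    all[, "var_animal"] + all[, "var_species"] + all[, "var_resid"]
  else all[, "var_animal"] + all[, "var_resid"]
  h2draw <- ifelse(denom > 0, all[, "var_animal"] / denom, 0)
  h2 <- c(mean = mean(h2draw),
          lower = unname(stats::quantile(h2draw, alpha)),
          upper = unname(stats::quantile(h2draw, 1 - alpha)))

  new("PosteriorSummary", fixed = fx, variance = vr, h2 = h2,
      h2Denominator = h2Denominator)
}
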