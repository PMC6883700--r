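# Shared helpers: random generators and independent oracles.

# sparse random polynomial with small integer coefficients
randomPoly <- function(vars, maxdeg = 2, nterms = 3) {
  nv <- length(vars)
  exps <- matrix(0L, nterms, nv)
  for (i in seq_len(nterms)) {
    td <- sample(0:maxdeg, 1)
    if (td > 0) for (k in seq_len(td)) {
      j <- sample(nv, 1)
      exps[i, j] <- exps[i, j] + 1L
    }
  }
  qpoly(vars, exps, as.character(sample(c(-9:-1, 1:9), nterms, TRUE)))
}

randomSystem <- function(nv = sample(2:3, 1)) {
  vars <- paste0("x", seq_len(nv))
  lapply(seq_len(nv), function(i) randomPoly(vars))
}

# random mass-action network over the given species
randomNetwork <- function(species, nreact = 5) {
  reacts <- lapply(seq_len(nreact), function(i) {
    nr <- sample(0:2, 1)
    np <- sample(1:2, 1)
    re <- table(sample(species, nr, replace = TRUE))
    pr <- table(sample(species, np, replace = TRUE))
    reaction(setNames(as.integer(re), names(re)),
             setNames(as.integer(pr), names(pr)),
             k = as.character(sample(1:9, 1)))
  })
  reactionNetwork(species, reacts)
}

# independent brute-force assembly of mass-action right-hand sides:
# numeric evaluation of sum over reactions of delta * k * prod(conc^stoich)
bruteForceRhs <- function(network, conc) {
  out <- setNames(rep(0, length(network@species)), network@species)
  for (r in network@reactions) {
    kval <- if (r$k %in% names(network@parameters)) network@parameters[[r$k]] else r$k
    k <- ratToNumeric(kval)
    rate <- k
    for (s in names(r$reactants)) {
      if (s %in% network@species) rate <- rate * conc[[s]]^r$reactants[[s]]
    }
    for (s in network@species) {
      d <- 0
      if (s %in% names(r$reactants)) d <- d - r$reactants[[s]]
      if (s %in% names(r$products)) d <- d + r$products[[s]]
      out[s] <- out[s] + d * rate
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multi-start damped-Newton solver on a square polynomial system; an
# independent route to the admissible steady states (no Groebner machinery)
multiStartNewton <- function(polys, vars, lo = 0, hi = 10, nstarts = 400, seed = 1) {
  set.seed(seed)
  evalF <- function(x) vapply(polys, qpEvalNum, numeric(1), point = setNames(x, vars))
  evalJ <- function(x) {
    J <- matrix(0, length(polys), length(vars))
    for (i in seq_along(polys)) for (j in seq_along(vars))
      J[i, j] <- qpEvalNum(qpDeriv(polys[[i]], vars[j]), setNames(x, vars))
    J
  }
  sols <- list()
  for (s in seq_len(nstarts)) {
    x <- runif(length(vars), lo, hi)
    for (it in 1:80) {
      f <- evalF(x)
      if (max(abs(f)) < 1e-12) break
      step <- tryCatch(qr.solve(evalJ(x), f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
      x <- x - step
    }
    if (max(abs(evalF(x))) < 1e-9 && all(x > -1e-8)) {
      dup <- any(vapply(sols, function(s0) max(abs(s0 - x)) < 1e-6, logical(1)))
      if (!dup) sols[[length(sols) + 1]] <- x
    }
  }
  if (!length(sols)) return(matrix(numeric(), 0, length(vars), dimnames = list(NULL, vars)))
  m <- do.call(rbind, sols)
  colnames(m) <- vars
  m[order(m[, 1]), , drop = FALSE]
}

sympyAvailable <- function() switchscan:::.sympy_available()

# squared root-difference discriminant oracle for a monic-(-1) cubic:
# D equals the product of squared root gaps when all three roots are real
rootGapDiscriminant <- function(roots) {
  stopifnot(length(roots) == 3)
  prod(outer(roots, roots, "-")[lower.tri(matrix(0, 3, 3))]^2)
}

.basis_equals <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  keyed <- function(ps) sort(vapply(ps, formatPoly, character(1)))
  identical(keyed(a), keyed(b))
}

.reorder_vars <- function(p, vars) switchscan:::.reorder_poly(p, vars)
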