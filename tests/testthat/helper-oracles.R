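# Independent brute-force oracles used across the suite.  These are written
# as plainly as possible (explicit loops, no shared code with the package
# internals) so they can stand as references for the vectorized
# implementations.

# Flood-fill connected-component labelling of a logical 3D mask by explicit
# queue-based BFS over the chosen neighborhood.
oracle_flood_fill <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz <= 2, , drop = FALSE],
                 "26" = offs)
  labels <- array(0L, dims)
  current <- 0L
  n_off <- nrow(offs)
  stack <- integer(prod(dims))
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    labels[start] <- current
    stack[1] <- start
    sp <- 1L
    while (sp > 0L) {
      lin <- stack[sp]; sp <- sp - 1L
      lin0 <- lin - 1L
      i <- lin0 %% dims[1] + 1L
      j <- (lin0 %/% dims[1]) %% dims[2] + 1L
      k <- lin0 %/% (dims[1] * dims[2]) + 1L
      for (m in seq_len(n_off)) {
        wi <- i + offs[m, 1]; wj <- j + offs[m, 2]; wk <- k + offs[m, 3]
        if (wi < 1L || wi > dims[1] || wj < 1L || wj > dims[2] ||
            wk < 1L || wk > dims[3]) next
        wlin <- (wk - 1L) * dims[1] * dims[2] + (wj - 1L) * dims[1] + wi
        if (mask[wlin] && labels[wlin] == 0L) {
          labels[wlin] <- current
          stack[sp <- sp + 1L] <- wlin
        }
      }
    }
  }
  labels
}

# component sizes as a sorted signature (for comparing two labelings up to
# label permutation)
component_signature <- function(labels_vec) {
  sort(as.integer(table(labels_vec[labels_vec != 0])))
}

# same-partition check: two labelings of the same foreground agree iff the
# co-membership relation is identical
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ka <- match(a, unique(a))
  kb <- match(b, unique(b))
  all(ka == kb)
}

# brute-force mean SUV over voxel centers within radius_mm of center_mm
oracle_sphere_mean <- function(suv, spacing, center_mm, radius_mm) {
  dims <- dim(suv)
  total <- 0; n <- 0
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    pos <- (c(i, j, k) - 1) * spacing
    if (sum((pos - center_mm)^2) <= radius_mm^2 + 1e-9) {
      total <- total + suv[i, j, k]; n <- n + 1
    }
  }
  total / n
}

# exhaustive SUVpeak: for every candidate center in `voxels`, average SUV
# over all in-grid voxels within the sphere radius, and take the max
oracle_suv_peak <- function(suv, spacing, voxels, sphere_volume_cm3 = 1) {
  dims <- dim(suv)
  r <- 10 * (3 * sphere_volume_cm3 / (4 * pi))^(1 / 3)
  best <- -Inf
  for (v in seq_len(nrow(voxels))) {
    ctr <- (voxels[v, ] - 1) * spacing
    total <- 0; n <- 0
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
      pos <- (c(i, j, k) - 1) * spacing
      if (sum((pos - ctr)^2) <= r^2 + 1e-9) {
        total <- total + suv[i, j, k]; n <- n + 1
      }
    }
    best <- max(best, total / n)
  }
  best
}

# hand product-limit estimator: returns data.frame(time, surv) at event times
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# hand log-rank statistic (1 df) via risk-set tallies
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(as.factor(group))  # 1/2
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# grid-search maximizer of the Cox partial likelihood (Efron ties) for a
# binary covariate x in {0,1}
oracle_cox_beta_grid <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  loglik <- function(beta) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      risk <- which(time >= t)
      dead <- which(time == t & event == 1)
      d <- length(dead)
      sr <- sum(exp(beta * x[risk]))
      sd_ <- sum(exp(beta * x[dead]))
      ll <- ll + beta * sum(x[dead])
      for (l in seq_len(d) - 1)
        ll <- ll - log(sr - (l / d) * sd_)
    }
    ll
  }
  vals <- vapply(grid, loglik, numeric(1))
  grid[which.max(vals)]
}

# Clopper-Pearson bounds by bisection on the binomial tail sums
oracle_cp_bisect <- function(k, n, level = 0.95, tol = 1e-10) {
  alpha <- 1 - level
  upper_tail <- function(p) sum(dbinom(k:n, n, p))   # P(X >= k)
  lower_tail <- function(p) sum(dbinom(0:k, n, p))   # P(X <= k)
  bisect <- function(f, target, lo, hi) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (k == 0) 0 else bisect(upper_tail, alpha / 2, 0, 1)
  hi <- if (k == n) 1 else bisect(function(p) 1 - lower_tail(p), 1 - alpha / 2, 0, 1)
  c(lo, hi)
}

# Fisher exact two-sided p by exhaustive hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random small cohort of lesion tables for property tests
random_cohort <- function(n_patients, seed) {
  set.seed(seed)
  lesions <- list()
  patients <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("R%03d", i)
    scanned <- runif(1) < 0.4
    n <- sample(1:6, 1)
    lesions[[i]] <- data.frame(
      patient_id = pid, lesion_id = seq_len(n),
      compartment = sample(c("nodes", "bones", "liver", "other"), n, TRUE),
      volume_cm3 = round(runif(n, 1, 20), 2),
      ratio_fdg = round(runif(n, 0.2, 4), 3),
      ratio_psma = round(runif(n, 0.2, 4), 3),
      ratio_dotatate = if (scanned) round(runif(n, 0.2, 4), 3) else NA_real_,
      stringsAsFactors = FALSE)
    patients[[i]] <- data.frame(patient_id = pid, dotatate_scanned = scanned,
                                stringsAsFactors = FALSE)
  }
  list(patients = do.call(rbind, patients), lesions = do.call(rbind, lesions))
}
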