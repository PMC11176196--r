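# Independent oracles used by the unit and acceptance tests. These mirror
# the documented rules with plain scalar/loop code and are kept separate
# from the package implementations they check.

# Brute-force PCIT: triple loop over unordered trios, scalar arithmetic.
pcit_keep_oracle <- function(r, guard = 1e-12) {
  n <- nrow(r)
  elim <- matrix(FALSE, n, n)
  pc <- function(rab, rac, rbc) {
    den <- sqrt((1 - rac^2) * (1 - rbc^2))
    if (den < guard) {
      return(NA_real_)
    }
    (rab - rac * rbc) / den
  }
  ratio <- function(partial, direct) {
    if (abs(direct) < guard) {
      return(0)
    }
    partial / direct
  }
  if (n >= 3) {
    for (x in 1:(n - 2)) {
      for (y in (x + 1):(n - 1)) {
        for (z in (y + 1):n) {
          rxy <- r[x, y]
          rxz <- r[x, z]
          ryz <- r[y, z]
          pxy <- pc(rxy, rxz, ryz)
          pxz <- pc(rxz, rxy, ryz)
          pyz <- pc(ryz, rxy, rxz)
          if (anyNA(c(pxy, pxz, pyz))) next # degenerate trio
          eps <- abs((ratio(pxy, rxy) + ratio(pxz, rxz) + ratio(pyz, ryz)) / 3)
          if (abs(rxy) < eps * abs(rxz) && abs(rxy) < eps * abs(ryz)) {
            elim[x, y] <- elim[y, x] <- TRUE
          }
          if (abs(rxz) < eps * abs(rxy) && abs(rxz) < eps * abs(ryz)) {
            elim[x, z] <- elim[z, x] <- TRUE
          }
          if (abs(ryz) < eps * abs(rxy) && abs(ryz) < eps * abs(rxz)) {
            elim[y, z] <- elim[z, y] <- TRUE
          }
        }
      }
    }
  }
  keep <- !elim
  diag(keep) <- FALSE
  dimnames(keep) <- dimnames(r)
  keep
}

# Random correlation matrix from simulated multivariate data.
random_corr <- function(n_vars, n_obs = 20) {
  x <- matrix(rnorm(n_obs * n_vars), n_obs, n_vars,
    dimnames = list(NULL, paste0("V", seq_len(n_vars)))
  )
  # add shared structure so strong and weak edges coexist
  f <- rnorm(n_obs)
  idx <- sample(n_vars, max(2, n_vars %/% 2))
  x[, idx] <- x[, idx] + outer(f, runif(length(idx), 0.5, 1.5))
  stats::cor(x)
}

# Trimmed-mean-of-M-values factors executed step by step per the documented
# procedure (reference by upper-quartile closeness; double trim on M and A;
# inverse asymptotic binomial variance weights; geometric mean 1).
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(cc) quantile(cc / sum(cc), 0.75))
  ref_i <- which.min(abs(uq - mean(uq)))
  ref <- counts[, ref_i]
  n_ref <- lib[ref_i]
  one_factor <- function(obs, n_obs) {
    both <- obs > 0 & ref > 0
    o <- obs[both]
    rr <- ref[both]
    m <- log2((o / n_obs) / (rr / n_ref))
    a <- (log2(o / n_obs) + log2(rr / n_ref)) / 2
    v <- (n_obs - o) / (n_obs * o) + (n_ref - rr) / (n_ref * rr)
    w <- 1 / v # inverse asymptotic binomial variance
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    f <- sum(w[keep] * m[keep]) / sum(w[keep])
    if (!is.finite(f) || abs(f) < 1e-6) f <- 0
    2^f
  }
  f <- vapply(
    seq_len(ncol(counts)),
    function(i) one_factor(counts[, i], lib[i]),
    numeric(1)
  )
  f / exp(mean(log(f)))
}

# Small, fast simulation for unit tests; `...` overrides the defaults.
small_config <- function(seed = 1, ...) {
  args <- list(
    n_animals_per_diet = 10,
    n_genes = 300,
    n_de_per_tissue = 30,
    n_regulators = 30,
    n_rewired_regulators = 4,
    n_targets_per_regulator = 5,
    missing_samples = list(muscle = c("A03", "A14"), rumen = "A17"),
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

toy_count_dataset <- function(seed = 1) {
  simulate_counts(small_config(seed))$dataset
}
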